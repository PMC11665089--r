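test_that("genome construction is deterministic and respects the design", {
  g1 <- small_genome(seed = 11)
  g2 <- small_genome(seed = 11)
  expect_equal(g1$sites, g2$sites)
  expect_equal(g1$annotation$genes, g2$annotation$genes)
  # same seed twice -> byte-identical annotation files
  d1 <- tempfile(); d2 <- tempfile()
  write_genome_annotation(g1, d1); write_genome_annotation(g2, d2)
  for (f in c("genes.bed", "tes.bed", "pericentromere.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # different seed -> different placements
  g3 <- small_genome(seed = 12)
  expect_false(identical(g1$sites$pos, g3$sites$pos))
})

test_that("pericentromere share and feature bookkeeping match the design", {
  g <- build_genome(genome_design(n_chrom = 2, chrom_length = 500000L,
                                  pericentromere_fraction = 0.2), seed = 21)
  tiles <- tile_genome(g$chrom_sizes, 50)
  mid_in_peri <- rep(FALSE, nrow(tiles))
  for (i in seq_len(nrow(g$annotation$pericentromeres))) {
    p <- g$annotation$pericentromeres[i]
    mid <- (tiles$start + tiles$end) / 2
    mid_in_peri <- mid_in_peri |
      (tiles$chrom == p$chrom & mid >= p$start & mid < p$end)
  }
  expect_equal(mean(mid_in_peri), 0.2, tolerance = 0.001)
  # requested long TEs are present, long, and pericentromeric
  long_tes <- g$annotation$tes[length > 2000]
  expect_equal(nrow(long_tes), 2L * 20L)
  in_peri <- logical(nrow(long_tes))
  for (i in seq_len(nrow(g$annotation$pericentromeres))) {
    p <- g$annotation$pericentromeres[i]
    in_peri <- in_peri | (long_tes$chrom == p$chrom & long_tes$start >= p$start &
                            long_tes$end <= p$end)
  }
  expect_true(all(in_peri))
  # genes never overlap the pericentromere
  genes <- g$annotation$genes
  for (i in seq_len(nrow(g$annotation$pericentromeres))) {
    p <- g$annotation$pericentromeres[i]
    expect_false(any(genes$chrom == p$chrom & genes$start < p$end &
                       genes$end > p$start))
  }
  # infeasible packing is a configuration error
  expect_error(build_genome(genome_design(
    chrom_length = 10000L, genes_per_chrom = 100L), seed = 1),
    "infeasible packing")
})

test_that("sampling honours the regime surface at scale", {
  g <- small_genome(seed = 31)
  # mu = 0.5 with near-degenerate spread and huge depth: LLN at one site set
  reg <- methylation_regime("flat", nu = 1e7, depth_mean = 1000,
                            depth_size = Inf, epsilon = 0)
  reg$table[, mu := 0.5]
  s <- simulate_sample(g, reg, "leaf", "WT", seed = 32)
  frac <- s[, sum(count_meth) / sum(count_meth + count_unmeth)]
  expect_equal(frac, 0.5, tolerance = 0.05)
  # degenerate zero depth still yields a syntactically valid report
  reg0 <- methylation_regime("flat", depth_mean = 0, depth_size = Inf)
  s0 <- simulate_sample(g, reg0, "leaf", "WT", seed = 33)
  expect_true(all(s0$count_meth + s0$count_unmeth == 0L))
  f <- tempfile(); write_cytosine_report(s0, f)
  expect_equal(nrow(read_cytosine_report(f)), nrow(s0))
  # closed form with bisulfite failure: mu 0.8, eps 0.005 -> 0.8*0.995 within
  # ±0.01 (the nonconversion model gives 0.8 + 0.2*0.005, also inside)
  reg8 <- methylation_regime("flat", nu = 20, depth_mean = 30,
                             epsilon = 0.005)
  reg8$table[, mu := 0.8]
  s8 <- simulate_sample(g, reg8, "leaf", "WT", seed = 34)
  big <- s8[seq_len(min(.N, 10000))]
  frac8 <- big[, sum(count_meth) / sum(count_meth + count_unmeth)]
  expect_equal(frac8, 0.8 * 0.995, tolerance = 0.0125)
  expect_error(methylation_regime("flat", nu = -1), "positive")
  expect_error(methylation_regime("flat", epsilon = 1), "epsilon")
})

test_that("identical (config, seed) reproduce byte-identical study outputs", {
  g <- small_genome(seed = 41)
  reg <- methylation_regime("regeneration", gene_cg_sd = 0.05)
  st1 <- simulate_study(g, reg, replicates = c(leaf = 2, callus = 2),
                        stages_by_genotype = list(WT = c("leaf", "callus")),
                        seed = 42, n_control_sites = 2000)
  st2 <- simulate_study(g, reg, replicates = c(leaf = 2, callus = 2),
                        stages_by_genotype = list(WT = c("leaf", "callus")),
                        seed = 42, n_control_sites = 2000)
  expect_equal(st1$sites, st2$sites)
  expect_equal(st1$truth, st2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_study(st1, d1); write_study(st2, d2)
  f1 <- file.path(d1, "reports", "WT_leaf_r1.CX_report.txt")
  f2 <- file.path(d2, "reports", "WT_leaf_r1.CX_report.txt")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("study bookkeeping: manifest cells, replicates, truth labels", {
  g <- small_genome(seed = 51)
  reg <- methylation_regime("regeneration")
  st <- simulate_study(g, reg, genotypes = c("WT", "mutant"),
                       replicates = c(leaf = 2, callus = 2, shoot = 2),
                       seed = 52, n_control_sites = 1000)
  expect_equal(nrow(st$manifest), 12L)
  expect_setequal(unique(st$truth$comparison_label),
                  c("c", "s", "dme:leaf", "dme:callus", "dme:shoot"))
  # WT-only, 3 stages x 3 replicates -> 9 samples
  st9 <- simulate_study(g, reg, genotypes = "WT",
                        replicates = c(leaf = 3, callus = 3, shoot = 3),
                        seed = 53, n_control_sites = 1000)
  expect_equal(nrow(st9$manifest), 9L)
  expect_equal(length(st9$sites), 9L)
})

test_that("truth flags are derivable from the regime alone (double entry)", {
  st <- simulate_reference_scenario(seed = 7, n_spike = 40, replicates = 2)
  # independent recomputation: a window is differential iff its sites sit
  # in a spiked window of the realised regime
  spikes <- st$regime$spikes
  truth <- st$truth[context == "CHH"]
  expect_equal(sum(truth$differential), nrow(spikes))
  flagged <- truth[differential == TRUE, paste(chrom, start)]
  expect_setequal(flagged, spikes[, paste(chrom, start)])
  # spiked windows carry |true delta| equal to the spike size
  expect_equal(abs(truth[differential == TRUE, true_delta]),
               rep(0.5, nrow(spikes)), tolerance = 1e-12)
  # and both directions are represented
  expect_equal(sum(truth[differential == TRUE, true_delta] > 0), 20L)
})

test_that("regime monotonicity propagates to estimated levels", {
  g <- small_genome(seed = 61)
  reg <- methylation_regime("regeneration", depth_mean = 50)
  reg <- realize_regime(g, reg, seed = 62)
  lv <- function(stage) {
    s <- simulate_sample(g, reg, stage, "WT", seed = 63)
    w <- compute_window_levels(s, g$chrom_sizes)
    average_level(w, g$annotation, "TE", context = "CHH")$mean
  }
  expect_lt(lv("callus"), lv("leaf"))
  expect_lt(lv("callus"), lv("shoot"))
})

test_that("recovery scoring handles the trivial and empty cases", {
  truth <- data.table::data.table(
    chrom = "Chr1", start = seq(0L, 450L, 50L), end = seq(50L, 500L, 50L),
    context = "CHH", comparison_label = "c",
    true_delta = c(rep(0.5, 3), rep(0, 7)),
    differential = c(rep(TRUE, 3), rep(FALSE, 7)))
  calls <- data.table::data.table(
    chrom = "Chr1", start = c(0L, 50L, 100L), end = c(50L, 100L, 150L),
    context = "CHH", direction = "hyper")
  sc <- score_recovery(calls, truth, comparison = "c")
  expect_equal(sc$sensitivity, 1.0)
  expect_equal(sc$fdr, 0.0)
  expect_warning(sc0 <- score_recovery(calls[0], truth, "c"), "empty call")
  expect_equal(sc0$sensitivity, 0.0)
  expect_true(is.na(sc0$fdr))
  # a call outside the truth tiling is a structural error
  off <- data.table::copy(calls)[, chrom := "Chr9"]
  expect_error(score_recovery(off, truth, "c"), "tiling")
})
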