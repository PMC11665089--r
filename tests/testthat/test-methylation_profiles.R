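# sites at every position of a span, constant coverage, given ratio
dense_sites <- function(chrom, from, to, ratio, ctx = "CHH", cov = 10L) {
  n <- to - from + 1L
  data.table::data.table(
    chrom = chrom, pos = from:to, strand = "+",
    count_meth = as.integer(round(ratio * cov)),
    count_unmeth = as.integer(cov - round(ratio * cov)), context = ctx)
}

test_that("a uniform methylome yields a flat profile at the true level", {
  feats <- data.table::data.table(chrom = "ChrP", start = c(3000L, 9000L),
                                  end = c(5000L, 12000L),
                                  strand = c("+", "-"))
  sites <- dense_sites("ChrP", 1L, 15000L, 0.3)
  prof <- meta_profile(sites, feats, profile_params())
  expect_equal(nrow(prof), 10 + 20 + 10)
  expect_true(all(abs(prof$mean_level - 0.3) < 1e-12))
  expect_true(all(prof$n_sites > 0))
})

test_that("sites map to the right zones and bins", {
  feats <- data.table::data.table(chrom = "ChrP", start = 2000L, end = 4000L,
                                  strand = "+")
  p <- profile_params(n_body_bins = 20, flank_bp = 2000, n_flank_bins = 10)
  # a site only in the first body fraction: body bin 1 = overall bin 11
  s1 <- dense_sites("ChrP", 2001L, 2050L, 0.8)
  prof1 <- meta_profile(s1, feats, p)
  expect_equal(prof1[!is.na(mean_level), bin_index], 11L)
  # a site 1 bp upstream lands in the last upstream bin (bin 10)
  s2 <- dense_sites("ChrP", 2000L, 2000L, 0.5)
  prof2 <- meta_profile(s2, feats, p)
  expect_equal(prof2[!is.na(mean_level), bin_index], 10L)
  # a site just past the end lands in the first downstream bin (bin 31)
  s3 <- dense_sites("ChrP", 4001L, 4001L, 0.5)
  prof3 <- meta_profile(s3, feats, p)
  expect_equal(prof3[!is.na(mean_level), bin_index], 31L)
})

test_that("reversing a feature's strand reverses the bin vector exactly", {
  set.seed(23)
  feats_p <- data.table::data.table(chrom = "ChrP", start = 5000L, end = 7000L,
                                    strand = "+")
  feats_m <- data.table::copy(feats_p)[, strand := "-"]
  n <- 800
  pos <- sort(sample(3000:9000, n))
  sites <- data.table::data.table(
    chrom = "ChrP", pos = pos, strand = "+",
    count_meth = rbinom(n, 20, runif(n)), count_unmeth = 0L, context = "CG")
  sites[, count_unmeth := as.integer(20L - count_meth)]
  pp <- profile_params(n_body_bins = 10, flank_bp = 1000, n_flank_bins = 5)
  fwd <- meta_profile(sites, feats_p, pp)
  rev <- meta_profile(sites, feats_m, pp)
  expect_equal(fwd$mean_level, base::rev(rev$mean_level))
  expect_equal(fwd$n_sites, base::rev(rev$n_sites))
})

test_that("profiles are invariant to feature order and record chunking", {
  set.seed(24)
  feats <- data.table::data.table(
    chrom = "ChrP", start = c(1000L, 4000L, 8000L),
    end = c(2500L, 6000L, 9500L), strand = c("+", "-", "+"))
  sites <- make_random_sites(2000, c(ChrP = 12000), seed = 25)
  pp <- profile_params(n_body_bins = 8, flank_bp = 500, n_flank_bins = 4)
  p1 <- meta_profile(sites, feats, pp, context = "CG")
  p2 <- meta_profile(sites[sample.int(nrow(sites))],
                     feats[c(3, 1, 2)], pp, context = "CG")
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("zero flank gives a pure body profile and short features skip", {
  feats <- data.table::data.table(chrom = "ChrP", start = c(2000L, 5000L),
                                  end = c(4000L, 5004L), strand = "+")
  sites <- dense_sites("ChrP", 1L, 6000L, 0.4)
  pp <- profile_params(n_body_bins = 10, flank_bp = 0)
  prof <- meta_profile(sites, feats, pp)
  expect_equal(nrow(prof), 10L)
  expect_true(all(prof$zone == "body"))
  expect_equal(attr(prof, "n_features_skipped"), 1L)  # 4 bp < 10 bins
  expect_equal(attr(prof, "n_features_used"), 1L)
})

test_that("generator body/flank contrast is recovered within tolerance", {
  set.seed(26)
  n_feat <- 50
  starts <- seq(2000L, by = 4000L, length.out = n_feat)
  feats <- data.table::data.table(chrom = "ChrP", start = starts,
                                  end = starts + 1500L,
                                  strand = sample(c("+", "-"), n_feat, TRUE))
  cs <- max(feats$end) + 3000L
  # body CHH 0.15, flank 0.05, depth 30: binomial read noise only
  all_pos <- sort(sample.int(cs, 60000))
  body_hit <- rep(FALSE, length(all_pos))
  for (i in seq_len(n_feat)) {
    body_hit <- body_hit | (all_pos > feats$start[i] & all_pos <= feats$end[i])
  }
  mu <- ifelse(body_hit, 0.15, 0.05)
  meth <- rbinom(length(all_pos), 30, mu)
  sites <- data.table::data.table(
    chrom = "ChrP", pos = all_pos, strand = "+",
    count_meth = as.integer(meth), count_unmeth = as.integer(30 - meth),
    context = "CHH")
  prof <- meta_profile(sites, feats, profile_params(n_body_bins = 10,
                                                    flank_bp = 1000,
                                                    n_flank_bins = 5))
  expect_true(all(abs(prof[zone == "body", mean_level] - 0.15) < 0.02))
  expect_true(all(abs(prof[zone != "body", mean_level] - 0.05) < 0.02))
})

test_that("stage profiles pool replicates idempotently", {
  sites <- make_random_sites(1500, c(ChrP = 10000), seed = 27)
  feats <- data.table::data.table(chrom = "ChrP", start = c(1000L, 6000L),
                                  end = c(3000L, 8000L), strand = c("+", "-"))
  m <- sample_manifest(c("r1", "r2"), c("WT", "WT"), c("leaf", "leaf"),
                       replicate_index = 1:2)
  # identical replicate inputs: pooled profile equals single-replicate one
  by_stage <- profile_by_stage(m, list(r1 = sites, r2 = sites), feats,
                               profile_params(n_body_bins = 6, flank_bp = 500,
                                              n_flank_bins = 2))
  single <- meta_profile(sites, feats,
                         profile_params(n_body_bins = 6, flank_bp = 500,
                                        n_flank_bins = 2), context = "CG")
  expect_equal(by_stage[stage == "leaf" & context == "CG", mean_level],
               single$mean_level)
  # a context with no qualifying sites warns and comes back undefined
  no_chh <- sites[context != "CHH"]
  expect_warning(
    prof2 <- profile_by_stage(m, list(r1 = no_chh, r2 = no_chh), feats,
                              profile_params(n_body_bins = 6, flank_bp = 500,
                                             n_flank_bins = 2)),
    "no qualifying CHH")
  expect_true(all(is.na(prof2[context == "CHH", mean_level])))
})
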