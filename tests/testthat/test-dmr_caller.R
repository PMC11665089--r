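test_that("exact count test matches enumeration and fisher.test oracles", {
  # hand-derived extreme table: p = 2 / C(20, 10)
  expect_equal(exact_count_test(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # balanced table is the null mode: p = 1
  expect_equal(exact_count_test(5, 5, 5, 5), 1)
  # both groups empty -> NA
  expect_true(is.na(exact_count_test(0, 0, 0, 0)))

  # random tables against stats::fisher.test (independent implementation)
  set.seed(1)
  tabs <- matrix(sample.int(31, 4 * 300, replace = TRUE) - 1L, ncol = 4)
  tabs <- tabs[rowSums(tabs) > 0, ]
  p_pkg <- exact_count_test(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  p_ref <- apply(tabs, 1, function(r) {
    stats::fisher.test(matrix(r, 2, 2, byrow = TRUE))$p.value
  })
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("BH adjustment equals the direct step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample.int(200, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("effect gate thresholds at a multiple of the population SD", {
  set.seed(3)
  deltas <- rnorm(1000, 0, 0.1)
  g <- effect_size_gate(deltas, 1)
  pop_sd <- sqrt(mean((deltas - mean(deltas))^2))
  expect_equal(g$threshold, pop_sd)
  expect_equal(g$mask, abs(deltas) > pop_sd)
  # a small delta fails, a large one passes
  d2 <- c(rnorm(500, 0, 0.1), 0.05, 0.40)
  g2 <- effect_size_gate(d2, 1)
  expect_false(g2$mask[501])
  expect_true(g2$mask[502])
  # degenerate distribution: SD 0, strict inequality, no window passes
  g3 <- effect_size_gate(rep(0.2, 50), 1)
  expect_equal(g3$threshold, 0)
  expect_false(any(g3$mask))
  expect_warning(effect_size_gate(0.1), "fewer than 2")
})

# compact deterministic two-group window fixture used by the call tests
make_group_fixture <- function(n_win = 400, reps = 3, delta_at = integer(0),
                               delta = 0.4, base = 0.3, depth = 60,
                               seed = 11, context = "CG") {
  set.seed(seed)
  mk_rep <- function(mu) {
    meth <- rbinom(n_win, depth, mu)
    data.table::data.table(
      chrom = "ChrF", start = seq(0L, by = 50L, length.out = n_win),
      end = seq(50L, by = 50L, length.out = n_win), context = context,
      n_sites = 3L, meth_reads = as.integer(meth),
      unmeth_reads = as.integer(depth - meth),
      level = meth / depth, level_pooled = meth / depth, qualified = TRUE)
  }
  mu_a <- rep(base, n_win)
  mu_b <- rep(base, n_win); mu_b[delta_at] <- base + delta
  list(a = lapply(seq_len(reps), function(i) mk_rep(mu_a)),
       b = lapply(seq_len(reps), function(i) mk_rep(mu_b)))
}

test_that("call_dmrs applies the double gate and labels directions", {
  fx <- make_group_fixture(delta_at = 1:20, seed = 21)
  res <- call_dmrs(fx$a, fx$b, dmr_params(), "c")
  expect_s3_class(res, "dmr_result")
  # spiked windows dominate the calls and are hyper (B gained)
  expect_gt(nrow(res$calls), 10)
  expect_true(all(res$calls$direction[res$calls$start < 1000] == "hyper"))
  expect_true(all(res$calls$q < 0.05))
  expect_true(all(abs(res$calls$delta) > res$threshold[["CG"]]))
  # hyper and hypo partition the calls
  expect_true(all(res$calls$direction %in% c("hyper", "hypo")))
  # a significant q alone is not enough: gate failures are not called
  tested <- res$tested
  expect_true(all(tested[called == TRUE, gate]))
})

test_that("only jointly qualified windows are tested", {
  fx <- make_group_fixture(n_win = 50, seed = 31)
  fx$a[[2]]$qualified[1:10] <- FALSE
  res <- call_dmrs(fx$a, fx$b, dmr_params(), "x")
  expect_equal(res$diagnostics$n_tested, 40L)
  expect_equal(res$diagnostics$n_lost_joint_qualification, 10L)
  expect_false(any(res$tested$start < 500))
})

test_that("swapping groups negates deltas and swaps hyper/hypo exactly", {
  fx <- make_group_fixture(delta_at = c(1:10, 390:400), seed = 41)
  ab <- call_dmrs(fx$a, fx$b, dmr_params(), "fwd")
  ba <- call_dmrs(fx$b, fx$a, dmr_params(), "rev")
  expect_equal(ab$tested$delta, -ba$tested$delta)
  expect_equal(ab$tested$p, ba$tested$p)
  expect_equal(ab$tested$q, ba$tested$q)
  key <- function(d) paste(d$chrom, d$start, d$context)
  expect_setequal(key(ab$calls[direction == "hyper"]),
                  key(ba$calls[direction == "hypo"]))
  expect_setequal(key(ab$calls[direction == "hypo"]),
                  key(ba$calls[direction == "hyper"]))
})

test_that("call counts are monotone in q threshold and SD multiplier", {
  fx <- make_group_fixture(delta_at = 1:30, seed = 51)
  n_calls <- function(q, m) {
    nrow(call_dmrs(fx$a, fx$b, dmr_params(q_threshold = q,
                                          effect_sd_multiplier = m), "x")$calls)
  }
  expect_gte(n_calls(0.05, 1), n_calls(0.01, 1))
  expect_gte(n_calls(0.01, 1), n_calls(0.001, 1))
  expect_gte(n_calls(0.05, 1), n_calls(0.05, 2))
  expect_gte(n_calls(0.05, 2), n_calls(0.05, 4))
})

test_that("the per-replicate regression test agrees directionally", {
  fx <- make_group_fixture(n_win = 120, delta_at = 1:10, seed = 61, depth = 80)
  res <- call_dmrs(fx$a, fx$b,
                   dmr_params(test = "per_replicate_regression"), "x")
  expect_true(all(res$tested$p >= 0 & res$tested$p <= 1, na.rm = TRUE))
  # spiked windows get small p, null windows mostly do not
  expect_lt(median(res$tested[start < 500, p]), 1e-4)
  expect_gt(median(res$tested[start >= 500, p]), 0.05)
})

test_that("stage_comparisons produces the configured comparison labels", {
  cs <- c(ChrT = 2000)
  mk <- function(seed) compute_window_levels(make_random_sites(500, cs, seed), cs)
  ids <- c("wl1", "wl2", "wc1", "wc2", "ws1", "ws2", "ml1", "mc1", "ms1")
  m <- sample_manifest(
    ids,
    genotype = c(rep("WT", 6), rep("mutant", 3)),
    stage = c("leaf", "leaf", "callus", "callus", "shoot", "shoot",
              "leaf", "callus", "shoot"),
    replicate_index = c(1, 2, 1, 2, 1, 2, 1, 1, 1))
  ws <- setNames(lapply(seq_along(ids), function(i) mk(i)), ids)
  res <- suppressWarnings(stage_comparisons(m, ws, dmr_params()))
  expect_setequal(names(res),
                  c("c", "s", "dme:leaf", "dme:callus", "dme:shoot"))
  # WT-only manifest: only the two stage comparisons
  m_wt <- m[genotype == "WT"]
  res_wt <- suppressWarnings(stage_comparisons(m_wt, ws[m_wt$sample_id]))
  expect_setequal(names(res_wt), c("c", "s"))
  # missing groups are a configuration error
  expect_error(stage_comparisons(m[stage == "leaf" & genotype == "mutant"],
                                 ws["ml1"]), "no comparable")
})
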