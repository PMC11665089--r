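#' DMR-calling parameters
#'
#' @param q_threshold q-value cutoff; a window is called only when
#'   `q < q_threshold` (strict).
#' @param effect_sd_multiplier the effect gate: `|delta|` must exceed
#'   `effect_sd_multiplier` times the population SD of the per-window
#'   methylation differences of the same context and comparison.
#' @param test `"pooled_exact"` (two-sided exact test on replicate-pooled
#'   counts, default) or `"per_replicate_regression"` (binomial GLM across
#'   replicates, likelihood-ratio p-value).
#' @param adjustment multiple-testing adjustment; only `"BH"`.
#' @return list of class `dmr_params`.
#' @export
dmr_params <- function(q_threshold = 0.05, effect_sd_multiplier = 1,
                       test = c("pooled_exact", "per_replicate_regression"),
                       adjustment = "BH") {
  test <- match.arg(test)
  if (!(q_threshold > 0 && q_threshold < 1)) stop("q_threshold must be in (0, 1)")
  if (effect_sd_multiplier <= 0) stop("effect_sd_multiplier must be positive")
  if (!identical(adjustment, "BH")) stop("only BH adjustment is supported")
  structure(list(q_threshold = q_threshold,
                 effect_sd_multiplier = effect_sd_multiplier,
                 test = test, adjustment = adjustment),
            class = "dmr_params")
}

#' Two-sided exact test on pooled methylation counts
#'
#' Vectorised two-sided Fisher exact p-value for the 2x2 table
#' `[[meth_a, unmeth_a], [meth_b, unmeth_b]]`: under the hypergeometric
#' null, all tables with the observed margins whose probability does not
#' exceed the observed table's probability (within a relative tolerance of
#' 1e-7, the usual convention) are summed.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b non-negative integer vectors
#'   (recycled to common length).
#' @return p-value vector; `NA` where both groups have zero coverage.
#' @export
exact_count_test <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- max(length(meth_a), length(unmeth_a), length(meth_b), length(unmeth_b))
  ma <- rep_len(as.numeric(meth_a), n); ua <- rep_len(as.numeric(unmeth_a), n)
  mb <- rep_len(as.numeric(meth_b), n); ub <- rep_len(as.numeric(unmeth_b), n)
  if (any(c(ma, ua, mb, ub) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  na <- ma + ua          # group A coverage (first row margin)
  k  <- ma + mb          # total methylated calls (first column margin)
  tot <- na + mb + ub
  p <- vapply(seq_len(n), function(i) {
    if (tot[i] == 0) return(NA_real_)
    lo <- max(0, k[i] - (tot[i] - na[i]))
    hi <- min(k[i], na[i])
    d <- dhyper(lo:hi, k[i], tot[i] - k[i], na[i])
    obs <- d[ma[i] - lo + 1]
    sum(d[d <= obs * (1 + 1e-7)])
  }, numeric(1))
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values; a thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p p-value vector, all in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Effect-size gate on per-window methylation differences
#'
#' The gate threshold is `multiplier` times the population standard
#' deviation (denominator n) of the deltas of all tested windows of one
#' context and comparison; a window passes when `|delta|` strictly exceeds
#' it. A degenerate delta distribution (zero SD) carries no scale to gate
#' against, so no window passes.
#'
#' @param deltas per-window level differences (group B minus group A).
#' @param multiplier SD multiplier (1 = one standard deviation).
#' @return list with `threshold`, `mask` (logical), `sd` and `mean_delta`;
#'   `NULL` threshold with a warning when fewer than two deltas are given.
#' @export
effect_size_gate <- function(deltas, multiplier = 1) {
  stopifnot(multiplier > 0)
  d <- deltas[!is.na(deltas)]
  if (length(d) < 2L) {
    warning("effect_size_gate: fewer than 2 deltas; gate undefined")
    return(list(threshold = NA_real_, mask = rep(FALSE, length(deltas)),
                sd = NA_real_, mean_delta = NA_real_))
  }
  pop_sd <- sqrt(mean((d - mean(d))^2))
  thr <- multiplier * pop_sd
  mask <- if (pop_sd == 0) rep(FALSE, length(deltas)) else
    !is.na(deltas) & abs(deltas) > thr
  list(threshold = thr, mask = mask, sd = pop_sd, mean_delta = mean(d))
}

# per-window binomial GLM across replicates; LRT p-value.
# counts: data.table with meth, unmeth, group (factor) rows = replicates
.regression_test_one <- function(meth, unmeth, group) {
  keep <- (meth + unmeth) > 0
  if (sum(keep) < 2L || length(unique(group[keep])) < 2L) return(NA_real_)
  fit1 <- try(stats::glm(cbind(meth, unmeth) ~ group, family = stats::binomial,
                         subset = keep), silent = TRUE)
  if (inherits(fit1, "try-error")) return(NA_real_)
  fit0 <- stats::glm(cbind(meth, unmeth) ~ 1, family = stats::binomial,
                     subset = keep)
  stats::pchisq(fit0$deviance - fit1$deviance, df = 1, lower.tail = FALSE)
}

#' Call differentially methylated windows between two groups
#'
#' Only windows jointly qualified in every replicate of both groups are
#' tested. Per tested window the difference `delta` is the mean of
#' per-replicate window levels in group B minus group A; the p-value comes
#' from the exact test on replicate-pooled counts (or the per-replicate
#' regression); q-values are BH-adjusted within each context; and a window
#' is called a DMR when `|delta|` strictly exceeds the effect gate
#' threshold AND `q < q_threshold`. Calls are labelled hyper (`delta > 0`,
#' B gained methylation relative to A) or hypo.
#'
#' @param group_a,group_b named lists of per-replicate window tables
#'   (identical tiling), e.g. from [compute_window_levels()].
#' @param params a [dmr_params()] object.
#' @param comparison_label label stored on every call (e.g. `"c"` for
#'   leaf-to-callus, `"s"` for callus-to-shoot, `"dme:shoot"`).
#' @return list of class `dmr_result`: `calls` (the DMRs), `tested` (all
#'   tested windows with delta/p/q), `threshold` (per-context gate
#'   thresholds), `params`, `diagnostics` (window counts lost per filter).
#' @export
call_dmrs <- function(group_a, group_b, params = dmr_params(),
                      comparison_label = "comparison") {
  stopifnot(inherits(params, "dmr_params"),
            length(group_a) >= 1, length(group_b) >= 1)
  all_tabs <- c(group_a, group_b)
  key <- .check_tiling(all_tabs)

  qual <- Reduce(`&`, lapply(all_tabs, function(t) t$qualified))
  tested <- copy(key)[, tested := qual]
  n_total <- nrow(key)

  lev_a <- rowMeans(do.call(cbind, lapply(group_a, `[[`, "level")))
  lev_b <- rowMeans(do.call(cbind, lapply(group_b, `[[`, "level")))
  ma <- Reduce(`+`, lapply(group_a, `[[`, "meth_reads"))
  ua <- Reduce(`+`, lapply(group_a, `[[`, "unmeth_reads"))
  mb <- Reduce(`+`, lapply(group_b, `[[`, "meth_reads"))
  ub <- Reduce(`+`, lapply(group_b, `[[`, "unmeth_reads"))

  tt <- cbind(tested, level_a = lev_a, level_b = lev_b,
              meth_a = ma, unmeth_a = ua, meth_b = mb, unmeth_b = ub)
  tt <- tt[tested == TRUE][, tested := NULL]
  if (nrow(tt) == 0L) {
    warning("call_dmrs: no jointly qualified windows",
            sprintf(" (%d windows before joint qualification)", n_total))
    return(structure(list(calls = data.table(), tested = tt,
                          threshold = numeric(0), params = params,
                          diagnostics = list(n_windows = n_total, n_tested = 0L)),
                     class = "dmr_result"))
  }
  tt[, delta := level_b - level_a]

  if (params$test == "pooled_exact") {
    tt[, p := exact_count_test(meth_a, unmeth_a, meth_b, unmeth_b)]
  } else {
    grp <- factor(c(rep("A", length(group_a)), rep("B", length(group_b))))
    meth_mat <- do.call(cbind, lapply(all_tabs, `[[`, "meth_reads"))
    unmeth_mat <- do.call(cbind, lapply(all_tabs, `[[`, "unmeth_reads"))
    idx <- which(qual)
    tt[, p := vapply(seq_len(.N), function(j) {
      i <- idx[j]
      .regression_test_one(meth_mat[i, ], unmeth_mat[i, ], grp)
    }, numeric(1))]
  }

  # BH and the SD gate are each applied within one context
  tt[, q := NA_real_]
  thresholds <- c()
  tt[, gate := FALSE]
  for (ctx in unique(tt$context)) {
    i <- which(tt$context == ctx & !is.na(tt$p))
    if (length(i) == 0L) next
    tt$q[i] <- bh_adjust(tt$p[i])
    g <- effect_size_gate(tt$delta[i], params$effect_sd_multiplier)
    thresholds[ctx] <- g$threshold
    tt$gate[i] <- g$mask
  }

  tt[, called := gate & !is.na(q) & q < params$q_threshold & delta != 0]
  tt[, direction := fifelse(delta > 0, "hyper", "hypo")]
  calls <- tt[called == TRUE,
              .(chrom, start, end, context, comparison_label = comparison_label,
                delta, p, q, direction,
                sd_threshold = thresholds[context])]
  setorder(calls, context, chrom, start)

  structure(list(
    calls = calls,
    tested = tt[, .(chrom, start, end, context, level_a, level_b, delta, p, q,
                    gate, called, direction)],
    threshold = thresholds,
    params = params,
    comparison_label = comparison_label,
    diagnostics = list(n_windows = n_total, n_tested = nrow(tt),
                       n_lost_joint_qualification = n_total - nrow(tt),
                       n_called = nrow(calls))),
    class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("DMR result '%s': %d/%d windows tested, %d called\n",
              x$comparison_label %||% "?", x$diagnostics$n_tested,
              x$diagnostics$n_windows, x$diagnostics$n_called))
  if (nrow(x$calls)) {
    tab <- x$calls[, .N, by = .(context, direction)]
    tab <- dcast(tab, context ~ direction, value.var = "N", fill = 0L)
    print(tab)
  }
  invisible(x)
}

#' Summarise hyper/hypo call counts per context
#'
#' The per-comparison tabulation of call counts by context and direction
#' (the shape of a stage-DMR bar chart).
#'
#' @param result a `dmr_result` or a list of them.
#' @return long `data.table`: comparison_label, context, direction, n.
#' @export
dmr_count_summary <- function(result) {
  results <- if (inherits(result, "dmr_result")) list(result) else result
  out <- rbindlist(lapply(results, function(r) {
    grid <- CJ(context = .CONTEXTS, direction = c("hyper", "hypo"))
    cnt <- if (nrow(r$calls)) r$calls[, .N, by = .(context, direction)] else
      data.table(context = character(), direction = character(), N = integer())
    g <- cnt[grid, on = .(context, direction)]
    g[is.na(N), N := 0L]
    g[, .(comparison_label = r$comparison_label %||% "?", context, direction, n = N)]
  }))
  out[]
}

#' Run the study's stage and genotype comparisons
#'
#' Within the wild type: leaf-to-callus (label `"c"`) and callus-to-shoot
#' (label `"s"`). Between genotypes: WT vs mutant at every stage where both
#' are present (labels `"dme:<stage>"`). Each comparison is a [call_dmrs()]
#' run over the replicates of the two groups.
#'
#' @param manifest a [sample_manifest()].
#' @param windows_by_sample named list of window tables keyed by sample_id.
#' @param params a [dmr_params()].
#' @return named list of `dmr_result` objects keyed by comparison label.
#' @export
stage_comparisons <- function(manifest, windows_by_sample, params = dmr_params()) {
  stopifnot(all(manifest$sample_id %in% names(windows_by_sample)))
  pick <- function(g, s) {
    ids <- manifest[genotype == g & stage == s, sample_id]
    windows_by_sample[ids]
  }
  have <- function(g, s) nrow(manifest[genotype == g & stage == s]) > 0
  results <- list()
  if (have("WT", "leaf") && have("WT", "callus")) {
    results[["c"]] <- call_dmrs(pick("WT", "leaf"), pick("WT", "callus"),
                                params, comparison_label = "c")
  }
  if (have("WT", "callus") && have("WT", "shoot")) {
    results[["s"]] <- call_dmrs(pick("WT", "callus"), pick("WT", "shoot"),
                                params, comparison_label = "s")
  }
  for (st in c("leaf", "callus", "shoot")) {
    if (have("WT", st) && have("mutant", st)) {
      lab <- paste0("dme:", st)
      results[[lab]] <- call_dmrs(pick("WT", st), pick("mutant", st),
                                  params, comparison_label = lab)
    }
  }
  if (length(results) == 0L) {
    stop("manifest provides no comparable (genotype, stage) groups")
  }
  results
}
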