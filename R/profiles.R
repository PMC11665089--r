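#' Meta-profile parameters
#'
#' @param n_body_bins equal body fractions per feature (default 20).
#' @param flank_bp flanking width on each side, bp (default 2000).
#' @param n_flank_bins fixed-width bins per flank (default 10); ignored
#'   when `flank_bp = 0`.
#' @param min_reads_per_cytosine coverage floor for a site's ratio to be
#'   used.
#' @return list of class `profile_params`.
#' @export
profile_params <- function(n_body_bins = 20L, flank_bp = 2000L,
                           n_flank_bins = 10L, min_reads_per_cytosine = 5L) {
  if (n_body_bins < 1L) stop("n_body_bins must be >= 1")
  if (flank_bp < 0L) stop("flank_bp must be >= 0")
  if (flank_bp > 0L && n_flank_bins < 1L) stop("n_flank_bins must be >= 1")
  structure(list(n_body_bins = as.integer(n_body_bins),
                 flank_bp = as.integer(flank_bp),
                 n_flank_bins = if (flank_bp > 0L) as.integer(n_flank_bins) else 0L,
                 min_reads_per_cytosine = as.integer(min_reads_per_cytosine)),
            class = "profile_params")
}

#' Meta-feature methylation profile
#'
#' Average methylation across scaled feature bodies plus fixed flanks: each
#' feature's body is divided into `n_body_bins` equal fractions and each
#' flank into `n_flank_bins` fixed-width bins; qualifying sites (coverage at
#' or above the read floor) are assigned to bins — mirrored for minus-strand
#' features so bin order is always 5' to 3' — and each bin's mean is the
#' unweighted mean of per-site ratios pooled over all features. A site
#' under several (possibly overlapping) features contributes to each.
#' Features shorter than `n_body_bins` bp are skipped; the skip count is
#' reported as an attribute.
#'
#' @param sites cytosine records (one context, or pre-filtered via
#'   `context`).
#' @param features interval table with `chrom`, `start`, `end` and
#'   optionally `strand` (unstranded features are treated as `+`).
#' @param params a [profile_params()].
#' @param context optional context filter applied to `sites`.
#' @return `data.table` with `bin_index` (1..n_flank+n_body+n_flank, 5'→3'),
#'   `zone` (`up`/`body`/`down`), `mean_level`, `n_sites`; bins with no
#'   sites have `NA` mean. Attributes: `n_features_used`,
#'   `n_features_skipped`.
#' @export
meta_profile <- function(sites, features, params = profile_params(),
                         context = NULL) {
  stopifnot(inherits(params, "profile_params"))
  ctx_keep <- context
  s <- as.data.table(sites)
  if (!is.null(ctx_keep)) s <- s[context %chin% ctx_keep]
  nf <- params$n_flank_bins; nb <- params$n_body_bins
  fl <- params$flank_bp
  n_bins <- nb + 2L * nf
  zones <- c(rep("up", nf), rep("body", nb), rep("down", nf))
  skeleton <- data.table(bin_index = seq_len(n_bins), zone = zones)

  feats <- as.data.table(features)
  if (!"strand" %in% names(feats)) feats[, strand := "+"]
  feats[!(strand %chin% c("+", "-")), strand := "+"]
  short <- (feats$end - feats$start) < nb
  n_skip <- sum(short)
  feats <- feats[!short]
  empty <- function() {
    out <- copy(skeleton)[, `:=`(mean_level = NA_real_, n_sites = 0L)]
    setattr(out, "n_features_used", nrow(feats))
    setattr(out, "n_features_skipped", n_skip)
    out
  }
  if (nrow(feats) == 0L || nrow(s) == 0L) {
    warning("meta_profile: no usable features or sites")
    return(empty())
  }

  s[, `:=`(cov = count_meth + count_unmeth)]
  s <- s[cov >= params$min_reads_per_cytosine]
  if (nrow(s) == 0L) {
    warning("meta_profile: no qualifying sites")
    return(empty())
  }
  s[, `:=`(p0 = pos - 1L, ratio = count_meth / cov)]

  # overlap join of sites against flank-extended features
  fx <- feats[, .(chrom, fs = start, fe = end, fstrand = strand,
                  s1 = start - fl, e1 = end + fl)]
  setkey(fx, chrom, s1, e1)
  sq <- s[, .(chrom, s1 = p0, e1 = p0 + 1L, ratio)]
  ov <- foverlaps(sq, fx, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) {
    warning("meta_profile: no sites overlap any feature window")
    return(empty())
  }
  x <- ov$i.s1                       # site 0-based position
  # mirror minus-strand features so the shared arithmetic is 5'->3'
  minus <- ov$fstrand == "-"
  x[minus] <- ov$fs[minus] + ov$fe[minus] - 1L - x[minus]
  st <- ov$fs; en <- ov$fe
  len <- en - st
  bin <- integer(length(x))
  up <- x < st
  dn <- x >= en
  body <- !up & !dn
  if (nf > 0L) {
    fw <- fl / nf
    d_up <- st[up] - x[up]                       # 1..fl
    bin[up] <- nf - as.integer(ceiling(d_up / fw)) + 1L
    d_dn <- x[dn] - en[dn]                       # 0..fl-1
    bin[dn] <- nf + nb + as.integer(floor(d_dn / fw)) + 1L
  }
  bin[body] <- nf + pmin(nb, as.integer(floor((x[body] - st[body]) / len[body] * nb)) + 1L)
  keep <- bin >= 1L & bin <= n_bins              # drops flank sites when fl = 0
  agg <- data.table(bin_index = bin[keep], ratio = ov$ratio[keep])[
    , .(mean_level = mean(ratio), n_sites = .N), by = bin_index]
  out <- agg[skeleton, on = "bin_index"]
  out[is.na(n_sites), n_sites := 0L]
  setcolorder(out, c("bin_index", "zone", "mean_level", "n_sites"))
  setorder(out, bin_index)
  setattr(out, "n_features_used", nrow(feats))
  setattr(out, "n_features_skipped", n_skip)
  out[]
}

#' Stage-wise meta-profiles
#'
#' One profile per (stage, context), with replicates pooled at the site
#' level (every replicate's qualifying sites enter the bin means).
#'
#' @param manifest a [sample_manifest()].
#' @param sites_by_sample named list of cytosine record tables keyed by
#'   sample_id.
#' @param features feature interval table (see [meta_profile()]).
#' @param params a [profile_params()].
#' @param genotype genotype to profile (default `"WT"`).
#' @param contexts contexts to profile.
#' @return long `data.table`: stage, genotype, context, bin_index, zone,
#'   mean_level, n_sites.
#' @export
profile_by_stage <- function(manifest, sites_by_sample, features,
                             params = profile_params(), genotype = "WT",
                             contexts = .CONTEXTS) {
  gt <- genotype
  m <- manifest[genotype == gt]
  if (nrow(m) == 0L) stop("no samples for genotype '", gt, "' in manifest")
  out <- list()
  for (st in unique(m$stage)) {
    ids <- m[stage == st, sample_id]
    missing <- setdiff(ids, names(sites_by_sample))
    if (length(missing)) stop("missing site tables for: ",
                              paste(missing, collapse = ", "))
    pooled <- rbindlist(sites_by_sample[ids], use.names = TRUE)
    for (ctx in contexts) {
      prof <- withCallingHandlers(
        meta_profile(pooled, features, params, context = ctx),
        warning = function(w) invokeRestart("muffleWarning"))
      if (all(prof$n_sites == 0L)) {
        warning(sprintf("profile_by_stage: no qualifying %s sites at stage %s",
                        ctx, st))
      }
      out[[length(out) + 1L]] <-
        cbind(data.table(stage = st, genotype = gt, context = ctx), prof)
    }
  }
  rbindlist(out)
}
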