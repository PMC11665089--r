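#' Windowing parameters
#'
#' Filters follow the windowed-average rule: a site qualifies when its
#' coverage reaches `min_reads_per_cytosine`, and a window qualifies for a
#' sample when it holds at least `min_cytosines_per_window` qualifying
#' sites. `read_filter = "window_total"` is an alternative reading in which
#' the read floor applies to the window's total coverage rather than each
#' cytosine; the per-site reading is canonical.
#'
#' @param window_size tile width in bp.
#' @param min_cytosines_per_window minimum qualifying cytosines per window.
#' @param min_reads_per_cytosine minimum coverage for a site to qualify.
#' @param contexts contexts to aggregate.
#' @param read_filter `"per_site"` (default) or `"window_total"`.
#' @return a list of class `windowing_params`.
#' @export
windowing_params <- function(window_size = 50L, min_cytosines_per_window = 3L,
                             min_reads_per_cytosine = 5L,
                             contexts = .CONTEXTS,
                             read_filter = c("per_site", "window_total")) {
  read_filter <- match.arg(read_filter)
  if (window_size < 1L) stop("window_size must be >= 1")
  if (min_cytosines_per_window < 1L) stop("min_cytosines_per_window must be >= 1")
  if (min_reads_per_cytosine < 0L) stop("min_reads_per_cytosine must be >= 0")
  stopifnot(all(contexts %in% .CONTEXTS))
  structure(list(window_size = as.integer(window_size),
                 min_cytosines_per_window = as.integer(min_cytosines_per_window),
                 min_reads_per_cytosine = as.integer(min_reads_per_cytosine),
                 contexts = contexts, read_filter = read_filter),
            class = "windowing_params")
}

#' Tile a genome into fixed-width windows
#'
#' Non-overlapping tiles anchored at coordinate 0; the final tile of each
#' chromosome may be shorter than `window_size`.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param window_size tile width.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open),
#'   ordered by chromosome then start.
#' @export
tile_genome <- function(chrom_sizes, window_size = 50L) {
  if (window_size <= 0L) stop("window_size must be positive")
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("chrom_sizes must be a named vector of positive lengths")
  }
  tiles <- lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(0L, len - 1L, by = as.integer(window_size))
    data.table(chrom = ch, start = starts,
               end = pmin(starts + as.integer(window_size), len))
  })
  rbindlist(tiles)
}

#' Aggregate per-cytosine counts into windowed methylation levels
#'
#' For one sample: the per-site ratio `count_meth / coverage` is computed at
#' sites whose coverage reaches the read floor, and the window level is the
#' unweighted mean of those qualifying per-site ratios. A window qualifies
#' when it holds enough qualifying sites; unqualified windows carry an
#' undefined (`NA`) level — distinct from zero — and are excluded from all
#' downstream means and tests. The pooled-count ratio
#' (`sum meth / sum coverage` over qualifying sites) is stored alongside as
#' `level_pooled`; the per-site mean is canonical.
#'
#' @param sites cytosine records for one sample
#'   (see [read_cytosine_report()]).
#' @param chrom_sizes named chromosome lengths; every record must fall
#'   within its chromosome.
#' @param params a [windowing_params()] object.
#' @return `data.table` with one row per (tile, context in
#'   `params$contexts`): `chrom`, `start`, `end`, `context`, `n_sites`
#'   (qualifying sites), `meth_reads`, `unmeth_reads` (sums over qualifying
#'   sites), `level`, `level_pooled`, `qualified`.
#' @export
compute_window_levels <- function(sites, chrom_sizes, params = windowing_params()) {
  stopifnot(inherits(params, "windowing_params"))
  s <- as.data.table(sites)[context %chin% params$contexts]
  bad_chrom <- !(s$chrom %chin% names(chrom_sizes))
  if (any(bad_chrom)) stop("record on unknown chromosome: ", s$chrom[which(bad_chrom)[1]])
  over <- s$pos > chrom_sizes[s$chrom]
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("record position %d exceeds length of %s", s$pos[i], s$chrom[i]))
  }
  w <- as.integer(params$window_size)
  s[, `:=`(start = ((pos - 1L) %/% w) * w, cov = count_meth + count_unmeth)]
  s[, ok := cov >= params$min_reads_per_cytosine]

  agg <- s[ok == TRUE,
           .(n_sites = .N,
             meth_reads = sum(count_meth),
             unmeth_reads = sum(count_unmeth),
             level = mean(count_meth / cov),
             win_cov = sum(cov)),
           by = .(chrom, start, context)]

  tiles <- tile_genome(chrom_sizes, w)
  grid <- tiles[, .(context = params$contexts), by = .(chrom, start, end)]
  out <- agg[grid, on = .(chrom, start, context)]
  out[is.na(n_sites), `:=`(n_sites = 0L, meth_reads = 0L, unmeth_reads = 0L,
                           win_cov = 0L)]
  if (params$read_filter == "per_site") {
    out[, qualified := n_sites >= params$min_cytosines_per_window]
  } else {
    # window-total reading: count every covered site, require total reads
    n_any <- s[cov > 0, .(n_any = .N), by = .(chrom, start, context)]
    out <- n_any[out, on = .(chrom, start, context)]
    out[is.na(n_any), n_any := 0L]
    out[, qualified := n_any >= params$min_cytosines_per_window &
          win_cov >= params$min_reads_per_cytosine]
    out[, n_any := NULL]
  }
  out[, level_pooled := fifelse(qualified & (meth_reads + unmeth_reads) > 0,
                                meth_reads / (meth_reads + unmeth_reads), NA_real_)]
  out[qualified == FALSE, level := NA_real_]
  out[, win_cov := NULL]
  setcolorder(out, c("chrom", "start", "end", "context", "n_sites",
                     "meth_reads", "unmeth_reads", "level", "level_pooled",
                     "qualified"))
  setorder(out, chrom, start, context)
  out[]
}

# assert that a list of window tables shares one tiling; returns the key
.check_tiling <- function(tables) {
  key0 <- tables[[1]][, .(chrom, start, end, context)]
  for (t in tables[-1]) {
    if (!identical(key0, t[, .(chrom, start, end, context)])) {
      stop("window tables are not tiled identically across samples")
    }
  }
  key0
}

#' Joint qualification mask across samples
#'
#' A window passes only when it is qualified in every listed sample — the
#' intersection of the per-sample qualification masks.
#'
#' @param windows_by_sample named list of window tables (identical tiling).
#' @param sample_ids samples to intersect; defaults to all.
#' @return `data.table` `chrom`, `start`, `end`, `context`, `pass`.
#' @export
joint_qualify <- function(windows_by_sample, sample_ids = names(windows_by_sample)) {
  stopifnot(length(sample_ids) >= 1, all(sample_ids %in% names(windows_by_sample)))
  tabs <- windows_by_sample[sample_ids]
  key <- .check_tiling(tabs)
  pass <- Reduce(`&`, lapply(tabs, function(t) t$qualified))
  cbind(key, pass = pass)
}

#' Mean methylation level over a window set
#'
#' Unweighted mean of qualified window levels, optionally restricted to
#' windows overlapping a feature class. Returns the contributing window
#' count alongside; an empty selection yields an `NA` mean with `n = 0`
#' and a warning (never silently zero).
#'
#' @param windows a window table for one sample (or pooled).
#' @param annotation a [feature_annotation()] (required unless
#'   `region = "genome"`).
#' @param region `"genome"`, `"gene"` or `"TE"`.
#' @param context optional context restriction.
#' @return list with `mean` and `n_windows`.
#' @export
average_level <- function(windows, annotation = NULL,
                          region = c("genome", "gene", "TE"), context = NULL) {
  region <- match.arg(region)
  ctx_keep <- context
  w <- windows[qualified == TRUE & !is.na(level)]
  if (!is.null(ctx_keep)) w <- w[context %chin% ctx_keep]
  if (region != "genome") {
    if (is.null(annotation)) stop("annotation required for region = '", region, "'")
    feats <- if (region == "gene") annotation$genes else annotation$tes
    hit <- .overlaps_any(w, feats)
    w <- w[hit]
  }
  if (nrow(w) == 0L) {
    warning("average_level: no qualifying windows in selection")
    return(list(mean = NA_real_, n_windows = 0L))
  }
  list(mean = mean(w$level), n_windows = nrow(w))
}

#' Bisulfite conversion rate from an unmethylated control
#'
#' Pools all contexts of a control sequence expected to be fully
#' unmethylated (in the source study, the plastid genome) and returns
#' `sum(count_unmeth) / sum(coverage)`.
#'
#' @param control_sites cytosine records from the control sequence.
#' @return list with `rate` (in \[0,1\], `NA` when total coverage is zero)
#'   and `n_calls` (total read calls used).
#' @export
conversion_rate <- function(control_sites) {
  tot <- sum(control_sites$count_meth) + sum(control_sites$count_unmeth)
  if (tot == 0) {
    warning("conversion_rate: zero total coverage in control")
    return(list(rate = NA_real_, n_calls = 0))
  }
  list(rate = sum(control_sites$count_unmeth) / tot, n_calls = tot)
}
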