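#' Feature annotation container
#'
#' Holds gene intervals, TE intervals (with lengths) and one
#' pericentromere interval per chromosome, all 0-based half-open, queryable
#' by overlap. Interval tables need columns `chrom`, `start`, `end` and may
#' carry `strand` and `name`.
#'
#' @param genes gene interval table (or `NULL`).
#' @param tes TE interval table (or `NULL`).
#' @param pericentromeres pericentromere intervals, at most one per
#'   chromosome (or `NULL`).
#' @param chrom_sizes named chromosome lengths.
#' @return list of class `feature_annotation`.
#' @export
feature_annotation <- function(genes = NULL, tes = NULL, pericentromeres = NULL,
                               chrom_sizes) {
  norm <- function(x, kind) {
    if (is.null(x)) return(NULL)
    x <- as.data.table(x)
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    if (!"strand" %in% names(x)) x[, strand := "+"]
    if (!"name" %in% names(x)) x[, name := paste0(kind, "_", .I)]
    bad <- !(x$chrom %chin% names(chrom_sizes)) | x$start < 0 |
      x$end > chrom_sizes[x$chrom] | x$end <= x$start
    if (any(bad)) stop(kind, " interval out of chromosome bounds or empty")
    x[, length := end - start]
    x[]
  }
  peri <- norm(pericentromeres, "pericentromere")
  if (!is.null(peri) && anyDuplicated(peri$chrom)) {
    stop("more than one pericentromere interval on a chromosome")
  }
  structure(list(genes = norm(genes, "gene"), tes = norm(tes, "TE"),
                 pericentromeres = peri, chrom_sizes = chrom_sizes),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("feature_annotation: %d genes, %d TEs, %d pericentromere intervals, %d chromosomes\n",
              nrow(x$genes %||% data.table()), nrow(x$tes %||% data.table()),
              nrow(x$pericentromeres %||% data.table()), length(x$chrom_sizes)))
  invisible(x)
}

# GRanges from a 0-based half-open interval table
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
}

# logical vector: does each interval in `x` overlap any interval in `feats`?
.overlaps_any <- function(x, feats) {
  if (is.null(feats) || nrow(feats) == 0L || nrow(x) == 0L) {
    return(rep(FALSE, nrow(x)))
  }
  IRanges::overlapsAny(.as_granges(x), .as_granges(feats), ignore.strand = TRUE)
}

#' Classify windows by genomic feature overlap
#'
#' A window overlapping (by at least 1 bp) both a gene and a TE is
#' `gene&TE`; only a gene, `gene`; only a TE, `TE`; neither, `IGR`
#' (intergenic). The four classes partition any window set.
#'
#' @param windows interval table (`chrom`, `start`, `end`).
#' @param annotation a [feature_annotation()].
#' @return character vector of classes, one per window.
#' @export
classify_windows <- function(windows, annotation) {
  stopifnot(inherits(annotation, "feature_annotation"))
  if (nrow(windows) == 0L) return(character(0))
  unknown <- !(windows$chrom %chin% names(annotation$chrom_sizes))
  if (any(unknown)) stop("window on unknown chromosome: ",
                         windows$chrom[which(unknown)[1]])
  in_gene <- .overlaps_any(windows, annotation$genes)
  in_te <- .overlaps_any(windows, annotation$tes)
  fifelse(in_gene & in_te, "gene&TE",
          fifelse(in_gene, "gene", fifelse(in_te, "TE", "IGR")))
}

#' Feature composition of a window set
#'
#' Counts and fractions over the classes gene / gene&TE / TE / IGR,
#' together with the matched genome background: the classification of every
#' genome tile of the same width.
#'
#' @param window_set interval table of windows or DMR calls.
#' @param annotation a [feature_annotation()].
#' @param window_size tile width for the background; inferred from the
#'   first window when `NULL`.
#' @param background include the genome-background composition.
#' @return list of class `composition_table` with `counts` (data.table
#'   class/n/fraction) and `background` (same shape or `NULL`).
#' @export
composition <- function(window_set, annotation, window_size = NULL,
                        background = TRUE) {
  if (nrow(window_set) == 0L) {
    warning("composition: empty window set")
    return(structure(list(counts = data.table(), background = NULL),
                     class = "composition_table"))
  }
  classes <- c("gene", "gene&TE", "TE", "IGR")
  tab <- function(cls) {
    n <- as.integer(table(factor(cls, levels = classes)))
    data.table(class = classes, n = n, fraction = n / sum(n))
  }
  counts <- tab(classify_windows(window_set, annotation))
  bg <- NULL
  if (background) {
    ws <- window_size %||% (window_set$end[1] - window_set$start[1])
    tiles <- tile_genome(annotation$chrom_sizes, ws)
    bg <- tab(classify_windows(tiles, annotation))
  }
  structure(list(counts = counts, background = bg),
            class = "composition_table")
}

#' TE length class
#'
#' Short is strictly below 500 bp, long strictly above 2000 bp;
#' the boundaries 500 and 2000 fall in the intermediate class.
#'
#' @param te_length positive TE lengths (bp).
#' @return character vector: `"short"`, `"intermediate"` or `"long"`.
#' @export
te_length_class <- function(te_length) {
  if (any(te_length <= 0)) stop("TE lengths must be positive")
  fifelse(te_length < 500, "short",
          fifelse(te_length > 2000, "long", "intermediate"))
}

#' TE length-class enrichment of a DMR set
#'
#' For DMRs overlapping TEs, tallies by the length class of the overlapped
#' TE (a DMR overlapping several TEs contributes to each) and compares with
#' the length-class composition of all TE-overlapping genome tiles:
#' `ratio = observed fraction / expected fraction`.
#'
#' @param dmr_set interval table of DMR calls.
#' @param annotation a [feature_annotation()] with TEs.
#' @param window_size background tile width; inferred when `NULL`.
#' @return `data.table` with class, n_observed, observed_fraction,
#'   expected_fraction, ratio; `NULL` with a warning when no DMR overlaps
#'   a TE.
#' @export
te_length_enrichment <- function(dmr_set, annotation, window_size = NULL) {
  stopifnot(inherits(annotation, "feature_annotation"))
  if (is.null(annotation$tes) || nrow(annotation$tes) == 0L) {
    stop("annotation carries no TEs")
  }
  classes <- c("short", "intermediate", "long")
  class_counts <- function(ivals) {
    hits <- GenomicRanges::findOverlaps(.as_granges(ivals),
                                        .as_granges(annotation$tes),
                                        ignore.strand = TRUE)
    cls <- te_length_class(annotation$tes$length[S4Vectors::subjectHits(hits)])
    as.integer(table(factor(cls, levels = classes)))
  }
  obs <- class_counts(dmr_set)
  if (sum(obs) == 0L) {
    warning("te_length_enrichment: no TE-overlapping DMRs")
    return(NULL)
  }
  ws <- window_size %||% (dmr_set$end[1] - dmr_set$start[1])
  exp_n <- class_counts(tile_genome(annotation$chrom_sizes, ws))
  out <- data.table(class = classes, n_observed = obs,
                    observed_fraction = obs / sum(obs),
                    expected_fraction = exp_n / sum(exp_n))
  out[, ratio := observed_fraction / expected_fraction]
  out[]
}

#' DMR density along chromosomes
#'
#' Counts DMR midpoints per fixed-width bin; the track behind a
#' chromosome-scale DMR position plot.
#'
#' @param dmr_set interval table of DMR calls.
#' @param chrom_sizes named chromosome lengths.
#' @param bin_size bin width in bp (default 100 kb).
#' @return `data.table`: chrom, bin_start, bin_end, count.
#' @export
chromosome_density <- function(dmr_set, chrom_sizes, bin_size = 100000L) {
  if (bin_size <= 0) stop("bin_size must be positive")
  bins <- tile_genome(chrom_sizes, bin_size)
  setnames(bins, c("start", "end"), c("bin_start", "bin_end"))
  bins[, count := 0L]
  if (nrow(dmr_set)) {
    mid <- (dmr_set$start + dmr_set$end) %/% 2L
    dd <- data.table(chrom = dmr_set$chrom,
                     bin_start = (mid %/% as.integer(bin_size)) * as.integer(bin_size))
    cnt <- dd[, .(count = .N), by = .(chrom, bin_start)]
    bins[cnt, count := i.count, on = .(chrom, bin_start)]
  }
  bins[]
}

#' Pericentromere enrichment of a DMR set
#'
#' Fraction of DMR midpoints inside the pericentromere intervals, and the
#' fold relative to the pericentromeric share of genome tiles (by tile
#' midpoint).
#'
#' @param dmr_set interval table of DMR calls.
#' @param annotation a [feature_annotation()] with pericentromeres.
#' @param window_size background tile width; inferred when `NULL`.
#' @return list: `fraction`, `fold`, `n_dmrs`, `background_fraction`.
#' @export
pericentromere_enrichment <- function(dmr_set, annotation, window_size = NULL) {
  stopifnot(inherits(annotation, "feature_annotation"))
  peri <- annotation$pericentromeres
  if (is.null(peri) || nrow(peri) == 0L) {
    stop("no pericentromere intervals defined in annotation")
  }
  in_peri <- function(ivals) {
    mid <- (ivals$start + ivals$end) %/% 2L
    pts <- data.table(chrom = ivals$chrom, start = mid, end = mid + 1L)
    .overlaps_any(pts, peri)
  }
  if (nrow(dmr_set) == 0L) {
    warning("pericentromere_enrichment: empty DMR set")
    return(list(fraction = NA_real_, fold = NA_real_, n_dmrs = 0L,
                background_fraction = NA_real_))
  }
  ws <- window_size %||% (dmr_set$end[1] - dmr_set$start[1])
  tiles <- tile_genome(annotation$chrom_sizes, ws)
  bg <- mean(in_peri(tiles))
  frac <- mean(in_peri(dmr_set))
  list(fraction = frac, fold = frac / bg, n_dmrs = nrow(dmr_set),
       background_fraction = bg)
}
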