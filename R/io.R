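#' @import data.table
#' @importFrom stats p.adjust rbeta rbinom rnbinom rnorm runif setNames
#'   complete.cases dhyper rpois sd quantile
#' @importFrom utils head tail packageVersion
NULL

# contexts recognised throughout the package
.CONTEXTS <- c("CG", "CHG", "CHH")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-cytosine methylation count report
#'
#' Parses a Bismark-style cytosine/CX report: a header-free tab-separated
#' file with columns chromosome, 1-based position, strand, methylated read
#' count, unmethylated read count, context (CG/CHG/CHH) and trinucleotide.
#' The trinucleotide column is parsed but ignored. Sites with zero coverage
#' are retained; coverage filtering happens at window aggregation, not at
#' parse time. Strand-resolved cytosines are kept as independent sites
#' (symmetric CG pairs are never merged).
#'
#' @param path path to the report file.
#' @param contexts contexts to retain; records in other known contexts are
#'   skipped silently. Defaults to all three.
#' @return a `data.table` with columns `chrom`, `pos` (1-based integer),
#'   `strand`, `count_meth`, `count_unmeth`, `context`, in file order.
#' @examples
#' f <- tempfile()
#' writeLines("Chr1\t15\t+\t8\t2\tCG\tCGA", f)
#' read_cytosine_report(f)
#' @export
read_cytosine_report <- function(path, contexts = .CONTEXTS) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE,
                          blank.lines.skip = FALSE)
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), count_meth = integer(),
                      count_unmeth = integer(), context = character()))
  }
  .validate_report_chunk(dt, offset = 0L, path = path, contexts = contexts)
}

# shared validation/conversion for whole-file and chunked reads; `offset` is
# the number of file lines preceding this chunk, so errors name file lines
.validate_report_chunk <- function(dt, offset, path, contexts) {
  if (ncol(dt) < 7L) {
    stop(sprintf("malformed cytosine report '%s': expected 7 columns, found %d",
                 path, ncol(dt)))
  }
  if (ncol(dt) > 7L) {
    extra <- Reduce(`|`, lapply(dt[, -(1:7)], function(x) !is.na(x) & x != ""))
    if (any(extra)) {
      stop(sprintf("malformed line %d in '%s': more than 7 fields",
                   which(extra)[1] + offset, path))
    }
    dt <- dt[, 1:7]
  }
  setnames(dt, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                 "context", "tri"))
  bad_field <- !complete.cases(dt[, 1:6]) |
    dt$chrom == "" | dt$context == ""
  if (any(bad_field)) {
    stop(sprintf("malformed line %d in '%s': wrong field count",
                 which(bad_field)[1] + offset, path))
  }
  int_ok <- function(x) grepl("^[0-9]+$", x)
  bad <- !int_ok(dt$pos) | dt$pos == "0"
  if (any(bad)) stop(sprintf("malformed line %d in '%s': position '%s' is not a positive integer",
                             which(bad)[1] + offset, path, dt$pos[which(bad)[1]]))
  bad <- !int_ok(dt$count_meth) | !int_ok(dt$count_unmeth)
  if (any(bad)) stop(sprintf("malformed line %d in '%s': non-integer count",
                             which(bad)[1] + offset, path))
  bad <- !(dt$strand %chin% c("+", "-"))
  if (any(bad)) stop(sprintf("malformed line %d in '%s': unknown strand '%s'",
                             which(bad)[1] + offset, path, dt$strand[which(bad)[1]]))
  bad <- !(dt$context %chin% .CONTEXTS)
  if (any(bad)) stop(sprintf("malformed line %d in '%s': unknown context '%s'",
                             which(bad)[1] + offset, path, dt$context[which(bad)[1]]))
  out <- dt[context %chin% contexts,
            .(chrom, pos = as.integer(pos), strand,
              count_meth = as.integer(count_meth),
              count_unmeth = as.integer(count_unmeth), context)]
  out[]
}

#' Stream a cytosine report in fixed-size chunks
#'
#' Reads the report `chunk_size` lines at a time and hands each validated
#' chunk (same columns as [read_cytosine_report()]) to `callback`, so memory
#' use is bounded by the chunk size rather than the file length.
#'
#' @param path report path.
#' @param callback function of one argument (a chunk `data.table`); its
#'   return values are collected in a list.
#' @param chunk_size lines per chunk.
#' @param contexts contexts to retain.
#' @return invisibly, the list of callback results.
#' @export
read_cytosine_report_chunked <- function(path, callback, chunk_size = 100000L,
                                         contexts = .CONTEXTS) {
  stopifnot(is.function(callback), chunk_size >= 1L)
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  results <- list()
  offset <- 0L
  repeat {
    dt <- tryCatch(
      data.table::fread(path, header = FALSE, sep = "\t",
                        colClasses = "character", fill = TRUE,
                        skip = offset, nrows = chunk_size,
                        blank.lines.skip = FALSE),
      error = function(e) NULL)
    if (is.null(dt) || nrow(dt) == 0L) break
    chunk <- .validate_report_chunk(dt, offset = offset, path = path,
                                    contexts = contexts)
    results[[length(results) + 1L]] <- callback(chunk)
    offset <- offset + nrow(dt)
    if (nrow(dt) < chunk_size) break
  }
  invisible(results)
}

#' Write a cytosine report in the Bismark dialect
#'
#' @param sites `data.table` with columns `chrom`, `pos`, `strand`,
#'   `count_meth`, `count_unmeth`, `context` and optionally `tri`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  stopifnot(all(c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                  "context") %in% names(sites)))
  out <- data.table(sites$chrom, sites$pos, sites$strand, sites$count_meth,
                    sites$count_unmeth, sites$context,
                    if ("tri" %in% names(sites)) sites$tri else
                      c(CG = "CGN", CHG = "CHG", CHH = "CHH")[sites$context])
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export DMR calls as BED6
#'
#' One row per call: chrom, 0-based start, half-open end,
#' `name = <comparison_label>:<direction>`, `score = min(1000,
#' round(-10 log10 q))`, strand `"."`. Rows are sorted by (chrom, start).
#' An empty call set produces an empty, header-free file.
#'
#' @param calls a `data.table` of DMR calls with columns `chrom`, `start`,
#'   `end`, `direction`, `q`, `comparison_label` (as produced by
#'   [call_dmrs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end", "direction", "q",
                  "comparison_label") %in% names(calls)))
  score <- ifelse(calls$q <= 0, 1000L,
                  pmin(1000L, as.integer(round(-10 * log10(calls$q)))))
  bed <- data.table(chrom = calls$chrom, start = calls$start, end = calls$end,
                    name = paste0(calls$comparison_label, ":", calls$direction),
                    score = score, strand = ".")
  setorder(bed, chrom, start)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 DMR export back into a call-like table
#'
#' Inverse of [write_dmr_bed()] up to the information BED retains
#' (intervals, label, direction, encoded q).
#'
#' @param path BED path.
#' @return `data.table` with `chrom`, `start`, `end`, `comparison_label`,
#'   `direction`, `score`.
#' @export
read_dmr_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      comparison_label = character(), direction = character(),
                      score = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  setnames(dt, c("chrom", "start", "end", "name", "score", "strand"))
  lab <- sub(":[^:]*$", "", dt$name)
  dir <- sub("^.*:", "", dt$name)
  data.table(chrom = dt$chrom, start = as.integer(dt$start),
             end = as.integer(dt$end), comparison_label = lab,
             direction = dir, score = as.integer(dt$score))
}

# GFF3 type synonyms accepted per feature kind
.GFF_TYPES <- list(
  gene = c("gene", "protein_coding_gene"),
  TE = c("transposable_element", "transposon", "TE",
         "transposable_element_gene", "repeat_region"),
  pericentromere = c("pericentromere", "pericentromeric_region", "region"))

#' Read a feature annotation file (BED or GFF3)
#'
#' BED input is 0-based half-open; GFF3 is 1-based closed. Both are
#' normalised to the package-internal 0-based half-open convention at this
#' boundary. For GFF3, rows are filtered to types matching `feature_kind`
#' when any such rows exist; otherwise all rows are used.
#'
#' @param path annotation file; format detected from the extension
#'   (`.gff`/`.gff3` vs anything else = BED).
#' @param feature_kind one of `"gene"`, `"TE"`, `"pericentromere"`.
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `name`, `length`, `kind`.
#' @export
read_annotation <- function(path, feature_kind = c("gene", "TE", "pericentromere")) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (length(ln) == 0L) stop("GFF3 file '", path, "' has no feature rows")
    dt <- data.table::fread(text = paste(ln, collapse = "\n"), header = FALSE,
                            sep = "\t", fill = TRUE)
    if (ncol(dt) < 9L) stop("GFF3 file '", path, "' has fewer than 9 columns")
    setnames(dt, 1:9, c("chrom", "source", "type", "start1", "end1", "score",
                        "strand", "phase", "attr"))
    keep <- dt$type %chin% .GFF_TYPES[[feature_kind]]
    if (any(keep)) dt <- dt[keep]
    name <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", dt$attr)
    name[!grepl("(?:ID|Name)=", dt$attr)] <- NA_character_
    out <- data.table(chrom = dt$chrom, start = as.integer(dt$start1) - 1L,
                      end = as.integer(dt$end1),
                      strand = ifelse(dt$strand %chin% c("+", "-"), dt$strand, "+"),
                      name = name)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
    if (ncol(dt) < 3L) stop("BED file '", path, "' has fewer than 3 columns")
    out <- data.table(chrom = as.character(dt[[1]]),
                      start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
                      strand = if (ncol(dt) >= 6) {
                        s <- as.character(dt[[6]]); ifelse(s %chin% c("+", "-"), s, "+")
                      } else "+",
                      name = if (ncol(dt) >= 4) as.character(dt[[4]]) else NA_character_)
  }
  if (any(out$end <= out$start)) {
    i <- which(out$end <= out$start)[1]
    stop(sprintf("invalid interval in '%s': [%d, %d) on %s (end <= start after normalisation)",
                 path, out$start[i], out$end[i], out$chrom[i]))
  }
  out[, `:=`(length = end - start, kind = feature_kind)]
  out[]
}

#' Write an interval table as BED6
#' @param intervals table with `chrom`, `start`, `end` and optional `name`,
#'   `strand` (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  bed <- data.table(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = 0L,
    strand = if ("strand" %in% names(intervals)) intervals$strand else ".")
  setorder(bed, chrom, start)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a sample manifest
#'
#' Encodes the experimental design: which report belongs to which
#' (genotype, stage, replicate) cell. Triples must be unique.
#'
#' @param sample_id character vector of sample identifiers.
#' @param genotype `"WT"` or `"mutant"` per sample.
#' @param stage `"leaf"`, `"callus"` or `"shoot"` per sample.
#' @param report_path path to each sample's cytosine report (may be `NA`
#'   when sites are held in memory).
#' @param replicate_index positive integer per sample.
#' @return a `data.table` of class `sample_manifest`.
#' @export
sample_manifest <- function(sample_id, genotype, stage, report_path = NA_character_,
                            replicate_index = seq_along(sample_id)) {
  stopifnot(all(genotype %in% c("WT", "mutant")),
            all(stage %in% c("leaf", "callus", "shoot")),
            all(replicate_index >= 1))
  m <- data.table(sample_id = as.character(sample_id), genotype = genotype,
                  stage = stage, report_path = report_path,
                  replicate_index = as.integer(replicate_index))
  if (anyDuplicated(m[, .(genotype, stage, replicate_index)])) {
    stop("manifest has duplicated (genotype, stage, replicate_index) triples")
  }
  if (anyDuplicated(m$sample_id)) stop("manifest has duplicated sample_ids")
  setattr(m, "class", c("sample_manifest", class(m)))
  m
}

#' Read a sample manifest from TSV
#' @param path TSV with columns sample_id, genotype, stage, report_path,
#'   replicate_index.
#' @return a `sample_manifest`.
#' @export
read_manifest <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  sample_manifest(dt$sample_id, dt$genotype, dt$stage,
                  dt$report_path %||% NA_character_, dt$replicate_index)
}

#' Write a window-level methylation table as TSV
#' @param windows window table from [compute_window_levels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  data.table::fwrite(windows, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a window-level methylation table
#' @param path TSV written by [write_window_table()].
#' @return window `data.table`.
#' @export
read_window_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  dt[]
}
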