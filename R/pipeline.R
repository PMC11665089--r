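#' Load and validate a run configuration
#'
#' A single YAML file drives the whole pipeline: manifest and annotation
#' paths, windowing / DMR / profile parameters, output directory and seed.
#' Parameter blocks are converted into their typed parameter objects (so
#' every invariant is checked up front); path existence is validated by the
#' stage that needs the path.
#'
#' @param path YAML file, or a list with the same structure.
#' @return list of class `run_config` with elements `output_dir`, `seed`,
#'   `manifest`, `annotation` (named paths), `windowing`
#'   ([windowing_params()]), `dmr` ([dmr_params()]), `profile`
#'   ([profile_params()]), `simulate` (free-form list), `control`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  take <- function(block, fn) {
    args <- cfg[[block]] %||% list()
    do.call(fn, args)
  }
  out <- list(
    output_dir = cfg$output_dir %||% "methtile_out",
    seed = as.integer(cfg$seed %||% 1L),
    manifest = cfg$manifest,
    annotation = cfg$annotation,
    control = cfg$control,
    windowing = take("windowing", windowing_params),
    dmr = take("dmr", dmr_params),
    profile = take("profile", profile_params),
    simulate = cfg$simulate %||% list())
  structure(out, class = "run_config")
}

# exhaustive path validation for one stage; all failures listed at once
.require_paths <- function(paths) {
  missing <- paths[!vapply(paths, function(p) !is.null(p) && file.exists(p),
                           logical(1))]
  if (length(missing)) {
    stop("configuration paths missing or nonexistent:\n  ",
         paste(names(missing), unlist(lapply(missing, function(p) p %||% "<unset>")),
               sep = " = ", collapse = "\n  "))
  }
  invisible(TRUE)
}

.read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}

.load_annotation <- function(cfg) {
  .require_paths(list(genes = cfg$annotation$genes, tes = cfg$annotation$tes,
                      chrom_sizes = cfg$annotation$chrom_sizes))
  peri <- NULL
  if (!is.null(cfg$annotation$pericentromere)) {
    .require_paths(list(pericentromere = cfg$annotation$pericentromere))
    peri <- read_annotation(cfg$annotation$pericentromere, "pericentromere")
  }
  feature_annotation(
    genes = read_annotation(cfg$annotation$genes, "gene"),
    tes = read_annotation(cfg$annotation$tes, "TE"),
    pericentromeres = peri,
    chrom_sizes = .read_chrom_sizes(cfg$annotation$chrom_sizes))
}

# machine-readable provenance record: parameters, versions, input checksums.
# deliberately timestamp-free so identical runs produce identical trees
.write_provenance <- function(dir, cfg, stage, inputs = character(0)) {
  rec <- list(
    stage = stage,
    package = "methtile",
    package_version = as.character(packageVersion("methtile")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    params = list(windowing = unclass(cfg$windowing),
                  dmr = unclass(cfg$dmr), profile = unclass(cfg$profile)),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(rec, file.path(dir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[methtile:%s] %s", stage, sprintf(...)))
}

#' Pipeline stage: simulate a study
#'
#' Builds the synthetic genome and regime described in the config's
#' `simulate` block and writes a complete study (reports, manifest, truth,
#' annotation, control) under `output_dir`. The returned config points at
#' the written files, so the following stages can run unchanged.
#'
#' @param cfg a [run_config()].
#' @return the updated config, invisibly; the study is attached as
#'   attribute `"study"`.
#' @export
run_simulate <- function(cfg) {
  sim <- cfg$simulate
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  design_args <- sim$design %||% list()
  genome <- build_genome(do.call(genome_design, design_args),
                         seed = cfg$seed)
  regime <- methylation_regime(
    preset = sim$preset %||% "regeneration",
    depth_mean = sim$depth_mean %||% 20,
    depth_size = sim$depth_size %||% 10,
    nu = sim$nu %||% 20,
    epsilon = sim$epsilon %||% 0.005,
    gene_cg_sd = sim$gene_cg_sd %||% 0)
  reps <- unlist(sim$replicates %||% c(leaf = 4L, callus = 3L, shoot = 4L))
  genotypes <- sim$genotypes %||% "WT"
  study <- simulate_study(genome, regime, genotypes = genotypes,
                          replicates = reps,
                          stages_by_genotype = sim$stages_by_genotype,
                          seed = cfg$seed, outdir = cfg$output_dir)
  .log_stage("simulate", "%d samples, %d sites/sample, genome %d bp",
             nrow(study$manifest), nrow(genome$sites),
             sum(genome$chrom_sizes))
  cfg$manifest <- file.path(cfg$output_dir, "manifest.tsv")
  cfg$control <- file.path(cfg$output_dir, "control.CX_report.txt")
  cfg$annotation <- list(
    genes = file.path(cfg$output_dir, "annotation", "genes.bed"),
    tes = file.path(cfg$output_dir, "annotation", "tes.bed"),
    pericentromere = file.path(cfg$output_dir, "annotation", "pericentromere.bed"),
    chrom_sizes = file.path(cfg$output_dir, "annotation", "chrom_sizes.tsv"))
  .write_provenance(cfg$output_dir, cfg, "simulate")
  attr(cfg, "study") <- study
  invisible(cfg)
}

#' Pipeline stage: aggregate reports into window tables
#'
#' Reads every manifest sample's cytosine report, computes windowed levels,
#' and writes one long-format TSV per context under
#' `output_dir/windows/` plus a provenance record.
#'
#' @param cfg a [run_config()].
#' @return named list of per-sample window tables, invisibly.
#' @export
run_aggregate <- function(cfg) {
  .require_paths(list(manifest = cfg$manifest,
                      chrom_sizes = cfg$annotation$chrom_sizes))
  manifest <- read_manifest(cfg$manifest)
  .require_paths(setNames(as.list(manifest$report_path), manifest$sample_id))
  chrom_sizes <- .read_chrom_sizes(cfg$annotation$chrom_sizes)
  wdir <- file.path(cfg$output_dir, "windows")
  dir.create(wdir, recursive = TRUE, showWarnings = FALSE)

  windows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    rec <- read_cytosine_report(manifest$report_path[i],
                                contexts = cfg$windowing$contexts)
    windows[[sid]] <- compute_window_levels(rec, chrom_sizes, cfg$windowing)
    .log_stage("aggregate", "%s: %d records in, %d/%d windows qualified",
               sid, nrow(rec), sum(windows[[sid]]$qualified),
               nrow(windows[[sid]]))
  }
  for (ctx in cfg$windowing$contexts) {
    long <- rbindlist(lapply(names(windows), function(sid) {
      w <- windows[[sid]][context == ctx]
      cbind(data.table(sample_id = sid), w)
    }))
    write_window_table(long, file.path(wdir, paste0("windows_", ctx, ".tsv")))
  }
  .write_provenance(cfg$output_dir, cfg, "aggregate", manifest$report_path)
  invisible(windows)
}

# rebuild the per-sample window list from the aggregate stage's TSVs
.load_windows <- function(cfg) {
  wdir <- file.path(cfg$output_dir, "windows")
  files <- file.path(wdir, paste0("windows_", cfg$windowing$contexts, ".tsv"))
  .require_paths(setNames(as.list(files), basename(files)))
  long <- rbindlist(lapply(files, read_window_table))
  split_cols <- setdiff(names(long), "sample_id")
  out <- lapply(split(long, by = "sample_id", keep.by = FALSE), function(d) {
    setorder(d, chrom, start, context)[]
  })
  out
}

#' Pipeline stage: call DMRs for every configured comparison
#'
#' Runs [stage_comparisons()] on the aggregated windows and writes, per
#' comparison, the tested-window table, the call table and a BED6 export;
#' hyper/hypo counts per context are echoed to the log.
#'
#' @param cfg a [run_config()].
#' @return named list of `dmr_result` objects, invisibly.
#' @export
run_dmr <- function(cfg) {
  .require_paths(list(manifest = cfg$manifest))
  manifest <- read_manifest(cfg$manifest)
  windows <- .load_windows(cfg)
  results <- stage_comparisons(manifest, windows, cfg$dmr)
  ddir <- file.path(cfg$output_dir, "dmr")
  dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(results)) {
    r <- results[[lab]]
    safe <- gsub("[^A-Za-z0-9]+", "_", lab)
    data.table::fwrite(r$calls, file.path(ddir, paste0("dmr_", safe, ".tsv")),
                       sep = "\t")
    data.table::fwrite(r$tested, file.path(ddir, paste0("tested_", safe, ".tsv")),
                       sep = "\t")
    write_dmr_bed(r$calls, file.path(ddir, paste0("dmr_", safe, ".bed")))
    cnt <- dmr_count_summary(r)
    for (j in seq_len(nrow(cnt))) {
      .log_stage("dmr", "%s %s %s: %d", lab, cnt$context[j], cnt$direction[j],
                 cnt$n[j])
    }
  }
  data.table::fwrite(dmr_count_summary(results),
                     file.path(ddir, "dmr_counts.tsv"), sep = "\t")
  .write_provenance(cfg$output_dir, cfg, "dmr")
  invisible(results)
}

#' Pipeline stage: figure-backing reports
#'
#' For every comparison's calls: feature composition (with genome
#' background), chromosome density tracks, TE length-class enrichment, and
#' — when a pericentromere BED is configured — pericentromere enrichment.
#' Also writes stage-wise meta-profiles for genes and TEs. Without a
#' pericentromere definition the enrichment outputs are skipped with a
#' warning and everything else is still produced.
#'
#' @param cfg a [run_config()].
#' @return `output_dir`, invisibly.
#' @export
run_report <- function(cfg) {
  annotation <- .load_annotation(cfg)
  manifest <- read_manifest(cfg$manifest)
  ddir <- file.path(cfg$output_dir, "dmr")
  rdir <- file.path(cfg$output_dir, "report")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  ws <- cfg$windowing$window_size

  call_files <- setdiff(
    list.files(ddir, pattern = "^dmr_.*\\.tsv$", full.names = TRUE),
    file.path(ddir, "dmr_counts.tsv"))
  for (f in call_files) {
    lab <- sub("^dmr_(.*)\\.tsv$", "\\1", basename(f))
    calls <- data.table::fread(f, sep = "\t")
    if (nrow(calls) == 0L) next
    comp <- composition(calls, annotation, window_size = ws)
    data.table::fwrite(cbind(set = "dmr", comp$counts),
                       file.path(rdir, paste0("composition_", lab, ".tsv")),
                       sep = "\t")
    data.table::fwrite(cbind(set = "background", comp$background),
                       file.path(rdir, paste0("composition_background_", lab, ".tsv")),
                       sep = "\t")
    dens <- calls[, chromosome_density(.SD, annotation$chrom_sizes),
                  by = .(context, direction)]
    data.table::fwrite(dens, file.path(rdir, paste0("density_", lab, ".tsv")),
                       sep = "\t")
    te <- te_length_enrichment(calls, annotation, window_size = ws)
    if (!is.null(te)) {
      data.table::fwrite(te, file.path(rdir, paste0("te_length_", lab, ".tsv")),
                         sep = "\t")
    }
    if (!is.null(annotation$pericentromeres)) {
      pe <- calls[, {
        e <- pericentromere_enrichment(.SD, annotation, window_size = ws)
        .(fraction = e$fraction, fold = e$fold, n_dmrs = e$n_dmrs)
      }, by = .(context, direction)]
      data.table::fwrite(pe, file.path(rdir, paste0("pericentromere_", lab, ".tsv")),
                         sep = "\t")
    } else {
      warning("no pericentromere BED configured; enrichment outputs skipped")
    }
  }

  # stage-wise meta-profiles from the raw reports
  sites <- lapply(setNames(manifest$report_path, manifest$sample_id),
                  read_cytosine_report)
  for (kind in c("gene", "TE")) {
    feats <- if (kind == "gene") annotation$genes else annotation$tes
    for (gt in unique(manifest$genotype)) {
      prof <- profile_by_stage(manifest, sites, feats, cfg$profile,
                               genotype = gt)
      prof[, feature_kind := kind]
      data.table::fwrite(prof,
                         file.path(rdir, sprintf("profile_%s_%s.tsv", kind, gt)),
                         sep = "\t")
    }
  }
  .write_provenance(cfg$output_dir, cfg, "report")
  invisible(cfg$output_dir)
}

#' Pipeline stage: score calls against simulation truth
#'
#' @param cfg a [run_config()]; expects `truth.tsv` under `output_dir`
#'   (written by [run_simulate()]) and the dmr stage's outputs.
#' @return named list of recovery scores per comparison, invisibly.
#' @export
run_score <- function(cfg) {
  truth_path <- file.path(cfg$output_dir, "truth.tsv")
  .require_paths(list(truth = truth_path))
  truth <- data.table::fread(truth_path, sep = "\t")
  ddir <- file.path(cfg$output_dir, "dmr")
  out <- list()
  call_files <- setdiff(
    list.files(ddir, pattern = "^dmr_.*\\.tsv$", full.names = TRUE),
    file.path(ddir, "dmr_counts.tsv"))
  for (f in call_files) {
    calls <- data.table::fread(f, sep = "\t")
    if (nrow(calls) == 0L) next
    lab <- calls$comparison_label[1]
    if (!lab %in% unique(truth$comparison_label)) next
    sc <- withCallingHandlers(score_recovery(calls, truth, comparison = lab),
                              warning = function(w) invokeRestart("muffleWarning"))
    out[[lab]] <- sc
    .log_stage("score", "%s: sensitivity %.3f, FDR %s (%d calls / %d true)",
               lab, sc$sensitivity,
               ifelse(is.na(sc$fdr), "NA", sprintf("%.3f", sc$fdr)),
               sc$n_called, sc$n_true)
  }
  jsonlite::write_json(
    lapply(out, function(s) s[c("sensitivity", "fdr", "n_true", "n_called")]),
    file.path(cfg$output_dir, "recovery_scores.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}

#' Pipeline stage: bisulfite conversion rate from the control track
#'
#' @param cfg a [run_config()] with a `control` report path.
#' @return the [conversion_rate()] result, invisibly.
#' @export
run_conversion <- function(cfg) {
  .require_paths(list(control = cfg$control))
  ctrl <- read_cytosine_report(cfg$control)
  cr <- conversion_rate(ctrl)
  .log_stage("conversion", "conversion rate %.4f over %d calls",
             cr$rate, cr$n_calls)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cr, file.path(cfg$output_dir, "conversion_rate.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cr)
}
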