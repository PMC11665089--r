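# region classes used by the regime table
.REGION_CLASSES <- c("gene", "te_arm", "te_peri", "igr_arm", "igr_peri")

#' Design of a synthetic toy genome
#'
#' A small multi-chromosome genome with a centred pericentromere
#' compartment on each chromosome, genes on the arms, short TEs on arms and
#' in the pericentromere, and long TEs concentrated in the pericentromere.
#' Cytosine sites are placed at configurable per-context densities per
#' compartment (the pericentromere is CHH-dense, as in heterochromatin).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param pericentromere_fraction fraction of each chromosome occupied by
#'   the centred pericentromere.
#' @param genes_per_chrom genes per chromosome (split across both arms).
#' @param gene_length_range min/max gene length, bp.
#' @param te_counts named counts per chromosome: `arm_short`, `arm_intermediate`,
#'   `peri_short`, `peri_long`.
#' @param te_length_ranges list of min/max lengths per TE class; long TEs
#'   must exceed 2000 bp and short TEs stay below 500 bp.
#' @param site_density list with `arm` and `peri` named vectors of sites
#'   per bp for CG/CHG/CHH.
#' @return list of class `genome_design`.
#' @export
genome_design <- function(n_chrom = 2L, chrom_length = 500000L,
                          pericentromere_fraction = 0.2,
                          genes_per_chrom = 60L,
                          gene_length_range = c(1500L, 3000L),
                          te_counts = c(arm_short = 25L, arm_intermediate = 8L,
                                        peri_short = 15L, peri_long = 20L),
                          te_length_ranges = list(short = c(100L, 499L),
                                                  intermediate = c(500L, 2000L),
                                                  long = c(2100L, 4000L)),
                          site_density = list(
                            arm = c(CG = 0.05, CHG = 0.04, CHH = 0.06),
                            peri = c(CG = 0.06, CHG = 0.06, CHH = 0.14))) {
  stopifnot(n_chrom >= 1, chrom_length > 0,
            pericentromere_fraction > 0, pericentromere_fraction < 1)
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 pericentromere_fraction = pericentromere_fraction,
                 genes_per_chrom = as.integer(genes_per_chrom),
                 gene_length_range = as.integer(gene_length_range),
                 te_counts = te_counts, te_length_ranges = te_length_ranges,
                 site_density = site_density),
            class = "genome_design")
}

# place features of given lengths in [a, b) without overlap, in the order
# given, with random gaps by stick-breaking over the free space;
# deterministic under the caller's RNG state
.place_features <- function(a, b, lengths) {
  n <- length(lengths)
  if (n == 0L) {
    return(data.table(start = integer(0), end = integer(0)))
  }
  free <- (b - a) - sum(lengths)
  if (free < 0) stop("infeasible packing: features exceed available space")
  cuts <- sort(runif(n))
  gaps <- floor(free * diff(c(0, cuts)))
  starts <- a + cumsum(gaps) + cumsum(c(0L, head(lengths, -1L)))
  data.table(start = as.integer(starts),
             end = as.integer(starts + lengths))
}

.random_tri <- function(context, n) {
  h <- function(k) sample(c("A", "C", "T"), k, replace = TRUE)
  switch(context,
         CG = paste0("CG", sample(c("A", "C", "G", "T"), n, replace = TRUE)),
         CHG = paste0("C", h(n), "G"),
         CHH = paste0("C", h(n), vapply(seq_len(n), function(i)
           sample(c("A", "C", "T"), 1), character(1))))
}

#' Build a synthetic genome
#'
#' Deterministically (given `seed`) places pericentromeres, genes and TEs,
#' then scatters cytosine sites per context and compartment at the design
#' densities. Each site carries its region class (gene / arm TE / peri TE /
#' arm IGR / peri IGR), the id of a containing gene (for genic CG
#' redistribution), a strand and a trinucleotide.
#'
#' @param design a [genome_design()].
#' @param seed integer seed.
#' @return list of class `synthetic_genome`: `chrom_sizes`, `annotation`
#'   (a [feature_annotation()]), `sites` (data.table), `design`, `seed`.
#' @export
build_genome <- function(design = genome_design(), seed = 1L) {
  stopifnot(inherits(design, "genome_design"))
  set.seed(seed)
  len <- design$chrom_length
  f <- design$pericentromere_fraction
  chroms <- paste0("Chr", seq_len(design$n_chrom))
  chrom_sizes <- setNames(rep(len, design$n_chrom), chroms)

  genes <- list(); tes <- list(); peris <- list()
  rlen <- function(rng, n) as.integer(round(runif(n, rng[1], rng[2])))
  for (ch in chroms) {
    p_start <- as.integer(round(len * (0.5 - f / 2)))
    p_end <- p_start + as.integer(round(len * f))
    peris[[ch]] <- data.table(chrom = ch, start = p_start, end = p_end)

    tc <- design$te_counts
    tr <- design$te_length_ranges
    for (arm in list(c(0L, p_start), c(p_end, len))) {
      ng <- design$genes_per_chrom %/% 2L
      ns <- as.integer(tc[["arm_short"]]) %/% 2L
      ni <- as.integer(tc[["arm_intermediate"]]) %/% 2L
      lens <- c(rlen(design$gene_length_range, ng),
                rlen(tr$short, ns), rlen(tr$intermediate, ni))
      kind <- c(rep("gene", ng), rep("TE", ns + ni))
      ord <- sample.int(length(lens))       # interleave genes and TEs
      placed <- .place_features(arm[1], arm[2], lens[ord])
      placed[, kind := kind[ord]]
      genes[[length(genes) + 1L]] <-
        placed[kind == "gene", .(chrom = ch, start, end,
                                 strand = sample(c("+", "-"), .N, replace = TRUE))]
      tes[[length(tes) + 1L]] <- placed[kind == "TE", .(chrom = ch, start, end)]
    }
    n_ps <- as.integer(tc[["peri_short"]]); n_pl <- as.integer(tc[["peri_long"]])
    plens <- c(rlen(tr$short, n_ps), rlen(tr$long, n_pl))
    placed <- .place_features(p_start, p_end, plens)
    tes[[length(tes) + 1L]] <- placed[, .(chrom = ch, start, end)]
  }
  genes <- rbindlist(genes); setorder(genes, chrom, start)
  genes[, name := sprintf("gene_%04d", .I)]
  tes <- rbindlist(tes, fill = TRUE); setorder(tes, chrom, start)
  tes[, `:=`(name = sprintf("te_%04d", .I), strand = "+")]
  peri <- rbindlist(peris)
  ann <- feature_annotation(genes = genes, tes = tes, pericentromeres = peri,
                            chrom_sizes = chrom_sizes)

  # scatter cytosine sites per compartment and context
  sites <- list()
  for (ch in chroms) {
    p <- peri[chrom == ch]
    regions <- list(arm = list(c(0L, p$start), c(p$end, len)),
                    peri = list(c(p$start, p$end)))
    for (comp in names(regions)) {
      dens <- design$site_density[[comp]]
      for (ctx in .CONTEXTS) {
        for (rg in regions[[comp]]) {
          rl <- rg[2] - rg[1]
          n <- as.integer(round(rl * dens[[ctx]]))
          if (n == 0L) next
          pos <- rg[1] + sort(sample.int(rl, n))   # 1-based positions
          sites[[length(sites) + 1L]] <- data.table(
            chrom = ch, pos = as.integer(pos),
            strand = sample(c("+", "-"), n, replace = TRUE),
            context = ctx, tri = .random_tri(ctx, n), compartment = comp)
        }
      }
    }
  }
  sites <- rbindlist(sites)
  setorder(sites, chrom, pos, context)

  # region class: gene > TE > IGR, split by compartment
  in_gene <- .overlaps_any(sites[, .(chrom, start = pos - 1L, end = pos)], genes)
  in_te <- .overlaps_any(sites[, .(chrom, start = pos - 1L, end = pos)], tes)
  sites[, region_class := fifelse(in_gene, "gene",
                           fifelse(in_te & compartment == "peri", "te_peri",
                            fifelse(in_te, "te_arm",
                             fifelse(compartment == "peri", "igr_peri", "igr_arm"))))]
  # containing gene id (first hit) for genic CG redistribution
  sites[, gene_id := NA_character_]
  if (any(in_gene)) {
    hits <- GenomicRanges::findOverlaps(
      .as_granges(sites[, .(chrom, start = pos - 1L, end = pos)]),
      .as_granges(genes), ignore.strand = TRUE, select = "first")
    sites[!is.na(hits), gene_id := genes$name[hits[!is.na(hits)]]]
  }
  structure(list(chrom_sizes = chrom_sizes, annotation = ann, sites = sites,
                 design = design, seed = seed),
            class = "synthetic_genome")
}

#' Write a synthetic genome's annotation files
#'
#' Emits `genes.bed`, `tes.bed`, `pericentromere.bed` and
#' `chrom_sizes.tsv` into `dir`, in the formats [read_annotation()]
#' consumes.
#'
#' @param genome a [build_genome()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_genome_annotation <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.bed"),
             tes = file.path(dir, "tes.bed"),
             pericentromere = file.path(dir, "pericentromere.bed"),
             chrom_sizes = file.path(dir, "chrom_sizes.tsv"))
  write_bed(genome$annotation$genes, paths["genes"])
  write_bed(genome$annotation$tes, paths["tes"])
  write_bed(genome$annotation$pericentromeres, paths["pericentromere"])
  data.table::fwrite(data.table(chrom = names(genome$chrom_sizes),
                                size = as.integer(genome$chrom_sizes)),
                     paths["chrom_sizes"], sep = "\t", col.names = FALSE)
  invisible(paths)
}

# built-in mean-methylation tables per (region_class, context, stage);
# the "regeneration" preset encodes the qualitative stage and genotype
# dynamics: pericentromeric CHH loss leaf->callus and recovery in shoots,
# gradual CHG gain, high stable CG at TEs, and mutant non-CG
# hypomethylation that is strongest in shoot-stage pericentromere.
.preset_mu <- function(preset) {
  row <- function(rc, ctx, gt, l, c, s) {
    data.table(region_class = rc, context = ctx, genotype = gt,
               stage = c("leaf", "callus", "shoot"), mu = c(l, c, s))
  }
  if (preset == "regeneration") {
    wt <- rbindlist(list(
      row("gene",     "CG",  "WT", 0.25, 0.25, 0.25),
      row("gene",     "CHG", "WT", 0.03, 0.03, 0.03),
      row("gene",     "CHH", "WT", 0.02, 0.02, 0.02),
      row("te_arm",   "CG",  "WT", 0.80, 0.80, 0.82),
      row("te_arm",   "CHG", "WT", 0.35, 0.38, 0.42),
      row("te_arm",   "CHH", "WT", 0.10, 0.05, 0.12),
      row("te_peri",  "CG",  "WT", 0.85, 0.78, 0.88),
      row("te_peri",  "CHG", "WT", 0.60, 0.65, 0.72),
      row("te_peri",  "CHH", "WT", 0.15, 0.04, 0.16),
      row("igr_arm",  "CG",  "WT", 0.05, 0.05, 0.05),
      row("igr_arm",  "CHG", "WT", 0.02, 0.02, 0.02),
      row("igr_arm",  "CHH", "WT", 0.03, 0.02, 0.04),
      row("igr_peri", "CG",  "WT", 0.75, 0.68, 0.78),
      row("igr_peri", "CHG", "WT", 0.50, 0.55, 0.62),
      row("igr_peri", "CHH", "WT", 0.13, 0.04, 0.14)))
    mut <- rbindlist(list(
      row("gene",     "CG",  "mutant", 0.25, 0.25, 0.25),
      row("gene",     "CHG", "mutant", 0.03, 0.03, 0.03),
      row("gene",     "CHH", "mutant", 0.02, 0.02, 0.02),
      row("te_arm",   "CG",  "mutant", 0.80, 0.80, 0.82),
      row("te_arm",   "CHG", "mutant", 0.35, 0.35, 0.35),
      row("te_arm",   "CHH", "mutant", 0.10, 0.05, 0.05),
      row("te_peri",  "CG",  "mutant", 0.85, 0.78, 0.86),
      row("te_peri",  "CHG", "mutant", 0.60, 0.60, 0.60),
      row("te_peri",  "CHH", "mutant", 0.15, 0.04, 0.05),
      row("igr_arm",  "CG",  "mutant", 0.05, 0.05, 0.05),
      row("igr_arm",  "CHG", "mutant", 0.02, 0.02, 0.02),
      row("igr_arm",  "CHH", "mutant", 0.03, 0.02, 0.03),
      row("igr_peri", "CG",  "mutant", 0.75, 0.68, 0.76),
      row("igr_peri", "CHG", "mutant", 0.50, 0.50, 0.50),
      row("igr_peri", "CHH", "mutant", 0.13, 0.04, 0.05)))
    rbind(wt, mut)
  } else if (preset == "flat") {
    # one surface shared by all stages and genotypes; used for null and
    # spike-recovery scenarios
    base <- data.table(
      region_class = .REGION_CLASSES,
      CG = c(0.25, 0.80, 0.80, 0.05, 0.75),
      CHG = c(0.03, 0.35, 0.55, 0.02, 0.45),
      CHH = c(0.02, 0.06, 0.10, 0.03, 0.10))
    long <- melt(base, id.vars = "region_class", variable.name = "context",
                 value.name = "mu", variable.factor = FALSE)
    CJ(stage = c("leaf", "callus", "shoot"),
       genotype = c("WT", "mutant"))[, as.list(long), by = .(stage, genotype)]
  } else stop("unknown regime preset: ", preset)
}

#' Methylation regime
#'
#' The generator's ground truth: a mean methylation level `mu` and
#' beta-binomial precision `nu` for every (region class, context, stage,
#' genotype) cell, a read-depth distribution, a bisulfite failure rate,
#' optional per-window spike overrides, and optional genic CG
#' redistribution. Per-site methylation probabilities follow a
#' `Beta(mu*nu, (1-mu)*nu)` across-site distribution (realised once per
#' study, see [realize_regime()]) and observed counts are binomial at the
#' sampled coverage.
#'
#' The default error model is bisulfite non-conversion: an unmethylated
#' cytosine escapes conversion with probability `epsilon` and reads as
#' methylated, so the apparent methylation probability is
#' `p + (1 - p) * epsilon` and an unmethylated control yields a conversion
#' rate of `1 - epsilon`. `error_model = "thinning"` instead thins true
#' methylation (`p * (1 - epsilon)`).
#'
#' @param preset `"regeneration"` (stage/genotype dynamics mirroring the
#'   regeneration study's directions) or `"flat"` (identical surfaces for
#'   all groups).
#' @param table optional explicit mu table overriding the preset: columns
#'   region_class, context, stage, genotype, mu.
#' @param nu beta-binomial precision (larger = less across-site spread).
#' @param depth_mean mean read depth.
#' @param depth_size negative-binomial size of the depth distribution
#'   (`Inf` = Poisson).
#' @param epsilon bisulfite failure rate in `[0, 1)`.
#' @param error_model `"nonconversion"` (default) or `"thinning"`.
#' @param gene_cg_sd SD of per-(gene, stage) CG offsets emulating genic CG
#'   redistribution; 0 disables.
#' @param window_size tile width used for spikes and truth tables.
#' @return list of class `methylation_regime`.
#' @export
methylation_regime <- function(preset = c("regeneration", "flat"), table = NULL,
                               nu = 20, depth_mean = 20, depth_size = 10,
                               epsilon = 0.005,
                               error_model = c("nonconversion", "thinning"),
                               gene_cg_sd = 0, window_size = 50L) {
  error_model <- match.arg(error_model)
  preset <- match.arg(preset)
  if (nu <= 0) stop("nu must be positive")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (depth_mean < 0) stop("depth_mean must be >= 0")
  tab <- if (is.null(table)) .preset_mu(preset) else as.data.table(table)
  if (any(tab$mu < 0 | tab$mu > 1)) stop("regime mu values must lie in [0, 1]")
  structure(list(table = tab, nu = nu, depth_mean = depth_mean,
                 depth_size = depth_size, epsilon = epsilon,
                 error_model = error_model, gene_cg_sd = gene_cg_sd,
                 window_size = as.integer(window_size),
                 spikes = NULL, gene_offsets = NULL, preset = preset),
            class = "methylation_regime")
}

#' Materialise the random parts of a regime
#'
#' Draws, under `seed`, (i) one latent quantile `u` per genome site and
#' (ii) per-(gene, stage) CG offsets (the genic CG redistribution), and
#' attaches both to the regime. A site's methylation probability in any
#' group is then `qbeta(u, mu*nu, (1-mu)*nu)`: the beta marginal gives the
#' across-site spread, while the shared quantile couples groups, so two
#' groups with the same `mu` have identical site probabilities (a
#' calibrated null) and a raised `mu` raises every site's probability
#' monotonically. All of this happens before any read counts are sampled,
#' so window truth is derivable from the realised regime alone.
#'
#' @param genome a [build_genome()] result.
#' @param regime a [methylation_regime()].
#' @param seed integer seed for the realisation draws.
#' @return the regime with `site_u` and (when enabled) `gene_offsets`
#'   attached.
#' @export
realize_regime <- function(genome, regime, seed = 1L) {
  set.seed(seed)
  regime$site_u <- runif(nrow(genome$sites))
  if (regime$gene_cg_sd > 0) {
    g <- CJ(gene_id = genome$annotation$genes$name,
            stage = c("leaf", "callus", "shoot"))
    g[, offset := rnorm(.N, 0, regime$gene_cg_sd)]
    regime$gene_offsets <- g
  }
  regime
}

# realised per-site methylation probability for one (stage, genotype)
.site_p <- function(genome, regime, stage, genotype) {
  if (is.null(regime$site_u)) stop("regime is not realised; call realize_regime()")
  mu <- .site_mu(genome, regime, stage, genotype)
  p <- numeric(length(mu))
  interior <- mu > 0 & mu < 1
  p[interior] <- stats::qbeta(regime$site_u[interior],
                              mu[interior] * regime$nu,
                              (1 - mu[interior]) * regime$nu)
  p[mu >= 1] <- 1
  p
}

# per-site mean methylation surface for one (stage, genotype); the ground
# truth every simulated sample of that group is drawn around
.site_mu <- function(genome, regime, stage, genotype) {
  st <- stage; gt <- genotype
  tab <- regime$table[stage == st & genotype == gt]
  if (nrow(tab) == 0L) stop("regime does not cover stage=", st, " genotype=", gt)
  s <- genome$sites
  mu <- tab[s, on = .(region_class, context), mu]
  if (anyNA(mu)) {
    miss <- unique(s[is.na(mu), .(region_class, context)])
    stop("regime missing cells: ",
         paste(miss$region_class, miss$context, sep = "/", collapse = ", "))
  }
  if (!is.null(regime$gene_offsets)) {
    off <- regime$gene_offsets[stage == st]
    o <- off[s, on = "gene_id", offset]
    sel <- !is.na(o) & s$context == "CG"
    mu[sel] <- mu[sel] + o[sel]
  }
  if (!is.null(regime$spikes)) {
    sp <- regime$spikes[stage == st & genotype == gt]
    if (nrow(sp)) {
      w <- as.integer(regime$window_size)
      key <- data.table(chrom = s$chrom, start = ((s$pos - 1L) %/% w) * w,
                        context = s$context)
      o <- sp[key, on = .(chrom, start, context), mu]
      mu[!is.na(o)] <- o[!is.na(o)]
    }
  }
  pmin(pmax(mu, 0), 1)
}

#' Simulate one WGBS sample
#'
#' Per site: the methylation probability is the realised regime surface
#' value (marginally `Beta(mu*nu, (1-mu)*nu)` across sites, see
#' [realize_regime()]); coverage comes from a negative-binomial (or
#' Poisson) depth distribution and the methylated count from a binomial at
#' the apparent methylation probability of the error model. Replicates of
#' a group share the surface and differ only in read sampling.
#' Deterministic given `seed`.
#'
#' @param genome a [build_genome()] result.
#' @param regime a realised [methylation_regime()]; an unrealised regime
#'   is realised on the fly under `seed` (fine for one-off samples, but a
#'   multi-sample study must share one realisation — use
#'   [simulate_study()]).
#' @param stage,genotype the group simulated.
#' @param seed integer seed.
#' @return `data.table` of cytosine records (`chrom`, `pos`, `strand`,
#'   `count_meth`, `count_unmeth`, `context`, `tri`), in genome site order.
#' @export
simulate_sample <- function(genome, regime, stage, genotype = "WT", seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(regime, "methylation_regime"))
  if (is.null(regime$site_u)) regime <- realize_regime(genome, regime, seed)
  p <- .site_p(genome, regime, stage, genotype)
  set.seed(seed)
  n <- length(p)
  cov <- if (is.finite(regime$depth_size)) {
    rnbinom(n, size = regime$depth_size, mu = regime$depth_mean)
  } else {
    rpois(n, regime$depth_mean)
  }
  p_app <- if (regime$error_model == "nonconversion") {
    p + (1 - p) * regime$epsilon
  } else {
    p * (1 - regime$epsilon)
  }
  meth <- rbinom(n, cov, p_app)
  s <- genome$sites
  data.table(chrom = s$chrom, pos = s$pos, strand = s$strand,
             count_meth = as.integer(meth),
             count_unmeth = as.integer(cov - meth),
             context = s$context, tri = s$tri)
}

#' Simulate an unmethylated control track
#'
#' A plastid-like sequence with true methylation zero everywhere; under the
#' non-conversion error model its apparent methylation equals the bisulfite
#' failure rate, so [conversion_rate()] recovers `1 - epsilon`.
#'
#' @param regime a [methylation_regime()].
#' @param n_sites number of control cytosines.
#' @param seed integer seed.
#' @return cytosine record `data.table` on chromosome `"ctrl"`.
#' @export
simulate_control <- function(regime, n_sites = 50000L, seed = 1L) {
  set.seed(seed)
  cov <- if (is.finite(regime$depth_size)) {
    rnbinom(n_sites, size = regime$depth_size, mu = regime$depth_mean)
  } else {
    rpois(n_sites, regime$depth_mean)
  }
  p_app <- if (regime$error_model == "nonconversion") regime$epsilon else 0
  meth <- rbinom(n_sites, cov, p_app)
  ctx <- sample(.CONTEXTS, n_sites, replace = TRUE, prob = c(0.25, 0.25, 0.5))
  data.table(chrom = "ctrl", pos = seq_len(n_sites),
             strand = sample(c("+", "-"), n_sites, replace = TRUE),
             count_meth = as.integer(meth),
             count_unmeth = as.integer(cov - meth),
             context = ctx, tri = ctx)
}

#' Window-level truth table from a realised regime
#'
#' For each genome tile and context, the true window mean methylation is
#' the mean of its sites' regime surface values per group; the truth delta
#' of a comparison is the group difference. Flags depend only on the
#' regime, never on sampled counts. Windows without sites carry `NA`.
#'
#' @param genome a [build_genome()] result.
#' @param regime a realised [methylation_regime()].
#' @param comparisons list of comparisons, each
#'   `list(label=, a=c(stage, genotype), b=c(stage, genotype))`.
#' @param flag_delta absolute truth delta at or above which a window is
#'   flagged differential (typically the declared spike size).
#' @return `data.table`: chrom, start, end, context, comparison_label,
#'   true_delta, differential.
#' @export
truth_windows <- function(genome, regime, comparisons, flag_delta = 0.2) {
  w <- as.integer(regime$window_size)
  tiles <- tile_genome(genome$chrom_sizes, w)
  out <- list()
  for (cmp in comparisons) {
    mu_a <- .site_mu(genome, regime, cmp$a[1], cmp$a[2])
    mu_b <- .site_mu(genome, regime, cmp$b[1], cmp$b[2])
    s <- genome$sites[, .(chrom, start = ((pos - 1L) %/% w) * w, context)]
    s[, `:=`(mu_a = mu_a, mu_b = mu_b)]
    agg <- s[, .(true_a = mean(mu_a), true_b = mean(mu_b)), by = .(chrom, start, context)]
    grid <- tiles[, .(context = .CONTEXTS), by = .(chrom, start, end)]
    t1 <- agg[grid, on = .(chrom, start, context)]
    t1[, `:=`(comparison_label = cmp$label, true_delta = true_b - true_a)]
    t1[, differential := !is.na(true_delta) & abs(true_delta) >= flag_delta]
    out[[length(out) + 1L]] <- t1[, .(chrom, start, end, context,
                                      comparison_label, true_delta, differential)]
  }
  rbindlist(out)
}

#' Simulate a full multi-sample study
#'
#' Generates one report per (genotype, stage, replicate) cell plus an
#' unmethylated control track and the window-level truth table for the
#' standard comparisons. The default replicate structure mirrors the
#' design the pipeline targets: four replicates of leaf and shoot, three
#' of callus. Fully deterministic given `seed`.
#'
#' @param genome a [build_genome()] result.
#' @param regime a [methylation_regime()]; realised internally.
#' @param genotypes genotypes to simulate; stages may be restricted per
#'   genotype via `stages_by_genotype`.
#' @param replicates named replicate counts per stage.
#' @param stages_by_genotype named list mapping genotype to its stages.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param n_control_sites control track size.
#' @param outdir when given, reports / manifest / truth / annotation are
#'   also written there.
#' @param flag_delta truth flag threshold (see [truth_windows()]).
#' @return list of class `methylome_study`: `manifest`, `sites` (named list
#'   of record tables), `control`, `truth`, `genome`, `regime`, `seed`.
#' @export
simulate_study <- function(genome, regime, genotypes = "WT",
                           replicates = c(leaf = 4L, callus = 3L, shoot = 4L),
                           stages_by_genotype = NULL, seed = 1L,
                           n_control_sites = 50000L, outdir = NULL,
                           flag_delta = 0.2) {
  stopifnot(all(replicates >= 1L))
  set.seed(seed)
  regime <- realize_regime(genome, regime, seed = sample.int(.Machine$integer.max, 1))
  cells <- rbindlist(lapply(genotypes, function(gt) {
    stages <- if (!is.null(stages_by_genotype)) stages_by_genotype[[gt]] else
      names(replicates)
    rbindlist(lapply(stages, function(st) {
      data.table(genotype = gt, stage = st, replicate_index = seq_len(replicates[[st]]))
    }))
  }))
  cells[, sample_id := sprintf("%s_%s_r%d", genotype, stage, replicate_index)]
  sample_seeds <- sample.int(.Machine$integer.max, nrow(cells) + 1L)

  sites <- vector("list", nrow(cells))
  names(sites) <- cells$sample_id
  for (i in seq_len(nrow(cells))) {
    sites[[i]] <- simulate_sample(genome, regime, cells$stage[i],
                                  cells$genotype[i], seed = sample_seeds[i])
  }
  control <- simulate_control(regime, n_control_sites,
                              seed = sample_seeds[nrow(cells) + 1L])

  cmp <- list()
  have <- function(gt, st) any(cells$genotype == gt & cells$stage == st)
  if (have("WT", "leaf") && have("WT", "callus")) {
    cmp <- c(cmp, list(list(label = "c", a = c("leaf", "WT"), b = c("callus", "WT"))))
  }
  if (have("WT", "callus") && have("WT", "shoot")) {
    cmp <- c(cmp, list(list(label = "s", a = c("callus", "WT"), b = c("shoot", "WT"))))
  }
  for (st in c("leaf", "callus", "shoot")) {
    if (have("WT", st) && have("mutant", st)) {
      cmp <- c(cmp, list(list(label = paste0("dme:", st),
                              a = c(st, "WT"), b = c(st, "mutant"))))
    }
  }
  truth <- if (length(cmp)) truth_windows(genome, regime, cmp, flag_delta) else NULL

  manifest <- sample_manifest(cells$sample_id, cells$genotype, cells$stage,
                              NA_character_, cells$replicate_index)
  study <- structure(list(manifest = manifest, sites = sites, control = control,
                          truth = truth, genome = genome, regime = regime,
                          seed = seed),
                     class = "methylome_study")
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

#' Write a simulated study to disk
#'
#' Reports in the Bismark dialect, manifest and truth as TSV, annotation
#' as BED — exactly the formats the I/O layer reads back.
#'
#' @param study a [simulate_study()] result.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(file.path(outdir, "reports"), recursive = TRUE, showWarnings = FALSE)
  m <- copy(study$manifest)
  paths <- file.path(outdir, "reports", paste0(m$sample_id, ".CX_report.txt"))
  for (i in seq_len(nrow(m))) {
    write_cytosine_report(study$sites[[m$sample_id[i]]], paths[i])
  }
  m[, report_path := paths]
  data.table::fwrite(m, file.path(outdir, "manifest.tsv"), sep = "\t")
  write_cytosine_report(study$control, file.path(outdir, "control.CX_report.txt"))
  if (!is.null(study$truth)) {
    data.table::fwrite(study$truth, file.path(outdir, "truth.tsv"), sep = "\t")
  }
  write_genome_annotation(study$genome, file.path(outdir, "annotation"))
  invisible(outdir)
}

#' Reference spike-recovery scenario
#'
#' Two groups drawn from one flat methylation surface, except for
#' `n_spike` pericentromeric CHH windows whose mean differs by
#' `spike_delta` between groups (half hypermethylated in group B, half
#' hypomethylated). The scenario the DMR caller's sensitivity and
#' empirical FDR are scored on: a 2 x 500 kb genome with a 20%
#' pericentromere, depth 20, three replicates per group.
#'
#' @param seed master seed.
#' @param n_spike number of spiked windows.
#' @param spike_delta absolute between-group difference in mu.
#' @param depth mean read depth.
#' @param replicates replicates per group.
#' @param base_mu pericentromeric CHH baseline level.
#' @param n_spike_min_sites minimum CHH sites for a window to be
#'   spikeable.
#' @return a `methylome_study` whose groups are the `leaf` (A) and
#'   `callus` (B) stages, with spike truth in `$truth` (comparison `"c"`).
#' @export
simulate_reference_scenario <- function(seed = 42L, n_spike = 200L,
                                        spike_delta = 0.5, depth = 20,
                                        replicates = 3L, base_mu = 0.1,
                                        n_spike_min_sites = 4L) {
  genome <- build_genome(genome_design(), seed = seed)
  regime <- methylation_regime("flat", depth_mean = depth)
  w <- regime$window_size

  # spikeable windows: fully pericentromeric, enough CHH sites
  set.seed(seed + 1L)
  peri <- genome$annotation$pericentromeres
  s <- genome$sites[context == "CHH"]
  s[, start := ((pos - 1L) %/% w) * w]
  cand <- s[, .(n = .N), by = .(chrom, start)][n >= n_spike_min_sites]
  # require full containment in a pericentromere interval
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(peri))) {
    keep <- keep | (cand$chrom == peri$chrom[i] &
                      cand$start >= peri$start[i] &
                      cand$start + w <= peri$end[i])
  }
  cand <- cand[keep]
  if (nrow(cand) < n_spike) stop("not enough spikeable pericentromeric CHH windows")
  pick <- cand[sample.int(nrow(cand), n_spike)]
  hyper <- seq_len(n_spike) <= n_spike %/% 2L

  hi <- base_mu + spike_delta
  spikes <- rbind(
    # hyper: group B (callus) raised
    pick[hyper][, .(chrom, start, end = start + w, context = "CHH",
                    stage = "callus", genotype = "WT", mu = hi)],
    # hypo: group A (leaf) raised, so B lost methylation
    pick[!hyper][, .(chrom, start, end = start + w, context = "CHH",
                     stage = "leaf", genotype = "WT", mu = hi)])
  # flat preset's pericentromeric CHH baseline is replaced by base_mu
  regime$table[context == "CHH" & region_class %in% c("te_peri", "igr_peri"),
               mu := base_mu]
  regime$spikes <- spikes

  simulate_study(genome, regime, genotypes = "WT",
                 replicates = c(leaf = replicates, callus = replicates),
                 stages_by_genotype = list(WT = c("leaf", "callus")),
                 seed = seed, flag_delta = spike_delta / 2)
}

#' Score DMR recovery against simulation truth
#'
#' Sensitivity is the fraction of truth-flagged windows that were called;
#' empirical FDR is the fraction of calls that are not truth-flagged.
#' Matching is by (chrom, start, context).
#'
#' @param calls DMR call table (from a `dmr_result`).
#' @param truth truth table from [truth_windows()] /
#'   `study$truth`, restricted to one comparison label when several are
#'   present (`comparison`).
#' @param comparison optional comparison label filter for `truth`.
#' @return list: `sensitivity`, `fdr` (`NA` when no calls), `n_true`,
#'   `n_called`, `n_true_called`, `by_direction` breakdown.
#' @export
score_recovery <- function(calls, truth, comparison = NULL) {
  tr <- as.data.table(truth)
  if (!is.null(comparison)) tr <- tr[comparison_label == comparison]
  if (nrow(tr) == 0L) stop("empty truth table for comparison")
  key <- c("chrom", "start", "context")
  if (nrow(calls)) {
    unknown <- !calls[, do.call(paste, .SD), .SDcols = key] %in%
      tr[, do.call(paste, .SD), .SDcols = key]
    if (any(unknown)) stop("call windows missing from truth tiling: tilings differ")
  }
  true_set <- tr[differential == TRUE]
  n_true <- nrow(true_set)
  n_called <- nrow(calls)
  if (n_called == 0L) {
    warning("score_recovery: empty call set; FDR undefined")
    return(list(sensitivity = 0, fdr = NA_real_, n_true = n_true,
                n_called = 0L, n_true_called = 0L, by_direction = NULL))
  }
  merged <- tr[calls, on = key]
  n_tp <- sum(merged$differential, na.rm = TRUE)
  by_dir <- merged[, .(n_called = .N, n_true = sum(differential, na.rm = TRUE)),
                   by = .(direction)]
  list(sensitivity = n_tp / n_true, fdr = (n_called - n_tp) / n_called,
       n_true = n_true, n_called = n_called, n_true_called = n_tp,
       by_direction = by_dir)
}
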