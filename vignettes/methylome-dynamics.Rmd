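---
title: "Windowed WGBS methylome analysis with methtile: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed WGBS methylome analysis with methtile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtile)
library(data.table)
```

# The problem

Plant regeneration through tissue culture proceeds in two steps: a
differentiated explant (a leaf) is reprogrammed into pluripotent callus, and
the callus then regenerates de novo shoots. Both transitions reshape the DNA
methylome, and in plants this involves three cytosine contexts — CG, CHG and
CHH — maintained by distinct pathways. The largest dynamics are concentrated
in pericentromeric heterochromatin, where transposable elements (TEs) are
dense: CHH methylation there is erased during callus induction and
re-established during shoot regeneration, while genic CG methylation is
redistributed rather than globally shifted. Demethylase mutants (loss of the
DEMETER glycosylase) additionally show global non-CG hypomethylation of the
pericentromere, strongest in regenerated shoots.

`methtile` implements the analysis that quantifies these dynamics from
whole-genome bisulfite sequencing (WGBS): windowed methylation levels,
differentially methylated region (DMR) calling, genomic-feature composition,
chromosomal and TE-length stratification, and meta-feature profiles —
together with a synthetic methylome generator that makes every stage
testable without sequencing data.

# Windowed methylation levels

The unit of analysis is a fixed, non-overlapping 50 bp tile anchored at
coordinate 0 (the tiling origin and non-overlap are conventions of this
package; only the 50 bp width is inherited from the upstream protocol). For
one sample and one context:

- the per-site methylation level is `count_meth / (count_meth +
  count_unmeth)`, computed only at sites whose coverage reaches
  `min_reads_per_cytosine` (default 5);
- the window level is the **unweighted mean of qualifying per-site
  ratios** — not the pooled-count ratio. The pooled ratio is stored
  alongside (`level_pooled`) because the DMR test operates on pooled
  counts, but the per-site mean is the canonical level;
- a window qualifies for a sample only if it holds at least
  `min_cytosines_per_window` (default 3) qualifying sites. Unqualified
  windows carry an `NA` level, which is deliberately distinct from 0: they
  are excluded from every mean and from DMR testing rather than dragged
  toward zero.

The read floor is interpreted **per cytosine**: each of the ≥ 3 cytosines
must individually reach 5 reads. The alternative reading (≥ 5 reads summed
over the window) would make the 3-cytosine floor nearly vacuous at any
realistic depth; it remains available as
`windowing_params(read_filter = "window_total")` and is recorded in the
window table either way. For any comparison, windows must be jointly
qualified in *every* replicate of *both* groups (`joint_qualify()`), so all
group means and tests rest on the same read support.

Whole-genome, gene and TE averages (`average_level()`) weight qualified
windows equally rather than by cytosine count; the choice is exposed in the
sense that the per-window levels are returned and can be reweighted by the
caller. The bisulfite conversion rate is estimated from an unmethylated
control sequence (in practice the plastid genome, which carries no
methylation) as `sum(unmethylated calls) / sum(all calls)` pooled over
contexts.

# DMR calling

A window is a DMR between groups A and B when it passes **two independent
gates**:

1. **Significance.** A two-sided exact test on the 2×2 table of
   replicate-pooled methylated/unmethylated counts
   (`exact_count_test()`), BH-adjusted within each (context, comparison)
   family (`bh_adjust()`), must give `q < 0.05` (strict).
2. **Effect size.** The per-window difference `delta = mean(levels_B) -
   mean(levels_A)` (means of per-replicate window levels) must satisfy
   `|delta| > s`, where `s` is one population standard deviation
   (denominator *n*) of the deltas of **all tested windows** of that
   context and comparison.

Direction is `hyper` when `delta > 0` (B gained methylation relative to A).
Hyper and hypo sets are disjoint by construction and their union is exactly
the set of windows passing both gates. Adjacent significant windows are
*not* merged into larger blocks; DMRs are reported at window resolution.

Design choices worth stating explicitly:

- **The SD gate is genome-wide, not within-window.** Reading "one standard
  deviation within each window" as an SD across ≤ 4 replicates inside one
  window would make the gate self-referential and wildly unstable at small
  replicate counts; the distribution over windows is the stable, testable
  reading, and the multiplier is configurable
  (`dmr_params(effect_sd_multiplier = )`).
- **Degenerate delta distributions gate everything out.** If every tested
  window has the same delta the population SD is exactly 0 and there is no
  scale to compare against; no window passes, rather than all of them.
- **Pooled Fisher by default, replicate regression as an option.** The
  pooled exact test is deterministic and oracle-checkable by exhaustive
  hypergeometric enumeration; it is implemented in-package as a vectorised
  enumeration because per-window calls to a general-purpose routine are
  impractical at 10^4–10^5 windows. A per-replicate binomial regression
  (likelihood-ratio test) is available via `dmr_params(test =
  "per_replicate_regression")` for replicate-aware behaviour.
- **BH, not SLIM.** q-values are Benjamini–Hochberg: standard, deterministic
  and fully specified. The adjustment method is recorded in the result.
- **Strict inequalities** at both thresholds (`>` for the gate, `<` for q),
  so boundary ties are not called.
- Because the test statistic, the q-value variant, and the exact windowing
  of any given upstream study are not fully pinned down by its methods
  description, absolute DMR counts from such studies are not reproduction
  targets for this package; the package's own acceptance checks are
  property- and simulation-based (below).

The standard comparison plan (`stage_comparisons()`) is: leaf→callus within
wild type (label `c`), callus→shoot within wild type (label `s`), and
WT→mutant at each stage where both genotypes are present (`dme:leaf`,
`dme:callus`, `dme:shoot`).

# Feature annotation and stratification

Windows are classified against gene and TE interval sets by ≥ 1 bp overlap
(the simplest testable reading of "overlapped with"): `gene&TE` when both
overlap, `gene` or `TE` when only one does, `IGR` otherwise — a partition,
so composition fractions always sum to 1. The genome background is the same
classification applied to every tile of the same width.

TE length classes are strict: short `< 500` bp, long `> 2000` bp, the
boundary values falling in `intermediate`. Enrichment compares the
length-class fractions of TE-overlapping DMRs against all TE-overlapping
tiles.

Chromosomal positions use the window midpoint (uniform 50 bp windows make
the midpoint unambiguous and avoid double-counting across bins); the
default display bin for chromosome-scale density tracks is 100 kb, with the
raw window positions always retained underneath. Pericentromere boundaries
are a required input (BED) because reference pericentromere coordinates are
assembly-specific; the synthetic genome defines its own.

# Meta-feature profiles

Profiles pool **per-site ratios**, not window levels: scaling a 50 bp
window into a fraction of a short TE body distorts exactly the features of
most interest. Each feature body is divided into `n_body_bins = 20` equal
fractions and each 2 kb flank into 10 fixed-width bins (all configurable;
meta-plot parameters are conventions, not inherited values). Sites are
assigned strand-aware — minus-strand features are mirrored so bins always
run 5′→3′ — and a bin's value is the unweighted mean of per-site ratios
pooled over all features. Features shorter than the bin count are skipped
(and counted) rather than up-weighted; overlapping features each receive
their sites independently, with no deduplication. With `flank_bp = 0` the
profile reduces to a pure body profile. Stage profiles pool replicates at
the site level, which is idempotent for identical replicates.

# The synthetic methylome generator

The generator is first-class, tested code, not a fixture. It emulates:

- a small multi-chromosome genome (default 2 × 500 kb) with a centred
  pericentromere occupying 20% of each chromosome;
- genes on the arms (interleaved with short/intermediate TEs), long
  (> 2 kb) TEs confined to the pericentromere, short TEs in both
  compartments;
- per-context cytosine densities that make the pericentromere CHH-dense
  (default 0.14 CHH sites/bp vs 0.06 on arms), mirroring heterochromatin;
- per-(region class, context, stage, genotype) mean methylation levels
  `mu`, with beta-distributed across-site spread of precision `nu`
  (default 20), negative-binomial read depth (mean 20, size 10), and a
  bisulfite failure rate `epsilon` (default 0.5%).

**Realisation model.** `nu` models *across-site* biological
heterogeneity. Each site receives one latent quantile `u`, drawn once per
study before any read counts, and its methylation probability in a group
with mean `mu` is `qbeta(u, mu*nu, (1-mu)*nu)`. Marginally across sites
this is exactly the beta distribution; across groups it couples sites so
that two groups with equal `mu` have *identical* site probabilities (a
properly calibrated null for the pooled count test) and a raised `mu`
raises every site's probability monotonically. Replicates of a group share
the surface and differ only in read sampling. The cost of this choice is
that replicate-level biological variance is not modelled — see
limitations.

**Error model.** Incomplete bisulfite conversion is modelled as
non-conversion: an unmethylated cytosine escapes conversion with
probability `epsilon` and reads as methylated, so the apparent methylation
probability is `p + (1-p)*epsilon` and an unmethylated control recovers a
conversion rate of `1 - epsilon` — which is what the plastid control is
for. The alternative (thinning true methylation by `1 - epsilon`) is
available as `error_model = "thinning"` but cannot produce a non-trivial
conversion-rate estimate from a fully unmethylated control.

**Presets.** The `"regeneration"` regime encodes the qualitative stage and
genotype directions of the regeneration system: pericentromeric TE CHH
0.15 → 0.04 → 0.16 across leaf → callus → shoot; a gradual CHG rise
(0.60 → 0.65 → 0.72) that the mutant lacks; high, nearly stable TE CG; low
genic non-CG; optional per-(gene, stage) CG offsets (`gene_cg_sd`)
emulating genic CG redistribution; and a mutant that tracks the wild type
into callus but fails to re-establish non-CG methylation in shoots
(pericentromeric CHH 0.05 vs 0.16). Magnitudes are this package's own
choices — chosen once as plausible for heterochromatic plant methylomes —
since the source system is described directionally, not numerically. The
`"flat"` preset gives every group one surface and is the basis of the null
and spike-recovery scenarios.

**Truth-first bookkeeping.** Differential flags are derived from the
realised regime (the `mu` surfaces, gene offsets and spike table) before
any counts are sampled; `truth_windows()` tabulates per-window true deltas
per comparison, and `score_recovery()` computes sensitivity and empirical
FDR against them. Everything is deterministic given `(config, seed)`, to
the point of byte-identical report files.

# What the tests show — and what they cannot

The acceptance suite checks, at fixed seeds and desk-scale problem sizes
(chosen as the package's reference conditions: 2 × 500 kb genome, depth 20,
3 replicates/group for the recovery scenarios; the full suite runs in a few
minutes on one CPU):

- exact-test p-values equal exhaustive hypergeometric enumeration to
  10⁻¹² over all 2×2 tables with row margins ≤ 30;
- BH q-values match a direct step-up recomputation on 10⁴ random vectors;
- window levels and qualification flags match a naive per-site brute-force
  implementation exactly, with monotone behaviour across filter grids;
- 200 spiked pericentromeric CHH windows (|Δμ| = 0.5) are recovered with
  sensitivity ≥ 0.90 at empirical FDR ≤ 0.10, and the same scenario with
  zero spikes calls ≤ 1% of tested windows;
- the `"regeneration"` preset reproduces the qualitative directions: TE CHH
  dips in callus; leaf→callus CHH hypo calls outnumber hyper calls;
  mutant shoots show CHH hypo ≫ hyper concentrated in the pericentromere
  (fold > 2);
- composition classes match exhaustive per-tile classification; group
  swaps mirror hyper/hypo exactly; the conversion-rate estimate recovers
  `1 - epsilon` within ±0.002.

Passing these shows the machinery is correct and the effect sizes the
generator encodes are recoverable. It does **not** show that real WGBS data
meet the generator's assumptions: real libraries have non-uniform coverage
along the genome, strand-asymmetric artefacts, mapping bias around
repetitive TEs (precisely the pericentromeric regions of interest),
replicate-level biological variance, and methylation autocorrelation along
chromosomes, none of which are simulated. Absolute DMR counts on real data
will also depend on the test variant and q-value method in ways the
simulation does not probe.

# Numerical and degenerate-input conventions

- All internal coordinates are 0-based half-open; conversion happens only
  at I/O boundaries (BED in/out directly; GFF3 converted on read; cytosine
  reports keep their 1-based positions in the `pos` column).
- Strand-resolved cytosines are independent sites; symmetric CG pairs are
  never merged (no merging step exists in the windowed-average protocol
  this follows).
- Empty selections (no qualifying windows, zero-coverage controls, empty
  call sets) return explicit `NA`-with-count results plus a warning — never
  a silent zero.
- BED scores encode q-values as `min(1000, round(-10*log10(q)))`, the
  Phred-style convention; `q = 0` caps at 1000.
- Ties: the effect gate and q-threshold use strict inequalities; the exact
  test sums tables with probability ≤ observed within the conventional
  `1e-7` relative tolerance.
- The parser rejects malformed report lines (wrong field count, non-integer
  counts, unknown strand or context) with the offending line number;
  zero-coverage sites parse fine and are filtered downstream.

# A small worked run

```{r example, eval = FALSE}
genome <- build_genome(genome_design(), seed = 1)
regime <- methylation_regime("regeneration")
study <- simulate_study(
  genome, regime, genotypes = "WT",
  replicates = c(leaf = 3, callus = 3),
  stages_by_genotype = list(WT = c("leaf", "callus")), seed = 1)
windows <- lapply(study$sites, compute_window_levels,
                  chrom_sizes = genome$chrom_sizes)
res <- stage_comparisons(study$manifest, windows)
dmr_count_summary(res[["c"]])
pericentromere_enrichment(
  res[["c"]]$calls[context == "CHH" & direction == "hypo"],
  genome$annotation, window_size = 50)
```

The same analysis is available from a shell through the bundled CLI
(`inst/scripts/methtile`), whose subcommands (`simulate`, `aggregate`,
`dmr`, `report`, `score`, `conversion`) are thin wrappers over the
`run_*()` functions driven by one YAML configuration; library and CLI
paths produce identical artifacts.

# Known limitations

- No merging of adjacent significant windows into larger DMR blocks.
- No smoothing or imputation of unqualified windows.
- The regression test option refits a GLM per window and is only practical
  for small window sets.
- The generator does not simulate read-level artefacts (FASTQ, alignment,
  duplicates), TE insertions, or replicate-level biological variance.
- Pericentromere boundaries must be supplied; the package does not infer
  them from methylation or repeat density.
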