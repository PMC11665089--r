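# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles deliberately avoid the package's own code paths.

# naive per-site windowed-level computation: plain loops over raw counts
oracle_window_levels <- function(sites, chrom_sizes, window_size = 50,
                                 min_reads = 5, min_cytosines = 3) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    for (ctx in unique(sites$context)) {
      for (s0 in starts) {
        e0 <- min(s0 + window_size, len)
        sel <- sites$chrom == ch & sites$context == ctx &
          sites$pos >= s0 + 1 & sites$pos <= e0
        sub <- sites[sel, , drop = FALSE]
        ratios <- c()
        for (i in seq_len(nrow(sub))) {
          cov <- sub$count_meth[i] + sub$count_unmeth[i]
          if (cov >= min_reads) ratios <- c(ratios, sub$count_meth[i] / cov)
        }
        qual <- length(ratios) >= min_cytosines
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = s0, end = e0, context = ctx,
          n_sites = length(ratios),
          level = if (qual) mean(ratios) else NA_real_,
          qualified = qual)
      }
    }
  }
  do.call(rbind, out)
}

# direct BH step-up recomputation
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, min(1, n / i * p[o[i]]))
    q_sorted[i] <- running
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# exhaustive hypergeometric enumeration of the two-sided exact p-value,
# written as a plain per-table loop (the conventional 1e-7 relative
# tolerance for ties)
oracle_exact_p <- function(ma, ua, mb, ub) {
  n1 <- ma + ua
  k <- ma + mb
  tot <- ma + ua + mb + ub
  if (tot == 0) return(NA_real_)
  lo <- max(0, k - (tot - n1))
  hi <- min(k, n1)
  probs <- numeric(hi - lo + 1)
  for (x in lo:hi) probs[x - lo + 1] <- stats::dhyper(x, k, tot - k, n1)
  obs <- probs[ma - lo + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# small deterministic cytosine site table on a toy genome
make_random_sites <- function(n = 1000, chrom_sizes = c(ChrT = 10000),
                              seed = 1, contexts = c("CG", "CHG", "CHH"),
                              max_cov = 30) {
  set.seed(seed)
  ch <- sample(names(chrom_sizes), n, replace = TRUE)
  pos <- vapply(ch, function(c) sample.int(chrom_sizes[[c]], 1), integer(1))
  cov <- sample.int(max_cov + 1, n, replace = TRUE) - 1L
  meth <- vapply(cov, function(k) if (k == 0) 0L else sample.int(k + 1, 1) - 1L,
                 integer(1))
  data.table::data.table(
    chrom = ch, pos = as.integer(pos),
    strand = sample(c("+", "-"), n, replace = TRUE),
    count_meth = meth, count_unmeth = as.integer(cov - meth),
    context = sample(contexts, n, replace = TRUE))
}

# a small annotation: one chromosome, a gene, a TE near it, pericentromere
make_toy_annotation <- function() {
  feature_annotation(
    genes = data.table::data.table(chrom = "ChrT", start = 0L, end = 200L,
                                   strand = "+", name = "g1"),
    tes = data.table::data.table(chrom = "ChrT",
                                 start = c(240L, 700L), end = c(300L, 3000L),
                                 name = c("te1", "te2")),
    pericentromeres = data.table::data.table(chrom = "ChrT", start = 4000L,
                                             end = 8000L),
    chrom_sizes = c(ChrT = 10000L))
}

# a small fast genome for simulator tests
small_genome <- function(seed = 11) {
  build_genome(genome_design(
    n_chrom = 2L, chrom_length = 100000L, genes_per_chrom = 12L,
    te_counts = c(arm_short = 8L, arm_intermediate = 2L,
                  peri_short = 4L, peri_long = 4L)), seed = seed)
}
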