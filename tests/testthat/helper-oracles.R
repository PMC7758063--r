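# Independent reference implementations used as oracles. These are coded
# directly from textbook formulas, separately from the package's vectorized
# paths.

# Weir & Cockerham (1984) variance components, one variant at a time, written
# as an explicit loop over subpopulations.
wc_fst_reference <- function(dosages, demes) {
  demes <- as.factor(demes)
  r <- nlevels(demes)
  num <- den <- 0
  for (v in seq_len(nrow(dosages))) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      g <- dosages[v, demes == levels(demes)[k]]
      n_i[k] <- length(g)
      p_i[k] <- sum(g) / (2 * length(g))
      h_i[k] <- mean(g == 1)
    }
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    if (p_bar > 0 && p_bar < 1) {
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# exhaustive LD pruning oracle for <= ~12 variants: among all subsets whose
# pairwise r^2 stays below the threshold, the greedy left-to-right rule keeps
# the lexicographically earliest maximal admissible subset; enumerate directly.
ld_prune_reference <- function(dosages, r2_threshold = 0.1) {
  M <- nrow(dosages)
  r2 <- suppressWarnings(stats::cor(t(dosages)))^2
  r2[is.na(r2)] <- 0
  keep <- logical(M)
  for (j in seq_len(M)) {
    ok <- TRUE
    for (i in seq_len(j - 1)) {
      if (keep[i] && r2[i, j] > r2_threshold) ok <- FALSE
    }
    keep[j] <- ok
  }
  which(keep)
}

# brute-force lead-SNP scan: for every causal variant, collect assigned
# variants by nearest-causal rule and pick the minimum-p one under threshold
lead_snp_reference <- function(sumstats, causal, p_threshold = 5e-4,
                               window_bp = 1e5) {
  picks <- integer(0)
  owner <- apply(cbind(sumstats$chrom, sumstats$pos), 1, function(sv) {
    cand <- which(causal$chrom == sv[1])
    if (length(cand) == 0) return(NA_integer_)
    d <- abs(causal$pos[cand] - sv[2])
    j <- cand[which.min(d)]
    if (min(d) <= window_bp / 2) j else NA_integer_
  })
  for (ci in seq_len(nrow(causal))) {
    rows <- which(owner == ci & !is.na(sumstats$p))
    if (length(rows) == 0) next
    rows <- rows[order(sumstats$p[rows], sumstats$pos[rows])]
    if (sumstats$p[rows[1]] < p_threshold) picks <- c(picks, rows[1])
  }
  sort(picks)
}
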