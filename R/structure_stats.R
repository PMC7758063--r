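#' LD pruning of a dosage matrix
#'
#' Greedy window-based pruning in the style of PLINK `--indep-pairwise 100 10
#' 0.1`: windows advance by variant count; within a window variants are
#' scanned left to right (by position order of the rows) and a variant is
#' dropped when its squared genotype correlation with any earlier retained
#' variant in the window exceeds the threshold, so the earlier-position
#' variant of a correlated pair is retained. Windows never span chromosomes.
#'
#' @param dosages Integer matrix, variants x individuals, with the variant
#'   table attached as attribute `"variants"` (as from [get_dosages()]); or a
#'   bare matrix (treated as one chromosome, rows in position order).
#' @param window_size,step,r2_threshold Window length and step in variants and
#'   the squared-correlation threshold (defaults 100 / 10 / 0.1).
#' @return Integer vector of retained row indices.
#' @export
ld_prune <- function(dosages, window_size = 100L, step = 10L, r2_threshold = 0.1) {
  M <- nrow(dosages)
  if (M == 0L) return(integer(0))
  v <- attr(dosages, "variants")
  chrom <- if (!is.null(v)) v$chrom else rep(1L, M)
  keep <- rep(TRUE, M)
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    m <- length(rows)
    starts <- if (m <= window_size) 1L else seq(1L, m - window_size + 1L, by = step)
    for (s in starts) {
      win <- rows[s:min(s + window_size - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      X <- t(dosages[win, , drop = FALSE])
      r2 <- suppressWarnings(stats::cor(X))^2
      r2[is.na(r2)] <- 0
      inwin <- rep(TRUE, length(win))
      for (j in 2:length(win)) {
        if (any(r2[which(inwin[1:(j - 1)]), j] > r2_threshold)) inwin[j] <- FALSE
      }
      keep[win[!inwin]] <- FALSE
    }
  }
  which(keep)
}

wc_components <- function(dosages, demes) {
  demes <- as.factor(demes)
  r <- nlevels(demes)
  if (r < 2L) stop("Weir-Cockerham FST needs at least two demes")
  idx <- split(seq_along(demes), demes)
  nj <- vapply(idx, length, integer(1))
  if (any(nj < 2L)) stop("every deme needs at least two individuals")
  M <- nrow(dosages)
  # per-deme allele frequency and heterozygote proportion, per variant
  pj <- matrix(0, M, r)
  hj <- matrix(0, M, r)
  for (k in seq_len(r)) {
    block <- dosages[, idx[[k]], drop = FALSE]
    pj[, k] <- rowSums(block) / (2 * nj[k])
    hj[, k] <- rowSums(block == 1L) / nj[k]
  }
  n_bar <- mean(nj)
  n_c <- (r * n_bar - sum(nj^2) / (r * n_bar)) / (r - 1)
  w <- nj / (r * n_bar)
  p_bar <- as.vector(pj %*% w)
  s2 <- as.vector(((pj - p_bar)^2) %*% nj) / ((r - 1) * n_bar)
  h_bar <- as.vector(hj %*% w)
  inner <- p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4
  a <- (n_bar / n_c) * (s2 - inner / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  poly <- p_bar > 0 & p_bar < 1
  list(a = a, total = a + b + cc, poly = poly)
}

#' Multi-population Weir-Cockerham FST (ratio of averages)
#'
#' Computes the Weir & Cockerham (1984) variance components a (among demes)
#' and a + b + c (total) per variant and returns FST = sum(a) / sum(a + b + c)
#' — the ratio-of-averages estimator, not the average of per-variant ratios.
#' The confidence interval is a block bootstrap over variants (1 Mb blocks by
#' default), since nearby variants share genealogies.
#'
#' @param dosages Variants x individuals dosage matrix (attribute `"variants"`
#'   used for block positions when present).
#' @param demes Deme label per individual (column).
#' @param n_boot Bootstrap resamples (default 1000; 0 disables the CI).
#' @param block_bp Block length in bp for the bootstrap (default 1e6).
#' @param conf Confidence level (default 0.95).
#' @return An `fst_result`: list with `fst`, `ci`, `n_variants`, `boot`.
#' @export
weir_cockerham_fst <- function(dosages, demes, n_boot = 1000L, block_bp = 1e6,
                               conf = 0.95) {
  comp <- wc_components(dosages, demes)
  if (!any(comp$poly)) stop("FST is undefined: all variants are monomorphic overall")
  a <- comp$a[comp$poly]
  tot <- comp$total[comp$poly]
  fst <- sum(a) / sum(tot)
  ci <- c(NA_real_, NA_real_)
  boot <- NULL
  if (n_boot > 0L) {
    v <- attr(dosages, "variants")
    block <- if (!is.null(v)) {
      (v$chrom[comp$poly] * 1e6 + floor(v$pos[comp$poly] / block_bp))
    } else {
      seq_along(a)  # no positions: ordinary bootstrap over variants
    }
    ba <- tapply(a, block, sum)
    bt <- tapply(tot, block, sum)
    B <- length(ba)
    boot <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(B, B, replace = TRUE)
      sum(ba[j]) / sum(bt[j])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  }
  structure(list(fst = fst, ci = ci, n_variants = sum(comp$poly),
                 boot = boot, conf = conf),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("FST = %.3g (%d%% CI %.3g - %.3g, %d variants)\n", x$fst,
              round(100 * x$conf), x$ci[1], x$ci[2], x$n_variants))
  invisible(x)
}

#' Percentile genomic inflation factor
#'
#' lambda_p = (p-th percentile of the observed chi-square test statistics) /
#' (p-th quantile of the chi-square distribution with 1 df). The median
#' (p = 0.5) is the standard genomic inflation factor; p = 0.999 is the tail
#' variant used to detect inflation confined to extreme statistics.
#'
#' @param stats Non-negative chi-square (1 df) association statistics.
#' @param p Percentile in (0, 1); default 0.5.
#' @return An `inflation_result`: list with `lambda`, `p`, `n_tests`.
#' @export
genomic_inflation <- function(stats, p = 0.5) {
  stats <- stats[!is.na(stats)]
  if (!(p > 0 && p < 1)) stop("percentile p must be in (0, 1)")
  if (any(stats < 0)) stop("chi-square statistics must be non-negative")
  need <- max(10, ceiling(1 / min(p, 1 - p)))
  if (length(stats) < need)
    stop("too few tests (", length(stats), ") to resolve the ", p, " percentile")
  lam <- unname(stats::quantile(stats, p)) / stats::qchisq(p, df = 1)
  structure(list(lambda = lam, p = p, n_tests = length(stats)),
            class = "inflation_result")
}

#' @export
print.inflation_result <- function(x, ...) {
  cat(sprintf("lambda_%g = %.4f (%d tests)\n", x$p, x$lambda, x$n_tests))
  invisible(x)
}

#' Rescale a genomic inflation factor to another sample size
#'
#' Inflation from stratification grows linearly with sample size:
#' lambda_N = (N / N0) * (lambda_N0 - 1) + 1.
#'
#' @param lambda_obs Observed lambda at sample size `N0`.
#' @param N0,N Observed and target sample sizes.
#' @export
rescale_lambda <- function(lambda_obs, N0, N) {
  stopifnot(lambda_obs >= 0, N0 > 0, N > 0)
  (N / N0) * (lambda_obs - 1) + 1
}

#' Genomic inflation of a birthplace GWAS
#'
#' Runs a covariate-free per-variant linear association of each individual's
#' grid coordinate (x = column/longitude, y = row/latitude) on dosage and
#' returns the median-percentile inflation factor of the resulting chi-square
#' statistics. This is the lambda_location calibration used to match the
#' simulated structure to an observed cohort.
#'
#' @param dosages Variants x individuals dosage matrix.
#' @param samples Sample table with `row` and `col` (see [sample_table()]).
#' @param axis "y" (row / latitude) or "x" (column / longitude).
#' @param p Percentile (default median).
#' @return An `inflation_result`.
#' @export
location_gwas_lambda <- function(dosages, samples, axis = c("y", "x"), p = 0.5) {
  axis <- match.arg(axis)
  coord <- if (axis == "y") samples$row else samples$col
  if (length(unique(samples$deme)) < 2L)
    stop("location GWAS needs individuals from more than one deme")
  chis <- marginal_chisq(dosages, as.numeric(coord))
  genomic_inflation(chis[!is.na(chis)], p = p)
}

# chi-square (1 df) statistics of per-variant simple linear regression,
# computed from correlations: t^2 = (n-2) r^2 / (1 - r^2)
marginal_chisq <- function(dosages, y) {
  n <- ncol(dosages)
  yc <- y - mean(y)
  sy <- sum(yc^2)
  xs <- rowSums(dosages)
  xy <- as.vector(dosages %*% yc)
  xx <- rowSums(dosages^2) - xs^2 / n
  r2 <- xy^2 / (xx * sy)
  out <- (n - 2) * r2 / (1 - r2)
  out[xx <= 0] <- NA_real_
  out
}
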