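#' Per-variant linear association with covariates
#'
#' Ordinary least squares of the phenotype on each variant's dosage with an
#' intercept and optional covariates (e.g. 100 PCs). Covariates are projected
#' out of both phenotype and dosages once, so the per-variant fit is a single
#' residual regression; p-values are two-sided from the t distribution with
#' n - k - 2 degrees of freedom. Constant (or fully covariate-explained)
#' dosages are skipped and flagged with NA statistics.
#'
#' @param dosages Variants x individuals dosage matrix (attribute `"variants"`
#'   carried through to the output when present).
#' @param phenotype Numeric phenotype vector (or a `phenotype_set`, using `$y`).
#' @param covariates Optional `pc_set` or numeric matrix (individuals x k);
#'   lists of such sets are column-bound (e.g. 50 common- + 50 rare-PCs).
#' @param chunk Variants per block (memory control).
#' @return A `summary_stats` data frame: chrom, pos, freq, beta, se, chisq, p.
#' @export
gwas_linear <- function(dosages, phenotype, covariates = NULL, chunk = 20000L) {
  y <- if (inherits(phenotype, "phenotype_set")) phenotype$y else as.numeric(phenotype)
  res <- gwas_scan_multi(dosages, matrix(y, ncol = 1), covariates, chunk)
  M <- nrow(dosages)
  v <- attr(dosages, "variants")
  out <- data.frame(
    chrom = if (!is.null(v)) v$chrom else NA_integer_,
    pos = if (!is.null(v)) v$pos else seq_len(M),
    freq = rowMeans(dosages) / 2,
    beta = res$beta[, 1], se = res$se[, 1], chisq = res$chisq[, 1],
    p = res$p[, 1])
  structure(out, class = c("summary_stats", "data.frame"), df = res$df)
}

# shared scan over one or many phenotype columns: covariates are projected out
# once, every phenotype column reuses the projected dosages
gwas_scan_multi <- function(dosages, Y, covariates = NULL, chunk = 20000L) {
  n <- ncol(dosages)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == n)
  C <- covariate_matrix(covariates, n)
  k <- ncol(C) - 1L  # minus intercept
  if (k + 2L >= n) stop("covariate count + 2 must be below the sample size")
  Q <- qr.Q(qr(C))
  Yt <- Y - Q %*% crossprod(Q, Y)
  yy <- colSums(Yt^2)
  df <- n - k - 2L
  M <- nrow(dosages); nT <- ncol(Y)
  beta <- se <- chisq <- matrix(NA_real_, M, nT)
  for (s in seq(1L, M, by = chunk)) {
    ix <- s:min(s + chunk - 1L, M)
    X <- dosages[ix, , drop = FALSE]
    XQ <- X %*% Q
    xx <- rowSums(X^2) - rowSums(XQ^2)
    XY <- X %*% Yt
    ok <- xx > 1e-10
    for (t in seq_len(nT)) {
      b <- ifelse(ok, XY[, t] / xx, NA_real_)
      rss <- pmax(yy[t] - b^2 * xx, 0)
      s2 <- rss / df / xx
      beta[ix, t] <- b
      se[ix, t] <- ifelse(ok, sqrt(s2), NA_real_)
      chisq[ix, t] <- ifelse(ok, b^2 / s2, NA_real_)
    }
  }
  p <- 2 * stats::pt(-sqrt(pmax(chisq, 0)), df = df)
  list(beta = beta, se = se, chisq = chisq, p = p, df = df)
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  if (inherits(covariates, "pc_set")) covariates <- covariates$vectors
  if (is.list(covariates) && !is.matrix(covariates))
    covariates <- do.call(cbind, lapply(covariates, function(x)
      if (inherits(x, "pc_set")) x$vectors else as.matrix(x)))
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  cbind(1, covariates)
}

#' Leave-one-chromosome-out mixed-model association
#'
#' For each chromosome, variance components are estimated once by restricted
#' maximum likelihood under the model y = Cb + g + e with g ~ N(0, sg^2 K),
#' where K is a GRM built from all other chromosomes (avoiding proximal
#' contamination); every variant on the chromosome is then tested by
#' generalized least squares in the eigenbasis of that K. The heritability
#' ratio is profiled on a one-dimensional grid. Covariates (e.g. 100 PCs)
#' enter as fixed effects.
#'
#' @param dosages Variants x individuals dosage matrix with a `"variants"`
#'   attribute giving each variant's chromosome.
#' @param phenotype Numeric vector or `phenotype_set`.
#' @param grm_dosages Dosage matrix (with `"variants"`) from which the LOCO
#'   GRMs are built (the spec's common- or rare-variant GRM source).
#' @param covariates As in [gwas_linear()].
#' @param h2_grid Grid for the variance-ratio search (default 0 to 0.95 by 0.05).
#' @param forced_h2 Fix the ratio instead of estimating (0 reduces exactly to
#'   [gwas_linear()]).
#' @return A `summary_stats` data frame with an `h2` column giving the
#'   per-chromosome variance-ratio estimate used.
#' @export
gwas_lmm_loco <- function(dosages, phenotype, grm_dosages, covariates = NULL,
                          h2_grid = seq(0, 0.95, by = 0.05), forced_h2 = NULL) {
  y <- if (inherits(phenotype, "phenotype_set")) phenotype$y else as.numeric(phenotype)
  v <- attr(dosages, "variants")
  if (is.null(v)) stop("dosages must carry a variant table with chromosomes")
  gv <- attr(grm_dosages, "variants")
  if (is.null(gv)) stop("grm_dosages must carry a variant table with chromosomes")
  chroms <- unique(v$chrom)
  if (length(union(unique(gv$chrom), chroms)) < 2L)
    stop("LOCO needs at least two chromosomes")
  n <- ncol(dosages)
  C <- covariate_matrix(covariates, n)
  out <- data.frame(chrom = v$chrom, pos = v$pos, freq = rowMeans(dosages) / 2,
                    beta = NA_real_, se = NA_real_, chisq = NA_real_,
                    p = NA_real_, h2 = NA_real_)
  for (ch in chroms) {
    if (sum(gv$chrom != ch) < 2L)
      stop("no variants left for the GRM when chromosome ", ch, " is excluded")
    K <- compute_grm(grm_dosages[gv$chrom != ch, , drop = FALSE],
                     source = "loco")$matrix
    e <- eigen(K, symmetric = TRUE)
    U <- e$vectors; d <- pmax(e$values, 0)
    ystar <- crossprod(U, y)
    Cstar <- crossprod(U, C)
    h2 <- if (!is.null(forced_h2)) forced_h2 else {
      ll <- vapply(h2_grid, function(h) reml_loglik(h, d, ystar, Cstar), numeric(1))
      if (all(!is.finite(ll))) stop("variance estimation failed on chromosome ", ch)
      h2_grid[which.max(ll)]
    }
    w <- 1 / (h2 * d + (1 - h2))
    rows <- which(v$chrom == ch)
    Xstar <- dosages[rows, , drop = FALSE] %*% U  # M x n rotated dosages
    out[rows, c("beta", "se", "chisq", "p", "h2")] <-
      gls_scan(Xstar, ystar, Cstar, w, h2)
  }
  structure(out, class = c("summary_stats", "data.frame"))
}

reml_loglik <- function(h, d, ystar, Cstar) {
  w <- 1 / (h * d + (1 - h))
  k <- ncol(Cstar)
  CtWC <- crossprod(Cstar, Cstar * w)
  CtWy <- crossprod(Cstar, ystar * w)
  bhat <- tryCatch(solve(CtWC, CtWy), error = function(e) NULL)
  if (is.null(bhat)) return(-Inf)
  r <- ystar - Cstar %*% bhat
  rss <- sum(r^2 * w)
  nk <- length(ystar) - k
  -0.5 * (nk * log(rss / nk) - sum(log(w)) + determinant(CtWC)$modulus)
}

gls_scan <- function(Xstar, ystar, Cstar, w, h2) {
  # residualize y and variants on fixed effects under weights w
  Cw <- Cstar * sqrt(w)
  yw <- as.vector(ystar) * sqrt(w)
  Q <- qr.Q(qr(Cw))
  yt <- yw - Q %*% crossprod(Q, yw)
  yy <- sum(yt^2)
  Xw <- Xstar * rep(sqrt(w), each = nrow(Xstar))
  XQ <- Xw %*% Q
  xx <- rowSums(Xw^2) - rowSums(XQ^2)
  xy <- as.vector(Xw %*% yt)  # yt is already orthogonal to the span of Q
  df <- length(yw) - ncol(Cw) - 1L
  ok <- xx > 1e-10
  b <- ifelse(ok, xy / xx, NA_real_)
  s2 <- pmax(yy - b^2 * xx, 0) / df / xx
  chisq <- ifelse(ok, b^2 / s2, NA_real_)
  data.frame(beta = b, se = ifelse(ok, sqrt(s2), NA_real_), chisq = chisq,
             p = 2 * stats::pt(-sqrt(pmax(chisq, 0)), df = df), h2 = h2)
}

#' Sibling-difference association test
#'
#' Regresses the within-pair phenotype difference on the within-pair dosage
#' difference, without an intercept (Mendelian segregation makes E[dx] = 0).
#' Because both siblings share their deme, any deme-level environment cancels
#' from dy, making the test immune to stratification.
#'
#' @param dx Dosage differences: numeric vector (one variant) or matrix
#'   (variants x pairs).
#' @param dy Phenotype differences per pair.
#' @return Data frame with beta, se, chisq, p per variant.
#' @export
sib_difference_test <- function(dx, dy) {
  if (is.null(dim(dx))) dx <- matrix(dx, nrow = 1)
  m <- ncol(dx)
  stopifnot(length(dy) == m)
  if (m < 2L) stop("need at least two sibling pairs")
  xx <- rowSums(dx^2)
  if (all(xx == 0)) stop("all dosage differences are zero; effect undefined")
  xy <- as.vector(dx %*% dy)
  b <- ifelse(xx > 0, xy / xx, NA_real_)
  df <- m - 1L
  rss <- pmax(sum(dy^2) - b^2 * xx, 0)
  s2 <- rss / df / xx
  chisq <- ifelse(xx > 0, b^2 / s2, NA_real_)
  data.frame(beta = b, se = ifelse(xx > 0, sqrt(s2), NA_real_), chisq = chisq,
             p = 2 * stats::pt(-sqrt(pmax(chisq, 0)), df = df))
}

#' Tail genomic inflation of summary statistics
#'
#' Delegates to [genomic_inflation()] at a tail percentile (default 99.9%),
#' optionally restricted to a variant class. Local environmental effects
#' inflate this tail while leaving the median untouched.
#'
#' @param stats A `summary_stats` data frame (or chi-square vector).
#' @param rows Optional row subset (e.g. indices of a variant class).
#' @param p Percentile (default 0.999).
#' @export
tail_inflation <- function(stats, rows = NULL, p = 0.999) {
  x <- if (is.data.frame(stats)) stats$chisq else stats
  if (!is.null(rows)) x <- x[rows]
  genomic_inflation(x[!is.na(x)], p = p)
}
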