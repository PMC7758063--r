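#' Genetic relatedness matrix from standardized dosages
#'
#' GRM = Z'Z / M where column i of Z' is individual i and each variant row is
#' standardized to mean zero and unit variance under Hardy-Weinberg:
#' z = (x - 2p) / sqrt(2p(1-p)), with p the derived-allele frequency computed
#' from the matrix itself. Monomorphic rows are excluded with a warning.
#'
#' @param dosages Variants x individuals dosage matrix.
#' @param source Label recorded on the result ("common", "rare", ...).
#' @param chunk Rows per accumulation block (memory control).
#' @return A `grm` object: list with `matrix` (n x n), `source`, `n_variants`.
#' @export
compute_grm <- function(dosages, source = "common", chunk = 5000L) {
  M <- nrow(dosages); n <- ncol(dosages)
  if (M < 2L) stop("need at least two variants")
  p <- rowMeans(dosages) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic variants excluded from the GRM")
  }
  rows <- which(poly)
  G <- matrix(0, n, n)
  for (s in seq(1L, length(rows), by = chunk)) {
    ix <- rows[s:min(s + chunk - 1L, length(rows))]
    Z <- (dosages[ix, , drop = FALSE] - 2 * p[ix]) / sqrt(2 * p[ix] * (1 - p[ix]))
    G <- G + crossprod(Z)
  }
  G <- G / length(rows)
  structure(list(matrix = G, source = source, n_variants = length(rows)),
            class = "grm")
}

#' Exact IBD-sharing relatedness matrix from simulated genealogies
#'
#' Extracts exact identity-by-descent segments (maximal intervals over which
#' two haplotypes descend from the same most recent common ancestor) from the
#' stored tree sequences, keeps segments at least `min_segment_cM` long (the
#' uniform map has 1 cM = 1 Mb at the default recombination rate of 1e-8), and
#' sets entry (i, j) to the summed shared length over the four haplotype pairs
#' divided by twice the haploid genome length, so entries lie in [0, 1]; a
#' full sibling without recombination averages 1/2 and a duplicated individual
#' scores 1. The diagonal is set to 1.
#'
#' In real data this quantity would come from an IBD detector (e.g. GERMLINE);
#' here the simulated genealogy gives it exactly.
#'
#' @param dataset A `genotype_dataset` (must carry its simulation store).
#' @param min_segment_cM Minimum segment length in cM (default 10).
#' @param genome_cM Total haploid map length in cM; default derived from the
#'   genome spec (1 cM per Mb).
#' @return A `grm` with source "ibd".
#' @export
ibd_sharing_grm <- function(dataset, min_segment_cM = 10, genome_cM = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!file.exists(file.path(dataset$dir, "chr1.trees")))
    stop("simulation store with genealogies not found; cannot compute exact IBD")
  if (is.null(genome_cM))
    genome_cM <- dataset$genome$n_chromosomes * dataset$genome$chromosome_length / 1e6
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  run_driver(c("ibd", "--dir", dataset$dir,
               "--min-span", format(min_segment_cM * 1e6, scientific = FALSE),
               "--out", out))
  pairs <- utils::read.table(out, header = TRUE, sep = "\t")
  n_full <- dataset$n_individuals
  G <- matrix(0, n_full, n_full)
  if (nrow(pairs) > 0) {
    ij <- cbind(pairs$i + 1L, pairs$j + 1L)
    G[ij] <- pairs$span
    G[ij[, c(2, 1), drop = FALSE]] <- pairs$span
  }
  G <- pmin(G / (2 * genome_cM * 1e6), 1)
  diag(G) <- 1
  keep <- dataset$individuals
  structure(list(matrix = G[keep, keep, drop = FALSE], source = "ibd",
                 genome_cM = genome_cM, min_segment_cM = min_segment_cM),
            class = "grm")
}

#' Principal components of a relatedness matrix
#'
#' Double-centers the GRM (removing the all-ones direction) and returns the
#' top k eigenpairs. Eigenvector sign is fixed by making each column's
#' largest-magnitude loading positive, so results are deterministic.
#'
#' For large matrices with k much smaller than n, the top-k subspace is
#' found by blocked orthogonal (subspace) iteration with a fixed iteration
#' count and a deterministic start, instead of a full eigendecomposition;
#' `method` overrides the automatic choice.
#'
#' @param grm A `grm` (or a bare symmetric matrix).
#' @param k Number of components (default 100; must be < n).
#' @param method "full", "subspace", or "auto" (subspace when n > 4000 and
#'   k <= n/10).
#' @return A `pc_set`: list with `vectors` (n x k, orthonormal), `values`
#'   (non-increasing), `source`.
#' @export
pca <- function(grm, k = 100L, method = c("auto", "full", "subspace")) {
  method <- match.arg(method)
  G <- if (inherits(grm, "grm")) grm$matrix else grm
  n <- nrow(G)
  if (k >= n) stop("k must be smaller than the number of individuals")
  cm <- colMeans(G)
  G <- G - matrix(cm, n, n, byrow = TRUE) - cm + mean(G)
  if (method == "auto")
    method <- if (n > 4000L && k <= n %/% 10L) "subspace" else "full"
  if (method == "full") {
    e <- eigen(G, symmetric = TRUE)
    vec <- e$vectors[, seq_len(k), drop = FALSE]
    val <- e$values[seq_len(k)]
  } else {
    sub <- subspace_eigen(G, k)
    vec <- sub$vectors
    val <- sub$values
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(vectors = vec, values = val,
                 source = if (inherits(grm, "grm")) grm$source else "matrix"),
            class = "pc_set")
}

# blocked orthogonal iteration for the top-k eigenpairs of a symmetric matrix;
# deterministic start (fixed RNG stream), fixed iteration count
subspace_eigen <- function(G, k, n_iter = 40L, oversample = 10L) {
  n <- nrow(G)
  kk <- min(n - 1L, k + oversample)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(760013L)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * kk), n, kk)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  for (i in seq_len(n_iter)) {
    Q <- qr.Q(qr(G %*% Q))
  }
  S <- crossprod(Q, G %*% Q)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(vectors = (Q %*% e$vectors)[, seq_len(k), drop = FALSE],
       values = e$values[seq_len(k)])
}

#' Variance in one component explained by a set of predictors
#'
#' R-squared of the ordinary least squares regression of `target` on all
#' predictor columns plus an intercept. Used to ask how much of, say, rare-PC1
#' is spanned by the 100 common-variant PCs.
#'
#' @param target Numeric vector (e.g. one PC).
#' @param predictors A `pc_set` or numeric matrix with the same individuals.
#' @export
variance_explained <- function(target, predictors) {
  P <- if (inherits(predictors, "pc_set")) predictors$vectors else as.matrix(predictors)
  n <- length(target)
  stopifnot(nrow(P) == n)
  if (ncol(P) >= n) stop("more predictors than observations")
  fit <- stats::lm.fit(cbind(1, P), target)
  1 - sum(fit$residuals^2) / sum((target - mean(target))^2)
}

#' Write principal components as TSV
#' @param pcs A `pc_set`.
#' @param ids Individual ids.
#' @param path Output path.
#' @export
write_pcs <- function(pcs, ids, path) {
  df <- data.frame(id = ids, pcs$vectors)
  names(df) <- c("id", paste0("PC", seq_len(ncol(pcs$vectors))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
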