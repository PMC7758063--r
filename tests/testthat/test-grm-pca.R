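test_that("genotype GRM matches hand-computed standardization", {
  # 3 individuals x 2 variants, worked by hand
  dos <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L))
  p <- rowMeans(dos) / 2
  Z <- (dos - 2 * p) / sqrt(2 * p * (1 - p))
  G <- compute_grm(dos, chunk = 1L)
  expect_equal(G$matrix, crossprod(Z) / 2, tolerance = 1e-12)
  expect_equal(G$n_variants, 2L)

  # duplicated individual: off-diagonal equals the smaller diagonal entry
  dup <- cbind(dos, dos[, 1])
  Gd <- compute_grm(dup)$matrix
  expect_equal(Gd[1, 4], min(Gd[1, 1], Gd[4, 4]), tolerance = 1e-12)

  # monomorphic rows are excluded with a warning
  expect_warning(compute_grm(rbind(dos, c(0L, 0L, 0L))), "monomorphic")
  expect_error(compute_grm(dos[1, , drop = FALSE]), "two variants")
})

test_that("panmictic individuals have near-zero mean relatedness", {
  ds <- panmictic_cohort()
  dos <- get_dosages(ds, class = "common")
  G <- compute_grm(dos)$matrix
  off <- G[upper.tri(G)]
  n <- ncol(G)
  # sample-frequency standardization centers rows exactly, so
  # mean(off) = -mean(diag)/(n-1) identically; both shrink to 0 at large n
  expect_equal(mean(off), -mean(diag(G)) / (n - 1), tolerance = 1e-10)
  expect_lt(abs(mean(off)), 0.05)
  expect_equal(mean(diag(G)), 1, tolerance = 0.1)
})

test_that("pca recovers closed-form structure and fixes signs", {
  # rank-1 matrix: PC1 proportional to v (after centering, use centered v)
  v <- c(2, -1, 3, 0.5, -2, 1, -3.5)
  v <- v - mean(v)
  pcs <- pca(tcrossprod(v), k = 2)
  expect_equal(abs(cor(pcs$vectors[, 1], v)), 1, tolerance = 1e-8)
  expect_equal(pcs$values[1], sum(v^2), tolerance = 1e-8)
  # sign rule: the largest-magnitude loading is positive
  expect_gt(pcs$vectors[which.max(abs(pcs$vectors[, 1])), 1], 0)

  # identity GRM: degenerate spectrum, but the sign rule keeps it deterministic
  a <- pca(diag(9), k = 3)
  b <- pca(diag(9), k = 3)
  expect_equal(a$vectors, b$vectors)
  expect_error(pca(diag(9), k = 9), "smaller")

  # orthonormal columns, non-increasing values
  set.seed(9)
  S <- crossprod(matrix(rnorm(200 * 30), 200, 30)) / 200
  pcs2 <- pca(S, k = 5)
  expect_equal(crossprod(pcs2$vectors), diag(5), tolerance = 1e-8)
  expect_true(all(diff(pcs2$values) <= 1e-10))
})

test_that("subspace iteration agrees with the full eigendecomposition", {
  set.seed(10)
  # spiked matrix with a clear spectral gap
  u <- qr.Q(qr(matrix(rnorm(300 * 5), 300, 5)))
  S <- u %*% diag(c(50, 40, 30, 20, 10)) %*% t(u) +
    crossprod(matrix(rnorm(100 * 300), 100, 300)) / 100
  full <- pca(S, k = 4, method = "full")
  sub <- pca(S, k = 4, method = "subspace")
  expect_equal(sub$values, full$values, tolerance = 1e-6)
  for (j in 1:4)
    expect_gt(abs(cor(sub$vectors[, j], full$vectors[, j])), 0.9999)
})

test_that("PCs separate strongly diverged demes", {
  ds <- twopop_cohort()
  dos <- get_dosages(ds, class = "common")
  pcs <- pca(compute_grm(dos), k = 5)
  is_b <- as.integer(sample_table(ds)$deme == "d1")
  expect_gt(abs(cor(pcs$vectors[, 1], is_b)), 0.9)
})

test_that("pca is invariant (up to sign) to individual ordering", {
  ds <- twopop_cohort()
  dos <- get_dosages(ds, class = "common")
  G <- compute_grm(dos)$matrix
  perm <- sample(nrow(G))
  p1 <- pca(G, k = 3)
  p2 <- pca(G[perm, perm], k = 3)
  for (j in 1:3)
    expect_equal(abs(cor(p2$vectors[, j], p1$vectors[perm, j])), 1,
                 tolerance = 1e-6)
})

test_that("variance explained spans the expected limits", {
  set.seed(12)
  P <- matrix(rnorm(50 * 4), 50, 4)
  target_in <- P %*% c(1, -2, 0.5, 3) + 5
  expect_equal(variance_explained(target_in, P), 1, tolerance = 1e-10)
  # orthogonal target
  resid <- lm.fit(cbind(1, P), rnorm(50))$residuals
  expect_lt(variance_explained(resid, P), 1e-10)
  expect_error(variance_explained(rnorm(3), matrix(rnorm(9), 3, 3)),
               "more predictors")
})

test_that("exact IBD sharing from genealogies behaves sensibly", {
  ds <- tiny_cohort()
  # above 10 cM nothing is shared on a 0.2 Mb chromosome (segments too short)
  K10 <- ibd_sharing_grm(ds, min_segment_cM = 10)
  expect_equal(unique(diag(K10$matrix)), 1)
  expect_true(all(K10$matrix[upper.tri(K10$matrix)] == 0))
  # with a permissive threshold sharing appears, bounded by [0, 1]
  K <- ibd_sharing_grm(ds, min_segment_cM = 0.005)
  off <- K$matrix[upper.tri(K$matrix)]
  expect_gt(mean(off), 0)
  expect_true(all(off >= 0 & off <= 1))
  # deleting the genealogy store makes the computation fail loudly
  ds2 <- ds; ds2$dir <- tempfile()
  expect_error(ibd_sharing_grm(ds2), "genealogies")
})
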