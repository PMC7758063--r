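test_that("per-variant OLS matches the normal equations to 1e-12", {
  # n = 5 toy with a covariate, solved via solve(t(X)X) directly
  y <- c(2.1, -0.3, 1.7, 0.4, -1.2)
  x <- c(0, 1, 2, 1, 0)
  cov1 <- c(0.5, -1, 0.2, 2, -0.7)
  dos <- matrix(x, nrow = 1)
  ss <- gwas_linear(dos, y, covariates = matrix(cov1))
  D <- cbind(1, cov1, x)
  bhat <- solve(crossprod(D), crossprod(D, y))
  expect_equal(ss$beta, bhat[3], tolerance = 1e-12)
  resid <- y - D %*% bhat
  s2 <- sum(resid^2) / (5 - 3)
  se <- sqrt(s2 * solve(crossprod(D))[3, 3])
  expect_equal(ss$se, se, tolerance = 1e-12)
  expect_equal(ss$p, 2 * pt(-abs(bhat[3] / se), df = 2), tolerance = 1e-12)

  # no-covariate version against lm()
  fit <- lm(y ~ x)
  ss0 <- gwas_linear(dos, y)
  expect_equal(ss0$beta, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(ss0$p, summary(fit)$coefficients[2, 4], tolerance = 1e-12)
})

test_that("permuted phenotypes give uniform p-values", {
  set.seed(40)
  n <- 400; M <- 1500
  dos <- matrix(rbinom(n * M, 2, 0.3), nrow = M)
  y <- rnorm(n)
  ss <- gwas_linear(dos, sample(y))
  expect_gt(ks.test(ss$p, "punif")$p.value, 1e-3)
  expect_lt(abs(genomic_inflation(ss$chisq, 0.5)$lambda - 1), 0.1)
})

test_that("constant dosages are flagged, not fatal", {
  dos <- rbind(rep(1L, 20), rbinom(20, 2, 0.5))
  ss <- gwas_linear(dos, rnorm(20))
  expect_true(is.na(ss$beta[1]))
  expect_false(is.na(ss$beta[2]))
})

test_that("OLS is invariant to rotation of orthonormal covariates", {
  set.seed(41)
  n <- 120; k <- 6
  dos <- matrix(rbinom(n * 40, 2, 0.4), nrow = 40)
  y <- rnorm(n)
  C <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  R <- qr.Q(qr(matrix(rnorm(k * k), k, k)))  # random rotation
  s1 <- gwas_linear(dos, y, covariates = C)
  s2 <- gwas_linear(dos, y, covariates = C %*% R)
  expect_equal(s1$beta, s2$beta, tolerance = 1e-10)
  expect_equal(s1$p, s2$p, tolerance = 1e-10)
})

test_that("LOCO mixed model reduces to OLS at zero variance component", {
  set.seed(42)
  n <- 80
  v <- data.frame(chrom = rep(1:2, each = 30), row = rep(1:30, 2),
                  pos = rep(1:30, 2), dcount = 1L)
  dos <- matrix(rbinom(n * 60, 2, 0.35), nrow = 60)
  attr(dos, "variants") <- v
  y <- rnorm(n)
  lin <- gwas_linear(dos, y)
  lmm <- gwas_lmm_loco(dos, y, dos, forced_h2 = 0)
  expect_equal(lmm$beta, lin$beta, tolerance = 1e-8)
  expect_equal(lmm$chisq, lin$chisq, tolerance = 1e-6)
})

test_that("LOCO variance component is near zero for unstructured traits", {
  set.seed(43)
  n <- 100
  v <- data.frame(chrom = rep(1:2, each = 40), row = rep(1:40, 2),
                  pos = rep(1:40, 2), dcount = 1L)
  dos <- matrix(rbinom(n * 80, 2, 0.3), nrow = 80)
  attr(dos, "variants") <- v
  y <- rnorm(n)
  lmm <- gwas_lmm_loco(dos, y, dos)
  expect_lt(mean(lmm$h2), 0.35)
  expect_lt(abs(genomic_inflation(lmm$chisq[!is.na(lmm$chisq)], 0.5)$lambda - 1),
            0.35)
})

test_that("sibling-difference regression is unbiased and guarded", {
  expect_error(sib_difference_test(matrix(0L, 1, 10), rnorm(10)), "zero")

  # parameter recovery over 200 replicates: mean within 2 MC standard errors
  set.seed(44)
  beta_true <- 0.7
  ests <- vapply(1:200, function(i) {
    dx <- sample(c(-1L, 0L, 1L), 60, replace = TRUE)
    dy <- beta_true * dx + rnorm(60)
    sib_difference_test(dx, dy)$beta
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(200)
  expect_lt(abs(mean(ests) - beta_true), 3 * mc_se)
})

test_that("tail inflation flags tail-only signals and delegates", {
  set.seed(45)
  stats <- qchisq((1:20000) / 20001, df = 1)
  expect_equal(tail_inflation(stats, p = 0.999)$lambda, 1, tolerance = 0.02)
  # replace the top 0.1% with huge statistics: tail blows up, median doesn't
  spiked <- stats
  spiked[sample(20000, 40)] <- 200
  expect_gt(tail_inflation(spiked, p = 0.999)$lambda, 5)
  expect_lt(abs(tail_inflation(spiked, p = 0.5)$lambda - 1), 0.05)
  # delegation: identical input via both call paths
  df <- data.frame(chisq = spiked)
  expect_identical(tail_inflation(df, p = 0.999)$lambda,
                   genomic_inflation(spiked, 0.999)$lambda)
  expect_error(tail_inflation(stats[1:100], p = 0.999), "too few")
})
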