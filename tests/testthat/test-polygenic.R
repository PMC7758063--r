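toy_sumstats <- function() {
  # 7 variants, 2 causal windows, printed p-values
  data.frame(chrom = c(1, 1, 1, 1, 1, 2, 2),
             pos = c(1e4, 4e4, 6e4, 1.2e5, 1.45e5, 2e4, 6e4),
             freq = 0.2,
             beta = c(0.5, -0.2, 0.9, 0.1, -0.6, 0.3, 0.2),
             se = 0.1,
             chisq = 1,
             p = c(2e-4, 1e-5, 3e-3, 4e-4, 2e-6, 0.5, 0.01))
}

toy_causal <- function() data.frame(chrom = c(1, 1, 2), pos = c(3e4, 1.3e5, 5e4))

test_that("lead-SNP ascertainment equals the brute-force scan", {
  ss <- toy_sumstats(); cz <- toy_causal()
  sel <- ascertain_lead_snps(ss, cz)
  ref <- lead_snp_reference(ss, cz)
  expect_equal(sort(match(paste(sel$chrom, sel$pos), paste(ss$chrom, ss$pos))),
               ref)
  # window 1 picks pos 4e4 (min p), window 2 picks pos 1.45e5;
  # chromosome-2 window has no sub-threshold variant and is dropped
  expect_equal(sel$pos, c(4e4, 1.45e5))
  expect_equal(sel$window, c(1, 2))

  # causal mode: only the causal variants themselves, under the threshold
  ss2 <- ss
  ss2$pos[1] <- 3e4  # make the causal variant itself present and significant
  selc <- ascertain_lead_snps(ss2, cz, mode = "causal")
  expect_equal(selc$pos, 3e4)

  # ties broken by smaller position
  ss3 <- ss
  ss3$p[c(1, 2)] <- 1e-5
  sel3 <- ascertain_lead_snps(ss3, cz)
  expect_equal(sel3$pos[1], 1e4)
})

test_that("polygenic scores are dot products with missingness accounting", {
  v <- data.frame(chrom = c(1, 1, 2), row = 1:3, pos = c(10, 20, 30),
                  dcount = c(2L, 3L, 1L))
  dos <- structure(rbind(c(0L, 1L, 2L), c(2L, 0L, 1L), c(1L, 1L, 0L)),
                   variants = v)
  eff <- data.frame(chrom = c(1, 2), pos = c(20, 30), beta = c(1, -2))
  sc <- compute_pgs(eff, dos)
  expect_equal(as.vector(sc), c(2 * 1 - 2 * 1, 0 * 1 - 2 * 1, 1 * 1 - 0))
  expect_equal(attr(sc, "n_missing"), 0L)

  eff0 <- data.frame(chrom = 1, pos = c(20, 999), beta = c(0, 0))
  sc0 <- compute_pgs(eff0, dos)
  expect_true(all(sc0 == 0))
  expect_equal(attr(sc0, "n_missing"), 1L)

  one <- data.frame(chrom = 1, pos = 10, beta = 1)
  expect_equal(as.vector(compute_pgs(one, dos)), c(0, 1, 2))
})

test_that("residual maps isolate bias and preserve shifts", {
  g <- rnorm(60)
  demes <- rep(c("d0", "d1", "d2"), each = 20)
  m0 <- residual_map(g, g, demes)
  expect_true(all(m0$mean_residual == 0))
  mc <- residual_map(g + 1.5, g, demes)
  expect_true(all(abs(mc$mean_residual - 1.5) < 1e-12))
  # unobserved deme: NA, never zero
  m3 <- residual_map(g, g - 1, demes, all_demes = c("d0", "d1", "d2", "d3"))
  expect_true(is.na(m3$mean_residual[m3$deme == "d3"]))
  expect_equal(m3$n[m3$deme == "d3"], 0L)
  expect_true(all(abs(m3$mean_residual[1:3] - 1) < 1e-12))
})

test_that("prediction accuracy is the squared correlation with guards", {
  g <- rnorm(100)
  expect_equal(prediction_accuracy(g, g), 1)
  set.seed(50)
  expect_lt(prediction_accuracy(rnorm(100), g), 0.1)
  expect_warning(acc0 <- prediction_accuracy(rep(1, 100), g), "zero variance")
  expect_equal(acc0, 0)
})

test_that("effect reestimation enforces cohort independence", {
  lead <- data.frame(chrom = 1, pos = 10, beta = 1)
  expect_error(
    reestimate_effects(lead, "unrelated", dosages = structure(
      matrix(0L, 1, 4), variants = data.frame(chrom = 1, pos = 10)),
      phenotype = rnorm(4),
      discovery_ids = c("a", "b"), second_ids = c("b", "c")),
    "independence")
})

test_that("reestimated effects are unbiased in an unstructured cohort", {
  set.seed(51)
  n <- 500
  reps <- vapply(1:100, function(i) {
    x <- rbinom(n, 2, 0.4)
    y <- 0.4 * x + rnorm(n)
    dos <- structure(matrix(as.integer(x), 1, n),
                     variants = data.frame(chrom = 1, row = 1, pos = 10,
                                           dcount = sum(x)))
    lead <- data.frame(chrom = 1, pos = 10, beta = NA)
    reestimate_effects(lead, "unrelated", dosages = dos, phenotype = y)$beta
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.4), 2 * sd(reps) / sqrt(100) + 1e-9)
})

test_that("map gradient summarizes the north-south axis", {
  g6 <- grid_spec(6, 6)
  map <- data.frame(deme = g6$coords$deme,
                    mean_residual = g6$coords$row * 0.5,
                    n = 10)
  expect_equal(map_gradient(map, g6), 1)
  map$mean_residual <- -g6$coords$row
  expect_equal(map_gradient(map, g6), -1)
})
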