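test_that("smooth and sharp environments follow the 2-sigma convention", {
  g6 <- grid_spec(6, 6)
  sm <- environment_spec("smooth", sigma = 1)
  mu <- stratsim:::deme_means(sm, g6)
  expect_equal(as.vector(tapply(mu, g6$coords$row, unique)),
               c(0, 0.4, 0.8, 1.2, 1.6, 2.0))

  sh <- environment_spec("sharp", sigma = 1, affected_deme = "d14")
  mu2 <- stratsim:::deme_means(sh, g6)
  expect_equal(unname(mu2["d14"]), 2)
  expect_true(all(mu2[names(mu2) != "d14"] == 0))
  expect_error(environment_spec("sharp", 1), "affected deme")

  # sigma = 0: phenotype equals the deme mean exactly
  samples <- data.frame(id = paste0("s", 1:36), deme = g6$deme_ids)
  env <- make_environment(environment_spec("smooth", 0), samples, g6, seed = 1)
  expect_equal(env$values, env$mu)
  expect_true(all(env$noise == 0))
})

test_that("causal variant selection picks one per 100 kb window", {
  v <- data.frame(chrom = rep(1:2, each = 50),
                  row = rep(1:50, 2),
                  pos = rep(seq(0, 9.8e5, by = 2e4), 2),
                  dcount = 5L)
  sel <- select_causal_variants(v, window_bp = 1e5, seed = 3)
  expect_equal(nrow(sel), 20)  # 10 windows x 2 chromosomes
  expect_true(all(table(sel$window) == 1))

  single <- data.frame(chrom = 1, row = 1, pos = 50, dcount = 2L)
  expect_equal(select_causal_variants(single, seed = 1)$row, 1)

  # uniformity within a 5-variant window
  win5 <- data.frame(chrom = 1, row = 1:5, pos = seq(10, 90, by = 20), dcount = 1L)
  picks <- vapply(1:1000, function(s)
    select_causal_variants(win5, seed = s)$row, integer(1))
  counts <- table(factor(picks, levels = 1:5))
  expect_gt(chisq.test(counts)$p.value, 1e-4)

  expect_warning(select_causal_variants(single, seed = 1, n_windows = 3),
                 "windows hold no variant")
})

test_that("effect sizes satisfy the variance normalization", {
  set.seed(20)
  p <- runif(300, 0.01, 0.99)
  # alpha = 0: shared variance h2 / sum(2p(1-p))
  e0 <- draw_effects(p, alpha = 0, h2 = 0.8, seed = 5)
  expect_equal(e0$sigma_l2, 0.8 / sum(2 * p * (1 - p)), tolerance = 1e-12)

  # alpha = -1: every variant contributes equally to genetic variance
  e1 <- draw_effects(p, alpha = -1, h2 = 0.8, seed = 5)
  contrib <- e1$sigma_l2 * (2 * p * (1 - p))^(-1) * 2 * p * (1 - p)
  expect_equal(contrib, rep(e1$sigma_l2, 300), tolerance = 1e-12)
  expect_equal(sum(contrib), 0.8, tolerance = 1e-12)

  expect_error(draw_effects(c(0.5, 1)), "in \\(0, 1\\)")

  # Monte-Carlo check of Var(g) = h2 over effect redraws at fixed genotypes
  n <- 600; M <- 150
  pf <- runif(M, 0.05, 0.95)
  X <- matrix(rbinom(n * M, 2, rep(pf, each = n)), nrow = M, byrow = TRUE)
  pk <- rowMeans(X) / 2
  vars <- vapply(1:50, function(s) {
    eff <- draw_effects(pk, alpha = -0.4, h2 = 0.8, seed = 1000 + s)
    var(genetic_values(X, eff$beta))
  }, numeric(1))
  expect_lt(abs(mean(vars) - 0.8), 0.05)

  # magnitude decreases with heterozygosity for negative alpha
  eff <- draw_effects(pk, alpha = -0.4, h2 = 0.8, seed = 77)
  expect_lt(cor(abs(eff$beta), pk * (1 - pk), method = "spearman"), 0)
})

test_that("phenotype assembly keeps its true decomposition", {
  g6 <- grid_spec(6, 6)
  samples <- data.frame(id = paste0("s", 1:360),
                        deme = rep(g6$deme_ids, each = 10))
  env <- make_environment(environment_spec("smooth", 1), samples, g6, seed = 2)
  ph <- assemble_phenotype(0, env, samples)
  expect_equal(ph$y, ph$env_mean + ph$noise)
  expect_true(all(ph$g == 0))

  # h2 = 0.8 trait without structured environment: Var(g)/Var(y) ~ 0.8
  set.seed(30)
  n <- 4000
  gvals <- rnorm(n, 0, sqrt(0.8))
  samples2 <- data.frame(id = seq_len(n), deme = "d0")
  env2 <- make_environment(environment_spec("sharp", sqrt(0.2),
                                            affected_deme = "d99"),
                           samples2, grid_spec(10, 10), seed = 3)
  # affected deme absent from the sample: pure noise environment
  ph2 <- assemble_phenotype(gvals, env2, samples2)
  expect_equal(var(ph2$g) / var(ph2$y), 0.8, tolerance = 0.05)

  # degenerate inputs give a constant phenotype
  env0 <- make_environment(environment_spec("smooth", 0),
                           samples2[1:5, ], grid_spec(1, 1), seed = 4)
  ph0 <- assemble_phenotype(rep(1, 5), env0, samples2[1:5, ])
  expect_true(all(ph0$y == 1))

  expect_error(assemble_phenotype(c(1, 2), env0, samples2[1:5, ]))
})

test_that("smooth-environment regression recovers the row gradient", {
  g6 <- grid_spec(6, 6)
  samples <- data.frame(id = seq_len(3600), deme = rep(g6$deme_ids, each = 100))
  env <- make_environment(environment_spec("smooth", 1), samples, g6, seed = 8)
  ph <- assemble_phenotype(0, env, samples)
  rows <- g6$coords$row[match(samples$deme, g6$coords$deme)]
  slope <- coef(lm(ph$y ~ rows))[2]
  expect_equal(unname(slope), 2 / 5, tolerance = 0.1)
})

test_that("derived seeds are deterministic, distinct, and in range", {
  s1 <- derive_seed(1, "env", 1)
  expect_identical(s1, derive_seed(1, "env", 1))
  expect_false(s1 == derive_seed(1, "env", 2))
  expect_false(s1 == derive_seed(1, "effects", 1))
  expect_false(s1 == derive_seed(2, "env", 1))
  seeds <- vapply(1:500, function(i) derive_seed(123, "stage", i), integer(1))
  expect_true(all(seeds > 0 & seeds < 2^31))
})
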