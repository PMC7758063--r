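# a hand-built gene set: 2 genes, 2,000 individuals, known carriers
toy_gene_set <- function() {
  variants <- data.frame(
    gene = c(1L, 1L, 1L, 1L, 2L, 2L),
    pos = c(10, 50, 90, 300, 20, 40),
    dcount = c(2L, 1L, 4L, 3L, 500L, 2L),
    exonic = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  carriers <- data.frame(
    gene = c(1L, 1L, 1L, 1L, 1L, 2L, 2L),
    vrow = c(1L, 1L, 2L, 3L, 4L, 1L, 2L),
    ind = c(1L, 2L, 3L, 1L, 1L, 4L, 4L),
    dosage = c(1L, 1L, 1L, 1L, 1L, 2L, 2L))
  structure(list(variants = variants, carriers = carriers,
                 samples = data.frame(id = paste0("s", 1:2000),
                                      deme = rep(c("a", "b"), 1000)),
                 n_individuals = 2000L, n_haplotypes = 4000L, n_genes = 2L,
                 model = gene_model(), retained = NULL), class = "gene_set")
}

test_that("gene burden counts rare exonic derived alleles only", {
  gs <- toy_gene_set()
  B <- gene_burden(gs, threshold = 0.001)
  # threshold is strict: dcount 4 (freq exactly 0.001) is excluded, 2 counts
  # individual 1 carries v1 (rare, 1 copy), v3 (freq 0.001, excluded) and
  # v4 (intronic): burden 1
  expect_equal(B[1, 1], 1L)
  expect_equal(B[1, 2], 1L)  # v1 only
  expect_equal(B[1, 3], 1L)  # v2 only
  # gene 2: v5 common (excluded), v6 rare with a homozygous carrier
  expect_equal(B[2, 4], 2L)
  expect_equal(sum(B[2, -4]), 0L)
  # single-gene extraction agrees
  expect_equal(gene_burden(gs, gene = 2L), B[2, ])
})

test_that("burden is zero when all variants are common", {
  gs <- toy_gene_set()
  gs$variants$dcount <- c(500L, 600L, 700L, 650L, 500L, 800L)
  B <- gene_burden(gs)
  expect_true(all(B == 0L))
})

test_that("the Gini coefficient matches its closed forms", {
  expect_equal(gini_coefficient(rep(5, 36)), 0, tolerance = 1e-15)
  expect_equal(gini_coefficient(c(rep(0, 35), 7)), 35 / 36, tolerance = 1e-15)
  expect_equal(gini_coefficient(c(0.1, 0.3, 0.6)), 1 / 3, tolerance = 1e-12)
  # invariances: deme relabeling (order) and overall scale
  x <- c(4, 0, 2, 9, 1)
  expect_equal(gini_coefficient(sample(x)), gini_coefficient(x))
  expect_equal(gini_coefficient(10 * x), gini_coefficient(x))
  expect_error(gini_coefficient(rep(0, 5)), "all deme burdens are zero")
  expect_error(gini_coefficient(5), "two demes")
  expect_error(gini_coefficient(c(-1, 2)), "non-negative")
})

test_that("variant-count matching thins to the target distribution", {
  # build a synthetic gene set with many rare variants per gene
  set.seed(60)
  n_genes <- 300L
  per <- 40L
  variants <- data.frame(
    gene = rep(seq_len(n_genes), each = per),
    pos = rep(seq_len(per), n_genes),
    dcount = 2L,
    exonic = TRUE)
  carriers <- data.frame(gene = variants$gene,
                         vrow = rep(seq_len(per), n_genes),
                         ind = sample(5000L, nrow(variants), replace = TRUE),
                         dosage = 1L)
  gs <- structure(list(variants = variants, carriers = carriers,
                       samples = data.frame(id = 1:5000, deme = "a"),
                       n_individuals = 5000L, n_haplotypes = 10000L,
                       n_genes = n_genes, model = gene_model(),
                       retained = NULL), class = "gene_set")
  thinned <- match_variant_counts(gs, target_mean = 16, target_sd = 4, seed = 2)
  counts <- rare_variant_counts(thinned)
  expect_equal(mean(counts), 16, tolerance = 1)
  expect_equal(sd(counts), 4, tolerance = 1)
  set.seed(99)
  expect_gt(ks.test(counts + runif(length(counts), -0.4, 0.4),
                    function(q) pnorm(q, 16, 4))$p.value, 1e-4)
  # carriers untouched: thinning only masks variants
  expect_identical(thinned$carriers, gs$carriers)
  # target 0 -> all burden zero
  zeroed <- match_variant_counts(gs, target_mean = 0, target_sd = 0, seed = 3)
  expect_true(all(rare_variant_counts(zeroed) == 0))
})

test_that("burden association has uniform p under permutation and skips", {
  set.seed(61)
  n <- 600
  B <- matrix(rpois(200 * n, 2), nrow = 200)
  y <- rnorm(n)
  res <- burden_association(B, y)
  expect_gt(ks.test(res$p, "punif")$p.value, 1e-3)
  # constant burden is skipped with NA
  B2 <- rbind(rep(3L, n), B[1, ])
  res2 <- burden_association(B2, y)
  expect_true(is.na(res2$beta[1]))
  expect_false(is.na(res2$beta[2]))
})
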