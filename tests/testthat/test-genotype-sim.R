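test_that("cohort simulation is deterministic per seed", {
  dem <- build_demography("recent", grid_spec(2, 2), m = 0.05)
  g <- genome_spec(1, 1e5)
  a <- simulate_cohort(dem, g, 5, seed = 99)
  b <- simulate_cohort(dem, g, 5, seed = 99)
  expect_equal(a$variants, b$variants)
  expect_equal(unclass(get_dosages(a)), unclass(get_dosages(b)),
               ignore_attr = TRUE)
  unlink(c(a$dir, b$dir), recursive = TRUE)
})

test_that("zero mutation rate yields zero variants", {
  dem <- build_demography("recent", grid_spec(2, 2), m = 0.05)
  ds <- simulate_cohort(dem, genome_spec(1, 1e5, mutation_rate = 0), 5, seed = 7)
  expect_equal(nrow(ds$variants), 0L)
  unlink(ds$dir, recursive = TRUE)
})

test_that("segregating-site count matches the Watterson expectation", {
  # single deme: ordinary coalescent with Ne = 10,000
  dem <- build_demography("recent", grid_spec(1, 1), m = 0)
  ds <- cached("watterson", function()
    simulate_cohort(dem, genome_spec(4, 2.5e5), 100, seed = 88))
  nhap <- 200
  theta <- 4 * 10000 * 1e-8 * 1e6
  expected <- theta * sum(1 / seq_len(nhap - 1))
  expect_lt(abs(nrow(ds$variants) / expected - 1), 0.2)
})

test_that("variant classes follow the study definitions", {
  toy <- list(variants = data.frame(chrom = 1, row = 1:6,
                                    pos = (1:6) * 10,
                                    dcount = c(900L, 901L, 3L, 17L, 0L, 18000L)),
              n_haplotypes = 18000L)
  # MAF exactly 0.05 (900/18000) is NOT common: strict inequality
  common <- classify_variants(toy, "common")
  expect_equal(common$dcount, 901L)
  # 3 copies in 18,000 haplotypes: both MAC 2-4 and frequency < 0.001
  expect_equal(classify_variants(toy, "rare_mac")$dcount, 3L)
  expect_true(3L %in% classify_variants(toy, "ultra_rare")$dcount)
  expect_true(17L %in% classify_variants(toy, "ultra_rare")$dcount)
  # monomorphic columns belong to no class
  for (cl in c("common", "rare_mac", "ultra_rare"))
    expect_false(any(classify_variants(toy, cl)$dcount %in% c(0L, 18000L)))
})

test_that("variant subsampling is uniform, seeded, and guarded", {
  vs <- data.frame(chrom = 1, row = 1:100, pos = 1:100, dcount = 5L)
  expect_equal(nrow(subsample_variants(vs, 100, seed = 1)), 100)
  expect_equal(nrow(subsample_variants(vs, 0, seed = 1)), 0)
  expect_error(subsample_variants(vs, 101, seed = 1), "exceeds")
  s1 <- subsample_variants(vs, 40, seed = 1)
  s1b <- subsample_variants(vs, 40, seed = 1)
  expect_equal(s1, s1b)
  # overlap of two independent draws near the hypergeometric expectation k^2/N
  ov <- replicate(40, {
    a <- subsample_variants(vs, 40, seed = sample.int(1e6, 1))$row
    b <- subsample_variants(vs, 40, seed = sample.int(1e6, 1))$row
    length(intersect(a, b))
  })
  expect_lt(abs(mean(ov) - 40^2 / 100), 2)
})

test_that("train/test split is stratified, disjoint, and guarded", {
  ds <- tiny_cohort()
  halves <- split_train_test(ds, 0.5)
  expect_length(intersect(halves$train$individuals, halves$test$individuals), 0)
  expect_equal(sort(c(halves$train$individuals, halves$test$individuals)),
               seq_len(ds$n_individuals))
  tr_by_deme <- table(sample_table(halves$train)$deme)
  te_by_deme <- table(sample_table(halves$test)$deme)
  expect_true(all(tr_by_deme == 6))
  expect_true(all(te_by_deme == 6))
  expect_error(split_train_test(ds, 1.0), "inside \\(0, 1\\)")
})

test_that("VCF export round-trips the dosage matrix", {
  skip_if_not_installed("vcfR")
  ds <- tiny_cohort()
  vs <- classify_variants(ds, "common")
  vs <- vs[seq_len(min(8, nrow(vs))), ]
  path <- tempfile(fileext = ".vcf")
  export_vcf(ds, path, variants = vs)
  back <- import_vcf_dosages(path)
  orig <- get_dosages(ds, variants = vs)
  expect_equal(back, unclass(orig), ignore_attr = TRUE)

  # header-only VCF for an empty variant set
  path2 <- tempfile(fileext = ".vcf")
  export_vcf(ds, path2, variants = vs[0, ])
  lines <- readLines(path2)
  expect_true(all(startsWith(lines, "#")))

  # hand-checked GT encoding on a 3-variant toy
  toy <- vs[1:3, ]
  path3 <- tempfile(fileext = ".vcf")
  export_vcf(ds, path3, variants = toy)
  body <- readLines(path3)
  body <- body[!startsWith(body, "#")]
  dos <- get_dosages(ds, variants = toy)
  gt_field <- strsplit(body[1], "\t")[[1]][-(1:9)]
  expect_equal(gt_field, c("0/0", "0/1", "1/1")[dos[1, ] + 1])
  unlink(c(path, path2, path3))
})

test_that("summary-table export writes samples, variants, and metadata", {
  ds <- tiny_cohort()
  out <- tempfile()
  export_summary_tables(ds, out)
  expect_true(file.exists(file.path(out, "samples.tsv")))
  expect_true(file.exists(file.path(out, "variants.tsv")))
  meta <- jsonlite::fromJSON(file.path(out, "run_meta.json"))
  expect_equal(meta$seed, ds$seed)
  expect_equal(meta$model, "recent")
  unlink(out, recursive = TRUE)
})
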