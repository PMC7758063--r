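test_that("grid migration matrix follows rook adjacency", {
  g <- grid_spec(6, 6)
  M0 <- build_grid_migration_matrix(g, 0)
  expect_true(all(M0 == 0))

  M <- build_grid_migration_matrix(g, 0.05)
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 0))
  # brute-force rook neighbour enumeration
  deg_expected <- sapply(seq_len(36) - 1L, function(i) {
    r <- i %/% 6; c <- i %% 6
    sum(c(r > 0, r < 5, c > 0, c < 5))
  })
  deg <- rowSums(M > 0)
  expect_equal(unname(deg), deg_expected)
  expect_true(all(M[M > 0] == 0.05))
  # corners have 2 neighbours, edges 3, interior 4
  expect_equal(sort(unique(deg_expected)), c(2, 3, 4))

  M2 <- build_grid_migration_matrix(grid_spec(2, 2), 0.1)
  expect_equal(unname(rowSums(M2 > 0)), rep(2, 4))

  expect_error(build_grid_migration_matrix(g, -0.1), "non-negative")
})

test_that("adjacency migration matrix matches the edge list", {
  empty <- build_adjacency_migration_matrix(matrix(character(0), 0, 2), 0.1,
                                            deme_ids = c("a", "b"))
  expect_true(all(empty == 0))

  path3 <- rbind(c("a", "b"), c("b", "c"))
  M <- build_adjacency_migration_matrix(path3, 0.08)
  expect_equal(unname(rowSums(M > 0)[c("a", "b", "c")]), c(1, 2, 1))
  expect_equal(M["a", "b"], 0.08)
  expect_true(isSymmetric(M))

  expect_error(build_adjacency_migration_matrix(rbind(c("a", "a")), 0.1),
               "self-adjacency")
})

test_that("shipped synthetic region fixture builds a consistent matrix", {
  fx <- england_wales_fixture()
  expect_length(fx$deme_ids, 35)
  expect_equal(sum(fx$weights), 1, tolerance = 1e-6)
  M <- build_adjacency_migration_matrix(fx$adjacency, 0.08,
                                        deme_ids = fx$deme_ids)
  deg_fixture <- table(factor(c(fx$adjacency$deme_a, fx$adjacency$deme_b),
                              levels = fx$deme_ids))
  expect_equal(unname(rowSums(M > 0)), as.vector(deg_fixture))
  # one region is heavily down-weighted (Cornwall-like sampling)
  expect_lt(min(fx$weights), 0.3 / 35)
})

test_that("demography specs encode the three model kinds", {
  rec <- build_demography("recent", grid_spec(6, 6), m = 0.05)
  expect_equal(rec$collapse_time, 100)
  expect_equal(length(rec$deme_ids), 36)
  expect_equal(rec$deme_Ne, 10000)
  expect_equal(rec$ancestral_Ne, 10000)

  perp <- build_demography("perpetual", grid_spec(6, 6), m = 0.07)
  expect_true(is.infinite(perp$collapse_time))

  expect_error(build_demography("complex", grid_spec(2, 2), m = 0.05),
               "admixture")
  fr <- assign_admixture_cline(grid_spec(2, 2), 1, 0)
  cx <- build_demography("complex", grid_spec(2, 2), m = 0.05,
                         admixture = admixture_spec(fr))
  expect_equal(cx$collapse_time, 100)
  expect_equal(cx$admixture$m1, 0.004)
})

test_that("admixture cline interpolates linearly by row", {
  g6 <- grid_spec(6, 6)
  flat <- assign_admixture_cline(g6, 0.5, 0.5)
  expect_true(all(flat == 0.5))

  cl <- assign_admixture_cline(g6, 1, 0)
  rows <- g6$coords$row
  expect_equal(unname(cl[rows == 0][1]), 1.0)
  expect_equal(as.vector(tapply(cl, rows, unique)),
               c(1.0, 0.8, 0.6, 0.4, 0.2, 0.0))
  # all demes within a row share a fraction
  expect_true(all(tapply(cl, rows, function(x) length(unique(x))) == 1))

  one_row <- assign_admixture_cline(grid_spec(1, 4), 0.7, 0.1)
  expect_true(all(one_row == 0.7))

  expect_error(assign_admixture_cline(g6, 1.2, 0), "\\[0, 1\\]")
})

test_that("demography JSON round trip preserves the spec", {
  fr <- assign_admixture_cline(grid_spec(6, 6), 0.8, 0.2)
  for (spec in list(
    build_demography("recent", m = 0.05),
    build_demography("perpetual", m = 0.07, perpetual_horizon = 5000),
    build_demography("complex", m = 0.08, admixture = admixture_spec(fr))
  )) {
    back <- demography_from_json(demography_to_json(spec))
    expect_equal(back$kind, spec$kind)
    expect_equal(back$migration, spec$migration)
    expect_equal(back$collapse_time, spec$collapse_time)
    expect_equal(back$deme_Ne, spec$deme_Ne)
    if (!is.null(spec$admixture))
      expect_equal(back$admixture$fractions, spec$admixture$fractions)
  }
})
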