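#' Generate sibling pairs by structured within-deme mating
#'
#' Samples parent pairs without replacement within each deme (parents are not
#' reused across pairs) and creates two children per pair. Each child
#' receives, independently for every chromosome, one of the two haplotypes of
#' each parent, without recombination — transmission is whole-haplotype per
#' chromosome. Both siblings inherit the parental deme, so they share any
#' deme-level environment exactly.
#'
#' @param dataset A `genotype_dataset` (or a view restricted to the parent
#'   pool, see [subset_individuals()]).
#' @param variants `variant_set` rows at which child genotypes are needed
#'   (e.g. the union of causal variants and ascertained lead SNPs).
#' @param n_pairs_per_deme Sibling pairs to create per deme.
#' @param seed Integer seed (mating and transmission are deterministic per seed).
#' @return A `sib_pair_set`: list with `pairs` (pair, deme, parent ids),
#'   dosage matrices `X1`, `X2` (variants x pairs) for the two siblings,
#'   `dx = X1 - X2`, and the `variants` table.
#' @export
mate_within_deme <- function(dataset, variants, n_pairs_per_deme, seed) {
  stopifnot(inherits(dataset, "genotype_dataset"), n_pairs_per_deme >= 1)
  H <- get_haplotypes(dataset, variants = variants)
  vtab <- attr(H, "variants")
  samp <- sample_table(dataset)
  demes <- unique(samp$deme)
  set.seed(as.integer(seed))
  pair_rows <- list(); P1 <- list(); P2 <- list()
  for (d in demes) {
    pool <- which(samp$deme == d)
    if (length(pool) < 2 * n_pairs_per_deme)
      stop("deme ", d, " has too few individuals for ", n_pairs_per_deme, " pairs")
    pick <- sample(pool, 2 * n_pairs_per_deme)
    P1[[d]] <- pick[seq_len(n_pairs_per_deme)]
    P2[[d]] <- pick[n_pairs_per_deme + seq_len(n_pairs_per_deme)]
  }
  p1 <- unlist(P1); p2 <- unlist(P2)
  npairs <- length(p1)
  pairs <- data.frame(pair = seq_len(npairs),
                      deme = rep(demes, each = n_pairs_per_deme),
                      parent1 = samp$id[p1], parent2 = samp$id[p2],
                      stringsAsFactors = FALSE)
  chroms <- unique(vtab$chrom)
  # one haplotype choice per (pair, child, parent, chromosome)
  draw <- array(sample(0:1, npairs * 2 * 2 * length(chroms), replace = TRUE),
                dim = c(npairs, 2, 2, length(chroms)))
  X1 <- matrix(0L, nrow(vtab), npairs)
  X2 <- matrix(0L, nrow(vtab), npairs)
  for (ci in seq_along(chroms)) {
    rows <- which(vtab$chrom == chroms[ci])
    for (k in seq_len(npairs)) {
      h1 <- 2L * p1[k] - 1L; h2 <- 2L * p2[k] - 1L
      X1[rows, k] <- H[rows, h1 + draw[k, 1, 1, ci]] + H[rows, h2 + draw[k, 1, 2, ci]]
      X2[rows, k] <- H[rows, h1 + draw[k, 2, 1, ci]] + H[rows, h2 + draw[k, 2, 2, ci]]
    }
  }
  structure(list(pairs = pairs, X1 = X1, X2 = X2, dx = X1 - X2,
                 variants = vtab, draws = draw, seed = as.integer(seed)),
            class = "sib_pair_set")
}

#' @export
print.sib_pair_set <- function(x, ...) {
  cat("<sib_pair_set>", nrow(x$pairs), "pairs,", nrow(x$variants), "variants\n")
  invisible(x)
}

#' Phenotypes for sibling pairs
#'
#' Gives each sibling y = g + mu_deme + independent noise using the same
#' causal architecture (shared effect sizes) as the discovery trait. The
#' deme-level environmental mean is identical within a pair, so it cancels
#' from the phenotype difference dy by construction.
#'
#' @param sibs A `sib_pair_set`.
#' @param causal_rows Row indices into `sibs$variants` of the causal variants.
#' @param beta Causal effect sizes aligned with `causal_rows`.
#' @param env_spec An [environment_spec()] (its sigma is the noise sd).
#' @param grid The [grid_spec()] for deme means.
#' @param seed Integer seed for the two independent noise draws.
#' @return The `sib_pair_set` with `y1`, `y2`, `dy`, `g1`, `g2` added.
#' @export
sib_phenotypes <- function(sibs, causal_rows, beta, env_spec, grid, seed) {
  stopifnot(inherits(sibs, "sib_pair_set"), length(causal_rows) == length(beta))
  g1 <- as.vector(crossprod(sibs$X1[causal_rows, , drop = FALSE], beta))
  g2 <- as.vector(crossprod(sibs$X2[causal_rows, , drop = FALSE], beta))
  mu <- deme_means(env_spec, grid)[sibs$pairs$deme]
  set.seed(as.integer(seed))
  n <- nrow(sibs$pairs)
  e1 <- stats::rnorm(n, 0, env_spec$sigma)
  e2 <- stats::rnorm(n, 0, env_spec$sigma)
  sibs$g1 <- g1; sibs$g2 <- g2
  sibs$y1 <- g1 + mu + e1
  sibs$y2 <- g2 + mu + e2
  sibs$dy <- sibs$y1 - sibs$y2
  sibs
}
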