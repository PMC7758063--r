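#' Structured environment specification
#'
#' Two spatial patterns of a non-genetic (or residual) environmental effect on
#' a grid of demes:
#' \describe{
#'   \item{smooth}{per-deme mean increases linearly with row index (a
#'     north-south gradient): mu = 0 in the northernmost row rising to
#'     2 * sigma in the southernmost, so the north-south difference is two
#'     residual standard deviations.}
#'   \item{sharp}{mu = 2 * sigma in exactly one affected deme, zero elsewhere
#'     (a local effect).}
#' }
#'
#' @param kind "smooth" or "sharp".
#' @param sigma Residual (noise) standard deviation, phenotype units.
#' @param affected_deme Deme id receiving the shift (sharp only).
#' @return An `environment_spec`.
#' @export
environment_spec <- function(kind = c("smooth", "sharp"), sigma = 1,
                             affected_deme = NULL) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  if (kind == "sharp" && is.null(affected_deme))
    stop("a sharp environment needs an affected deme")
  structure(list(kind = kind, sigma = sigma, affected_deme = affected_deme),
            class = "environment_spec")
}

deme_means <- function(spec, grid) {
  mu <- stats::setNames(rep(0, length(grid$deme_ids)), grid$deme_ids)
  if (spec$kind == "smooth") {
    if (grid$n_rows > 1L)
      mu[] <- 2 * spec$sigma * grid$coords$row / (grid$n_rows - 1L)
  } else {
    if (!spec$affected_deme %in% grid$deme_ids) stop("unknown affected deme")
    mu[spec$affected_deme] <- 2 * spec$sigma
  }
  mu
}

#' Draw per-individual environmental values
#'
#' Each individual receives its deme mean plus independent Gaussian noise with
#' sd `sigma`. The mean and noise components are returned separately so a
#' phenotype's true decomposition is retained.
#'
#' @param spec An [environment_spec()].
#' @param samples Sample table with `deme` (and grid provided via `grid`).
#' @param grid The [grid_spec()] mapping demes to rows.
#' @param seed Integer seed.
#' @return List with `values` (mu + noise), `mu`, `noise`.
#' @export
make_environment <- function(spec, samples, grid, seed) {
  mu_by_deme <- deme_means(spec, grid)
  mu <- unname(mu_by_deme[samples$deme])
  set.seed(as.integer(seed))
  noise <- stats::rnorm(nrow(samples), 0, spec$sigma)
  list(values = mu + noise, mu = mu, noise = noise)
}

#' Pick causal variants, one per 100 kb window
#'
#' Windows tile each chromosome half-open from position 0; in every window
#' containing at least one variant, one is chosen uniformly at random (empty
#' windows are skipped with a warning). At the 200 Mb main genome this yields
#' 2,000 causal variants.
#'
#' @param variants Variant table (chrom, row, pos, ...).
#' @param window_bp Window length (default 1e5).
#' @param seed Integer seed.
#' @param n_windows Expected number of windows (e.g. genome length / 1e5); if
#'   supplied and some windows hold no variant, a warning reports the skips.
#' @return Rows of `variants` for the chosen causal variants, with a
#'   `window` column appended.
#' @export
select_causal_variants <- function(variants, window_bp = 1e5, seed,
                                   n_windows = NULL) {
  win <- paste(variants$chrom, floor(variants$pos / window_bp), sep = ":")
  set.seed(as.integer(seed))
  picks <- unlist(lapply(split(seq_len(nrow(variants)), win), function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }))
  picks <- sort(unname(picks))
  if (!is.null(n_windows) && length(picks) < n_windows)
    warning(n_windows - length(picks), " windows hold no variant and were skipped")
  out <- variants[picks, , drop = FALSE]
  out$window <- win[picks]
  out
}

#' Draw frequency-dependent causal effect sizes
#'
#' Effects follow beta_k ~ N(0, sigma_l^2 [2 p_k (1 - p_k)]^alpha) with
#' sigma_l^2 solved so the total genetic variance
#' sigma_g^2 = sigma_l^2 * sum([2 p_k (1 - p_k)]^(alpha + 1)) equals the
#' target heritability h2, making the defining identity
#' Var(sum beta_k x_k) = h2 hold exactly in expectation (the per-variant
#' sampling variance of dosage is 2 p (1 - p)). alpha = -0.4 (a height-like
#' architecture) makes rarer variants carry larger effects.
#'
#' @param freqs Derived-allele frequencies of the causal variants (in (0,1)).
#' @param alpha Frequency-scaling exponent (default -0.4).
#' @param h2 Target genetic variance (default 0.8).
#' @param seed Integer seed.
#' @return List with `beta` and `sigma_l2`.
#' @export
draw_effects <- function(freqs, alpha = -0.4, h2 = 0.8, seed) {
  if (any(freqs <= 0 | freqs >= 1)) stop("causal frequencies must be in (0, 1)")
  sigma_l2 <- h2 / sum((2 * freqs * (1 - freqs))^(alpha + 1))
  set.seed(as.integer(seed))
  het <- 2 * freqs * (1 - freqs)
  beta <- stats::rnorm(length(freqs), 0, sqrt(sigma_l2 * het^alpha))
  list(beta = beta, sigma_l2 = sigma_l2)
}

#' True genetic values from causal dosages and effects
#'
#' g_i = sum_k beta_k x_ik.
#'
#' @param causal_dosages Causal variants x individuals dosage matrix.
#' @param beta Effect per causal variant.
#' @export
genetic_values <- function(causal_dosages, beta) {
  stopifnot(nrow(causal_dosages) == length(beta))
  as.vector(crossprod(causal_dosages, beta))
}

#' Assemble a phenotype from its components
#'
#' y = g + mu_deme + noise, with all components stored (never reconstructed).
#' For a heritable trait the convention is sigma = sqrt(1 - h2) for the
#' environment spec, so the structured shift of 2 * sigma is expressed
#' relative to the residual scale and Var(y) is about 1 in the unstructured
#' baseline.
#'
#' @param g Genetic values (0 for a non-heritable trait).
#' @param environment Output of [make_environment()].
#' @param samples Sample table (for ids/demes).
#' @return A `phenotype_set` data frame: id, deme, y, g, env_mean, noise.
#' @export
assemble_phenotype <- function(g, environment, samples) {
  n <- nrow(samples)
  if (length(g) == 1L) g <- rep(g, n)
  stopifnot(length(g) == n, length(environment$values) == n)
  structure(data.frame(id = samples$id, deme = samples$deme,
                       y = g + environment$values, g = g,
                       env_mean = environment$mu, noise = environment$noise,
                       stringsAsFactors = FALSE),
            class = c("phenotype_set", "data.frame"))
}

#' Seeds for repeated phenotype iterations
#'
#' Deterministically derives one seed per named stage/iteration from a master
#' seed (kept below 2^31), so the study's "20 random iterations of the
#' phenotype" are reproducible from a single seed.
#'
#' @param seed Master seed.
#' @param stage Stage name (string).
#' @param i Iteration number (default 1).
#' @export
derive_seed <- function(seed, stage, i = 1L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 69621 + i * 16807) %% 2147483629 + 1)
}
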