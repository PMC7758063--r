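#' Ascertain lead SNPs around causal variants
#'
#' Clumping-and-thresholding as used for polygenic scores: every tested
#' variant is assigned to its nearest causal variant on the same chromosome
#' when it lies within `window_bp / 2` of it (windows are centered on causal
#' variants); within each window the minimum-p variant is selected if its
#' p-value is below `p_threshold`, ties broken by smaller position. Windows
#' with no sub-threshold variant contribute nothing.
#'
#' With `mode = "causal"` the window's causal variant itself is selected
#' (subject to the same p-value threshold), giving the known-variant
#' comparison score.
#'
#' @param sumstats A `summary_stats` data frame (needs chrom, pos, beta, p).
#' @param causal Causal-variant table (chrom, pos), e.g. from
#'   [select_causal_variants()].
#' @param p_threshold Significance threshold (default 5e-4).
#' @param window_bp Window size around each causal variant (default 1e5).
#' @param mode "lead_snp" or "causal".
#' @return Selected rows of `sumstats` with a `window` column (index of the
#'   causal variant owning the window).
#' @export
ascertain_lead_snps <- function(sumstats, causal, p_threshold = 5e-4,
                                window_bp = 1e5, mode = c("lead_snp", "causal")) {
  mode <- match.arg(mode)
  sel <- integer(0)
  win <- integer(0)
  causal_key <- paste(causal$chrom, causal$pos)
  stats_key <- paste(sumstats$chrom, sumstats$pos)
  for (ch in unique(causal$chrom)) {
    cpos <- causal$pos[causal$chrom == ch]
    cidx <- which(causal$chrom == ch)
    srow <- which(sumstats$chrom == ch & !is.na(sumstats$p))
    if (length(srow) == 0L) next
    spos <- sumstats$pos[srow]
    nearest <- vapply(spos, function(p) which.min(abs(cpos - p)), integer(1))
    dist <- abs(spos - cpos[nearest])
    ok <- dist <= window_bp / 2
    if (mode == "causal") ok <- ok & stats_key[srow] %in% causal_key
    srow <- srow[ok]; nearest <- nearest[ok]
    for (wi in unique(nearest)) {
      rows <- srow[nearest == wi]
      pv <- sumstats$p[rows]
      best <- rows[order(pv, sumstats$pos[rows])][1]
      if (sumstats$p[best] < p_threshold) {
        sel <- c(sel, best)
        win <- c(win, cidx[wi])
      }
    }
  }
  o <- order(sel)
  out <- sumstats[sel[o], , drop = FALSE]
  out$window <- win[o]
  out
}

#' Polygenic scores from estimated effects
#'
#' score_i = sum_k beta_k x_ik over the selected variants. Selected variants
#' are matched to the dosage rows by chromosome and position; variants absent
#' from the test data contribute zero and are counted in attribute
#' `"n_missing"`.
#'
#' @param effects Data frame with chrom, pos and `beta` (e.g. output of
#'   [ascertain_lead_snps()] or [reestimate_effects()]).
#' @param dosages Test-cohort dosage matrix with a `"variants"` attribute.
#' @return Numeric score per test individual.
#' @export
compute_pgs <- function(effects, dosages) {
  v <- attr(dosages, "variants")
  key <- paste(v$chrom, v$pos)
  m <- match(paste(effects$chrom, effects$pos), key)
  missing <- is.na(m)
  sc <- rep(0, ncol(dosages))
  if (any(!missing)) {
    sc <- as.vector(crossprod(dosages[m[!missing], , drop = FALSE],
                              effects$beta[!missing]))
  }
  structure(sc, n_missing = sum(missing))
}

#' Per-deme mean residual polygenic score
#'
#' The residual score subtracts each test individual's true simulated genetic
#' value from their polygenic score, isolating bias; the map averages it per
#' deme. Demes listed in `all_demes` but unobserved get NA (never zero).
#'
#' @param scores Polygenic scores of the test individuals.
#' @param g True genetic values of the same individuals.
#' @param demes Deme label per individual.
#' @param all_demes Optional complete deme list for the map.
#' @return Data frame: deme, mean_residual, n.
#' @export
residual_map <- function(scores, g, demes, all_demes = NULL) {
  stopifnot(length(scores) == length(g), length(g) == length(demes))
  resid <- scores - g
  agg <- tapply(resid, demes, mean)
  if (is.null(all_demes)) all_demes <- names(agg)
  nn <- tapply(rep(1L, length(demes)), demes, sum)
  data.frame(deme = all_demes,
             mean_residual = as.vector(agg[all_demes]),
             n = ifelse(is.na(nn[all_demes]), 0L, as.vector(nn[all_demes])),
             row.names = NULL)
}

#' Predictive accuracy of a polygenic score
#'
#' Proportion of variance in true genetic values explained by the score
#' (squared correlation). A zero-variance score has accuracy 0 (with warning).
#'
#' @param scores,g Score and true genetic value per individual.
#' @export
prediction_accuracy <- function(scores, g) {
  stopifnot(length(scores) == length(g), length(g) >= 2)
  if (stats::var(scores) == 0) {
    warning("polygenic score has zero variance; accuracy set to 0")
    return(0)
  }
  stats::cor(scores, g)^2
}

#' Reestimate ascertained effects in a second cohort
#'
#' Keeps the ascertainment (the selected variants) fixed and replaces their
#' effect estimates with estimates from an independent cohort: either
#' sibling-difference regressions (`mode = "sib"`) or a standard linear GWAS
#' in unrelated individuals (`mode = "unrelated"`). Variants monomorphic in
#' the second cohort get effect 0 (counted in attribute `"n_zeroed"`).
#'
#' @param lead Selected variants (chrom, pos, ...) from [ascertain_lead_snps()].
#' @param mode "sib" or "unrelated".
#' @param sibs A `sib_pair_set` with phenotypes (sib mode).
#' @param dosages,phenotype,covariates Second-cohort data (unrelated mode).
#' @param discovery_ids,second_ids Individual ids of the discovery and second
#'   cohorts; any overlap is an error (the second cohort must be independent).
#' @return `lead` with its `beta` (and se, p where available) replaced.
#' @export
reestimate_effects <- function(lead, mode = c("sib", "unrelated"), sibs = NULL,
                               dosages = NULL, phenotype = NULL,
                               covariates = NULL,
                               discovery_ids = NULL, second_ids = NULL) {
  mode <- match.arg(mode)
  if (!is.null(discovery_ids) && !is.null(second_ids) &&
      length(intersect(discovery_ids, second_ids)) > 0)
    stop("second cohort overlaps the discovery cohort; reestimation requires independence")
  key <- paste(lead$chrom, lead$pos)
  if (mode == "sib") {
    stopifnot(inherits(sibs, "sib_pair_set"), !is.null(sibs$dy))
    m <- match(key, paste(sibs$variants$chrom, sibs$variants$pos))
    if (any(is.na(m))) stop("sib pair set lacks some ascertained variants")
    dx <- sibs$dx[m, , drop = FALSE]
    mono <- rowSums(dx != 0) == 0
    est <- data.frame(beta = rep(0, length(m)), se = NA_real_, p = NA_real_)
    if (any(!mono)) {
      fit <- sib_difference_test(dx[!mono, , drop = FALSE], sibs$dy)
      est[!mono, c("beta", "se", "p")] <- fit[, c("beta", "se", "p")]
    }
  } else {
    v <- attr(dosages, "variants")
    m <- match(key, paste(v$chrom, v$pos))
    if (any(is.na(m))) stop("second cohort lacks some ascertained variants")
    X <- dosages[m, , drop = FALSE]
    ss <- gwas_linear(X, phenotype, covariates)
    mono <- is.na(ss$beta)
    est <- data.frame(beta = ifelse(mono, 0, ss$beta), se = ss$se, p = ss$p)
  }
  lead$beta <- est$beta
  lead$se <- est$se
  lead$p <- est$p
  structure(lead, n_zeroed = sum(est$beta == 0 & is.na(est$se)))
}

#' Correlation of a residual map with the north-south axis
#'
#' Convenience summary of spatial bias: Pearson correlation between per-deme
#' mean residual scores and the deme's grid row.
#'
#' @param map Output of [residual_map()].
#' @param grid A [grid_spec()].
#' @export
map_gradient <- function(map, grid) {
  rows <- grid$coords$row[match(map$deme, grid$coords$deme)]
  ok <- !is.na(map$mean_residual)
  stats::cor(map$mean_residual[ok], rows[ok])
}
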