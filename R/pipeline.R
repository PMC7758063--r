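#' Experiment configuration
#'
#' Bundles everything one simulation experiment needs: demographic model,
#' genome preset, sample sizes, environment, trait architecture, the
#' structure-correction method, iteration count and the master seed. Every
#' stochastic stage derives its seed from the master seed and the stage name
#' (see [derive_seed()]), so a config fully determines its outputs.
#'
#' @param model "perpetual", "recent" or "complex".
#' @param m Migration rate between adjacent demes.
#' @param genome A [genome_spec()].
#' @param n_per_deme Diploid individuals per deme (train + test together).
#' @param environment An [environment_spec()], or NULL for no structured
#'   environment.
#' @param h2 Trait heritability (0 = non-heritable phenotype).
#' @param alpha Frequency-scaling exponent of effect sizes.
#' @param correction One of "none", "common_pca", "rare_pca", "ibd_pca",
#'   "common_rare_pca", "lmm_common", "lmm_rare".
#' @param n_pcs Number of PC covariates (default 100; split 50/50 for
#'   "common_rare_pca").
#' @param n_iterations Phenotype iterations to average over (default 20).
#' @param seed Master seed.
#' @param grid A [grid_spec()] (default 6 x 6).
#' @param admixture Optional [admixture_spec()] for the complex model.
#' @param perpetual_horizon Engine horizon for the perpetual model (see
#'   [build_demography()]).
#' @param max_common,max_rare Caps on variants entering the common/rare GRMs.
#' @param causal_window_bp Causal-variant window (default 1e5).
#' @param train_fraction Training fraction of the cohort (default 0.5).
#' @param tail_p Tail percentile for inflation summaries (default 0.999).
#' @export
experiment_config <- function(model, m, genome, n_per_deme,
                              environment = NULL, h2 = 0, alpha = -0.4,
                              correction = "common_pca", n_pcs = 100L,
                              n_iterations = 20L, seed = 1L,
                              grid = grid_spec(), admixture = NULL,
                              perpetual_horizon = 5000,
                              max_common = 200000L, max_rare = 1000000L,
                              causal_window_bp = 1e5, train_fraction = 0.5,
                              tail_p = 0.999) {
  correction <- match.arg(correction,
    c("none", "common_pca", "rare_pca", "ibd_pca", "common_rare_pca",
      "lmm_common", "lmm_rare"))
  stopifnot(h2 >= 0, h2 <= 1, n_iterations >= 1)
  structure(list(model = model, m = m, genome = genome, n_per_deme = n_per_deme,
                 environment = environment, h2 = h2, alpha = alpha,
                 correction = correction, n_pcs = as.integer(n_pcs),
                 n_iterations = as.integer(n_iterations), seed = as.integer(seed),
                 grid = grid, admixture = admixture,
                 perpetual_horizon = perpetual_horizon,
                 max_common = max_common, max_rare = max_rare,
                 causal_window_bp = causal_window_bp,
                 train_fraction = train_fraction, tail_p = tail_p),
            class = "experiment_config")
}

config_demography <- function(config) {
  build_demography(config$model, grid = config$grid, m = config$m,
                   admixture = config$admixture,
                   perpetual_horizon = config$perpetual_horizon)
}

#' Migration-rate calibration table
#'
#' For each rate, simulates a cohort, LD-prunes the common variants, and
#' reports mean Weir-Cockerham FST with its bootstrap CI plus the median
#' genomic inflation of covariate-free GWAS on the two grid coordinates
#' (lambda latitude / longitude). This mirrors the migration-calibration
#' table used to match the simulations to an observed cohort's structure.
#'
#' @param kind Demographic model kind.
#' @param rates Migration rates to scan.
#' @param genome A [genome_spec()] (default: calibration preset, 10 x 1 Mb).
#' @param n_per_deme Individuals per deme (default 250).
#' @param seed Master seed (one cohort per rate, seeds derived).
#' @param perpetual_horizon Engine horizon for perpetual runs.
#' @param max_common Cap on exported common variants per cohort.
#' @param n_boot Bootstrap resamples for the FST CI.
#' @return Data frame sorted by rate: model, m, fst, ci_lo, ci_hi,
#'   lambda_lat, lambda_lon, n_variants_pruned.
#' @export
run_calibration <- function(kind, rates, genome = genome_calibration(),
                            n_per_deme = 250L, seed = 1L,
                            perpetual_horizon = 5000, max_common = 100000L,
                            n_boot = 200L) {
  stopifnot(length(rates) >= 1, all(rates >= 0))
  rates <- sort(rates)
  rows <- lapply(seq_along(rates), function(i) {
    dem <- build_demography(kind, grid = grid_spec(), m = rates[i],
                            perpetual_horizon = perpetual_horizon)
    ds <- simulate_cohort(dem, genome, n_per_deme,
                          seed = derive_seed(seed, paste0("calib_", kind), i))
    res <- tryCatch(
      calibration_row(ds, max_common = max_common, n_boot = n_boot),
      error = function(e) {
        warning("rate ", rates[i], " failed: ", conditionMessage(e))
        list(fst = NA_real_, ci = c(NA_real_, NA_real_),
             lambda_lat = NA_real_, lambda_lon = NA_real_, n_pruned = NA_integer_)
      })
    unlink(ds$dir, recursive = TRUE)
    data.frame(model = kind, m = rates[i], fst = res$fst,
               ci_lo = res$ci[1], ci_hi = res$ci[2],
               lambda_lat = res$lambda_lat, lambda_lon = res$lambda_lon,
               n_variants_pruned = res$n_pruned)
  })
  do.call(rbind, rows)
}

calibration_row <- function(ds, max_common = 100000L, n_boot = 200L) {
  dos <- get_dosages(ds, class = "common", max_variants = max_common,
                     subsample_seed = ds$seed)
  kept <- ld_prune(dos)
  pruned <- dos[kept, , drop = FALSE]
  attr(pruned, "variants") <- attr(dos, "variants")[kept, , drop = FALSE]
  fst <- weir_cockerham_fst(pruned, sample_table(ds)$deme, n_boot = n_boot)
  lat <- location_gwas_lambda(dos, sample_table(ds), axis = "y")
  lon <- location_gwas_lambda(dos, sample_table(ds), axis = "x")
  list(fst = fst$fst, ci = fst$ci, lambda_lat = lat$lambda,
       lambda_lon = lon$lambda, n_pruned = length(kept))
}

experiment_grms <- function(config) {
  switch(config$correction,
    none = character(0),
    common_pca = "common",
    rare_pca = "rare_mac",
    common_rare_pca = c("common", "rare_mac"),
    ibd_pca = character(0),
    lmm_common = "common",
    lmm_rare = "rare_mac")
}

#' Run one named experiment end to end
#'
#' Simulates (or reuses) the cohort, optionally splits train/test, builds the
#' requested correction (PCs of a common-, rare- or IBD-based GRM, or a LOCO
#' mixed model), then for each phenotype iteration simulates the phenotype,
#' runs the per-variant association scan on the training individuals and
#' summarizes genomic inflation by variant class. For heritable traits it
#' additionally ascertains causal-window lead SNPs, builds polygenic scores in
#' the test half, and accumulates residual score maps, prediction accuracy and
#' the north-south residual gradient. Metrics are averaged over iterations and
#' written as JSON alongside TSV tables and a log of all seeds.
#'
#' Large cohorts are processed chromosome by chromosome from the export cache
#' (nothing beyond one chromosome is held in memory); this streaming mode
#' supports non-heritable phenotypes and PCA corrections. Polygenic-score
#' experiments and the LOCO mixed model hold the genotype matrix and are meant
#' for moderate cohort sizes.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created; default tempdir).
#' @param keep_cohort Keep the simulation store (default FALSE: deleted,
#'   unless `dataset` was supplied).
#' @param dataset Optional pre-simulated `genotype_dataset` to reuse across
#'   corrections (must match the config's model and genome).
#' @return Invisibly, the metrics list (also written to `metrics.json`).
#' @export
run_experiment <- function(config, out_dir = tempfile("stratsim_exp_"),
                           keep_cohort = FALSE, dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "log.txt")
  logln <- function(...) cat(..., "\n", file = logfile, append = TRUE)
  t0 <- Sys.time()
  logln("master seed:", config$seed)

  owns <- is.null(dataset)
  ds <- if (owns) {
    simulate_cohort(config_demography(config), config$genome, config$n_per_deme,
                    seed = derive_seed(config$seed, "cohort"))
  } else dataset
  logln("cohort:", ds$n_individuals, "individuals,", nrow(ds$variants), "variants")

  if (config$train_fraction >= 1) {
    train <- ds; test <- NULL
  } else {
    halves <- split_train_test(ds, config$train_fraction)
    train <- halves$train; test <- halves$test
  }
  n_train <- length(train$individuals)
  train_cols <- match(train$individuals, ds$individuals)
  nchrom <- config$genome$n_chromosomes
  is_lmm <- config$correction %in% c("lmm_common", "lmm_rare")
  hold <- (as.numeric(nrow(ds$variants)) * ds$n_individuals * 4) < 1.2e9
  if (!hold && (is_lmm || config$h2 > 0))
    stop("this cohort is too large to hold in memory; LOCO mixed models and ",
         "polygenic-score experiments need a smaller scale")
  logln("mode:", if (hold) "in-memory" else "streaming")

  load_chrom <- function(ch) {
    full <- get_dosages(ds, variants = ds$variants[ds$variants$chrom == ch, ])
    attr(full, "variants") <- cbind(attr(full, "variants"))
    full
  }

  # pass 1: within-train variant classes and the GRM(s) the correction needs
  grm_classes <- experiment_grms(config)
  G <- lapply(grm_classes, function(x) matrix(0, n_train, n_train))
  names(G) <- grm_classes
  Gm <- stats::setNames(rep(0L, length(grm_classes)), grm_classes)
  class_rows <- list(common = vector("list", nchrom),
                     rare_mac = vector("list", nchrom))
  held <- if (hold) vector("list", nchrom)
  vtabs <- vector("list", nchrom)
  nh <- 2L * n_train
  full_train <- length(train_cols) == ds$n_individuals
  for (ch in seq_len(nchrom)) {
    full <- load_chrom(ch)
    vtabs[[ch]] <- attr(full, "variants")
    tr <- if (full_train) full else full[, train_cols, drop = FALSE]
    dc <- rowSums(tr)
    mac <- pmin(dc, nh - dc)
    class_rows$common[[ch]] <- which(mac / nh > 0.05)
    class_rows$rare_mac[[ch]] <- which(mac >= 2L & mac <= 4L)
    for (cls in grm_classes) {
      rows <- class_rows[[cls]][[ch]]
      if (length(rows) < 2L) next
      X <- tr[rows, , drop = FALSE]
      p <- rowMeans(X) / 2
      ok <- p > 0 & p < 1
      Z <- (X[ok, , drop = FALSE] - 2 * p[ok]) / sqrt(2 * p[ok] * (1 - p[ok]))
      G[[cls]] <- G[[cls]] + crossprod(Z)
      Gm[cls] <- Gm[cls] + sum(ok)
      rm(X, Z)
    }
    if (hold) held[[ch]] <- full
    rm(full, tr)
    invisible(gc(FALSE))
  }
  grms <- lapply(grm_classes, function(cls) {
    if (Gm[cls] < 2L) stop("not enough variants for the ", cls, " GRM")
    structure(list(matrix = G[[cls]] / Gm[cls], source = cls,
                   n_variants = Gm[cls]), class = "grm")
  })
  names(grms) <- grm_classes
  rm(G)
  covs <- switch(config$correction,
    none = NULL,
    common_pca = pca(grms$common, k = config$n_pcs),
    rare_pca = pca(grms$rare_mac, k = config$n_pcs),
    common_rare_pca = list(pca(grms$common, k = config$n_pcs %/% 2L),
                           pca(grms$rare_mac, k = config$n_pcs %/% 2L)),
    ibd_pca = pca(ibd_sharing_grm(train), k = config$n_pcs),
    lmm_common = pca(grms$common, k = config$n_pcs),
    lmm_rare = pca(grms$rare_mac, k = config$n_pcs))
  if (!is_lmm) rm(grms)
  invisible(gc(FALSE))
  logln("correction:", config$correction)

  lmm_class <- if (config$correction == "lmm_common") "common" else "rare_mac"
  samp_test <- if (!is.null(test)) sample_table(test)
  all_variants <- do.call(rbind, vtabs)
  chrom_offset <- c(0L, cumsum(vapply(vtabs, nrow, integer(1))))
  class_all <- list(
    common = unlist(lapply(seq_len(nchrom), function(ch)
      class_rows$common[[ch]] + chrom_offset[ch])),
    rare_mac = unlist(lapply(seq_len(nchrom), function(ch)
      class_rows$rare_mac[[ch]] + chrom_offset[ch])))
  nT <- config$n_iterations

  # phenotype components for every iteration up front, so each chromosome is
  # visited once for all iterations
  envs <- vector("list", nT)
  causal_list <- vector("list", nT)
  eff_list <- vector("list", nT)
  Gmat <- matrix(0, ds$n_individuals, nT)
  for (it in seq_len(nT)) {
    envs[[it]] <- if (is.null(config$environment)) {
      list(values = numeric(ds$n_individuals), mu = numeric(ds$n_individuals),
           noise = numeric(ds$n_individuals))
    } else {
      make_environment(config$environment, ds$samples, config$grid,
                       seed = derive_seed(config$seed, "env", it))
    }
    if (config$h2 > 0) {
      causal <- select_causal_variants(all_variants, config$causal_window_bp,
                                       seed = derive_seed(config$seed, "causal", it))
      crow <- match(paste(causal$chrom, causal$pos),
                    paste(all_variants$chrom, all_variants$pos))
      cd <- do.call(rbind, lapply(seq_len(nchrom), function(ch) {
        ix <- crow[causal$chrom == ch] - chrom_offset[ch]
        held[[ch]][ix, , drop = FALSE]
      }))
      freqs <- rowMeans(cd[, train_cols, drop = FALSE]) / 2
      okf <- freqs > 0 & freqs < 1
      causal <- causal[okf, , drop = FALSE]
      eff <- draw_effects(freqs[okf], config$alpha, config$h2,
                          seed = derive_seed(config$seed, "effects", it))
      Gmat[, it] <- genetic_values(cd[okf, , drop = FALSE], eff$beta)
      causal_list[[it]] <- causal
      eff_list[[it]] <- eff
      rm(cd)
    }
  }
  Y <- Gmat + vapply(envs, `[[`, numeric(ds$n_individuals), "values")
  Ytr <- Y[train_cols, , drop = FALSE]

  # one pass over chromosomes, scanning all iterations together
  Mtot <- nrow(all_variants)
  beta <- se <- chisq <- pval <- matrix(NA_real_, Mtot, nT)
  freq_all <- rep(NA_real_, Mtot)
  for (ch in seq_len(nchrom)) {
    rows <- chrom_offset[ch] + seq_len(nrow(vtabs[[ch]]))
    if (is_lmm) {
      for (it in seq_len(nT)) {
        out <- gwas_lmm_loco_chrom(held, vtabs, ch, train_cols, Ytr[, it],
                                   lmm_class, class_rows, covs)
        beta[rows, it] <- out$beta; se[rows, it] <- out$se
        chisq[rows, it] <- out$chisq; pval[rows, it] <- out$p
        freq_all[rows] <- out$freq
      }
    } else {
      X <- if (hold) held[[ch]] else load_chrom(ch)
      Xtr <- if (full_train) X else X[, train_cols, drop = FALSE]
      res <- gwas_scan_multi(Xtr, Ytr, covs)
      beta[rows, ] <- res$beta; se[rows, ] <- res$se
      chisq[rows, ] <- res$chisq; pval[rows, ] <- res$p
      freq_all[rows] <- rowMeans(Xtr) / 2
      if (!hold) rm(X)
      if (!full_train) rm(Xtr)
    }
    logln("chromosome", ch, "scanned")
  }

  acc <- list()
  for (it in seq_len(nT)) {
    ss <- data.frame(chrom = all_variants$chrom, pos = all_variants$pos,
                     freq = freq_all, beta = beta[, it], se = se[, it],
                     chisq = chisq[, it], p = pval[, it])
    it_metrics <- list(
      lambda_median_common = tail_inflation(ss, class_all$common, p = 0.5)$lambda,
      lambda_tail_common = tail_inflation(ss, class_all$common,
                                          p = config$tail_p)$lambda,
      lambda_median_rare = tail_inflation(ss, class_all$rare_mac, p = 0.5)$lambda,
      lambda_tail_rare = tail_inflation(ss, class_all$rare_mac,
                                        p = config$tail_p)$lambda)

    if (config$h2 > 0 && is.null(test)) {
      logln("iteration", it, ": PGS stage skipped (no test set)")
    } else if (config$h2 > 0) {
      test_cols <- match(test$individuals, ds$individuals)
      g_test <- Gmat[test_cols, it]
      for (lab in c("lead_snp", "causal")) {
        sel <- ascertain_lead_snps(ss, causal_list[[it]], mode = lab)
        srow <- match(paste(sel$chrom, sel$pos),
                      paste(all_variants$chrom, all_variants$pos))
        seld <- do.call(rbind, lapply(seq_len(nchrom), function(ch) {
          ix <- srow[sel$chrom == ch] - chrom_offset[ch]
          held[[ch]][ix, test_cols, drop = FALSE]
        }))
        attr(seld, "variants") <- all_variants[srow, , drop = FALSE]
        sc <- compute_pgs(sel, seld)
        map <- residual_map(sc, g_test, samp_test$deme,
                            all_demes = config$grid$coords$deme)
        it_metrics[[paste0("pgs_gradient_", lab)]] <- map_gradient(map, config$grid)
        it_metrics[[paste0("pgs_accuracy_", lab)]] <- prediction_accuracy(sc, g_test)
        key <- paste0("map_", lab)
        acc[[key]] <- if (is.null(acc[[key]])) map$mean_residual / nT
                      else acc[[key]] + map$mean_residual / nT
      }
    }
    acc$metrics[[it]] <- it_metrics
    logln("iteration", it, "done")
  }

  if (config$h2 == 0) logln("PGS stage skipped (h2 = 0)")
  metric_names <- names(acc$metrics[[1]])
  metrics <- lapply(stats::setNames(metric_names, metric_names), function(nm)
    mean(vapply(acc$metrics, function(m) m[[nm]], numeric(1)), na.rm = TRUE))
  metrics$correction <- config$correction
  metrics$model <- config$model
  metrics$n_iterations <- config$n_iterations
  writeLines(as.character(jsonlite::toJSON(metrics, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(out_dir, "metrics.json"))
  if (!is.null(acc$map_lead_snp)) {
    maps <- data.frame(config$grid$coords,
                       mean_residual_lead = acc$map_lead_snp,
                       mean_residual_causal = acc$map_causal)
    utils::write.table(maps, file.path(out_dir, "residual_maps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logln("elapsed:", format(Sys.time() - t0))
  if (owns && !keep_cohort) unlink(ds$dir, recursive = TRUE)
  invisible(metrics)
}

# LOCO scan for one chromosome inside run_experiment: builds the GRM from the
# configured class on all other chromosomes, then GLS-scans this chromosome.
gwas_lmm_loco_chrom <- function(held, vtabs, ch, train_cols, y, cls,
                                class_rows, covs) {
  parts <- lapply(seq_along(held), function(c2) {
    if (c2 == ch) return(NULL)
    rows <- class_rows[[cls]][[c2]]
    if (length(rows) == 0L) return(NULL)
    list(m = held[[c2]][rows, train_cols, drop = FALSE],
         v = vtabs[[c2]][rows, , drop = FALSE])
  })
  parts <- Filter(Negate(is.null), parts)
  grm_dos <- structure(do.call(rbind, lapply(parts, `[[`, "m")),
                       variants = do.call(rbind, lapply(parts, `[[`, "v")))
  target <- held[[ch]][, train_cols, drop = FALSE]
  attr(target, "variants") <- vtabs[[ch]]
  out <- gwas_lmm_loco(target, y, grm_dos, covariates = covs)
  out[, c("chrom", "pos", "freq", "beta", "se", "chisq", "p")]
}

#' Rank structure corrections by residual inflation
#'
#' Runs (or takes) a set of experiment results that differ only in their
#' correction method and tabulates tail inflation and, when available, the
#' residual polygenic-score gradient; the correction with the smallest common
#' -variant tail inflation is flagged. Exact ties are reported as ties rather
#' than broken arbitrarily.
#'
#' @param results Named list of metrics lists (as returned by
#'   [run_experiment()]).
#' @return Data frame ranked by `lambda_tail_common`, with attribute
#'   `"best"` (character vector; length > 1 on ties).
#' @export
compare_corrections <- function(results) {
  if (length(results) < 2L) stop("need at least two corrections to compare")
  models <- vapply(results, function(r) r$model, character(1))
  if (length(unique(models)) != 1L)
    stop("corrections must be compared on the same model")
  corr <- vapply(results, function(r) r$correction, character(1))
  if (anyDuplicated(corr)) stop("duplicate correction labels")
  tab <- data.frame(
    correction = corr,
    lambda_tail_common = vapply(results, function(r)
      r$lambda_tail_common, numeric(1)),
    lambda_tail_rare = vapply(results, function(r)
      r$lambda_tail_rare, numeric(1)),
    pgs_gradient_lead = vapply(results, function(r)
      if (is.null(r$pgs_gradient_lead_snp)) NA_real_ else r$pgs_gradient_lead_snp,
      numeric(1)),
    row.names = NULL)
  tab <- tab[order(tab$lambda_tail_common), , drop = FALSE]
  best_val <- min(tab$lambda_tail_common)
  structure(tab, best = tab$correction[tab$lambda_tail_common == best_val])
}
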