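#' Gene structure for burden simulations
#'
#' The default mimics an average human gene: eight exons of 160 bp (1,280 bp
#' of exon in total) separated by introns of 6,938 bp. Without recombination
#' the introns are irrelevant to the genealogy and are omitted (zero-length
#' spacers), so the simulated span is just the concatenated exons; with
#' recombination the full span is simulated and introns act as recombining
#' spacers between exons.
#'
#' @param n_exons,exon_length,intron_length Gene geometry in bp.
#' @param recombination Simulate recombination across the gene?
#' @export
gene_model <- function(n_exons = 8L, exon_length = 160L, intron_length = 6938L,
                       recombination = FALSE) {
  stopifnot(n_exons >= 1, exon_length > 0, intron_length >= 0)
  structure(list(n_exons = as.integer(n_exons),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 recombination = isTRUE(recombination),
                 total_exon_length = as.integer(n_exons * exon_length)),
            class = "gene_model")
}

#' Simulate independent gene replicates
#'
#' Each gene is an independent coalescent replicate of the demography for the
#' same per-deme sample sizes; sample k of every replicate is identified with
#' cohort individual k (individuals are exchangeable within demes across
#' replicates). Variant tables record all variants with exon membership;
#' carrier lists (individual, dosage) are exported for low-frequency exonic
#' variants so burdens can be computed sparsely.
#'
#' @param demography A [build_demography()] spec.
#' @param model A [gene_model()].
#' @param n_genes Number of genes.
#' @param n_per_deme Diploid individuals per deme (single count or named).
#' @param seed Integer seed.
#' @param mutation_rate,recombination_rate Per-bp per-generation rates.
#' @param dir Store directory (default tempdir).
#' @return A `gene_set`: list with `variants` (gene, pos, dcount, exonic),
#'   `carriers` (gene, vrow, ind, dosage), `samples`, `n_individuals`,
#'   `n_haplotypes`, `model`.
#' @export
simulate_genes <- function(demography, model, n_genes, n_per_deme, seed,
                           mutation_rate = 1e-8, recombination_rate = 1e-8,
                           dir = tempfile("stratsim_genes_")) {
  stopifnot(inherits(demography, "demography_spec"), inherits(model, "gene_model"))
  samples_cfg <- if (length(n_per_deme) == 1L && is.null(names(n_per_deme)))
    as.integer(n_per_deme) else as.list(round(n_per_deme))
  cfg <- list(
    demography = jsonlite::fromJSON(demography_to_json(demography),
                                    simplifyVector = TRUE),
    n_genes = as.integer(n_genes),
    n_exons = model$n_exons, exon_length = model$exon_length,
    intron_length = model$intron_length, recombination = model$recombination,
    mutation_rate = mutation_rate, recombination_rate = recombination_rate,
    samples = samples_cfg, seed = as.integer(seed))
  cfg$demography$deme_ids <- I(cfg$demography$deme_ids)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config.json")
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                           null = "null")), cfg_path)
  run_driver(c("genes", "--config", cfg_path, "--out", dir))
  variants <- as.data.frame(arrow::read_feather(file.path(dir, "gene_variants.feather")))
  carriers <- as.data.frame(arrow::read_feather(file.path(dir, "gene_carriers.feather")))
  samples <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(variants = variants, carriers = carriers, samples = samples,
                 n_individuals = nrow(samples), n_haplotypes = 2L * nrow(samples),
                 n_genes = as.integer(n_genes), model = model, meta = meta,
                 retained = NULL, dir = dir),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$n_genes, "genes,", x$n_individuals, "individuals\n")
  invisible(x)
}

#' Exonic rare-variant count per gene
#'
#' Number of exonic variants with derived-allele frequency below `threshold`
#' (computed in the analyzed sample) in each gene.
#'
#' @param genes A `gene_set`.
#' @param threshold Frequency cutoff (default 0.001).
#' @return Integer vector of length `n_genes`.
#' @export
rare_variant_counts <- function(genes, threshold = 0.001) {
  v <- genes$variants
  keep <- v$exonic & v$dcount > 0 & v$dcount / genes$n_haplotypes < threshold
  if (!is.null(genes$retained)) keep <- keep & genes$retained
  tab <- table(factor(v$gene[keep], levels = seq_len(genes$n_genes)))
  as.integer(tab)
}

#' Thin exonic rare variants to a target count distribution
#'
#' Draws a per-gene target count from round(N(mean, sd)) (floored at zero) and
#' retains that many exonic rare variants uniformly at random, so burden
#' comparisons across demographic models are not confounded by differences in
#' the number of rare variants. Carrier deme labels are untouched. Genes with
#' fewer variants than their target are flagged in attribute `"short"`.
#'
#' @param genes A `gene_set`.
#' @param target_mean,target_sd Target distribution (default 16 and 4).
#' @param threshold Rare-variant frequency cutoff (default 0.001).
#' @param seed Integer seed.
#' @return The `gene_set` with a `retained` logical mask over its variant table.
#' @export
match_variant_counts <- function(genes, target_mean = 16, target_sd = 4,
                                 threshold = 0.001, seed = 1L) {
  v <- genes$variants
  rare <- v$exonic & v$dcount > 0 & v$dcount / genes$n_haplotypes < threshold
  set.seed(as.integer(seed))
  targets <- pmax(0L, as.integer(round(stats::rnorm(genes$n_genes, target_mean,
                                                    target_sd))))
  retained <- rare
  short <- integer(0)
  for (g in seq_len(genes$n_genes)) {
    ix <- which(rare & v$gene == g)
    tg <- targets[g]
    if (length(ix) < tg) {
      short <- c(short, g)
    } else if (length(ix) > tg) {
      drop <- if (tg == 0L) ix else ix[-sample.int(length(ix), tg)]
      retained[drop] <- FALSE
    }
  }
  genes$retained <- retained
  attr(genes, "short") <- short
  genes
}

#' Per-individual gene burden
#'
#' Total count of derived alleles across a gene's exons at variants below the
#' frequency threshold (frequency computed in the analyzed sample). Intronic
#' variants never contribute.
#'
#' @param genes A `gene_set`.
#' @param threshold Frequency cutoff (default 0.001).
#' @param gene Optional single gene index; default all genes.
#' @return Matrix genes x individuals of integer burdens (a vector when
#'   `gene` is given).
#' @export
gene_burden <- function(genes, threshold = 0.001, gene = NULL) {
  v <- genes$variants
  keep <- v$exonic & v$dcount > 0 & v$dcount / genes$n_haplotypes < threshold
  if (!is.null(genes$retained)) keep <- keep & genes$retained
  # carriers reference rows within each gene's variant table
  v$within <- stats::ave(seq_len(nrow(v)), v$gene, FUN = seq_along)
  keykeep <- paste(v$gene[keep], v$within[keep])
  cc <- genes$carriers
  ok <- paste(cc$gene, cc$vrow) %in% keykeep
  cc <- cc[ok, , drop = FALSE]
  gsel <- if (is.null(gene)) seq_len(genes$n_genes) else gene
  B <- matrix(0L, length(gsel), genes$n_individuals)
  if (nrow(cc) > 0) {
    gi <- match(cc$gene, gsel)
    use <- !is.na(gi)
    if (any(use)) {
      # accumulate dosages (an individual can carry several variants in a gene)
      sums <- rowsum(as.integer(cc$dosage[use]),
                     group = (gi[use] - 1) * genes$n_individuals + cc$ind[use])
      at <- as.numeric(rownames(sums))
      B[cbind((at - 1) %/% genes$n_individuals + 1,
              (at - 1) %% genes$n_individuals + 1)] <- sums[, 1]
    }
  }
  if (!is.null(gene)) B[1, ] else B
}

#' Per-gene burden association
#'
#' Linear regression of the phenotype on each gene's burden with optional PC
#' covariates (same model as [gwas_linear()], with the burden as the
#' predictor). Genes with zero burden variance are skipped (NA).
#'
#' @param burdens Genes x individuals burden matrix from [gene_burden()].
#' @param phenotype Numeric vector or `phenotype_set`.
#' @param covariates As in [gwas_linear()].
#' @return Data frame: beta, se, chisq, p per gene.
#' @export
burden_association <- function(burdens, phenotype, covariates = NULL) {
  ss <- gwas_linear(burdens, phenotype, covariates)
  ss[, c("beta", "se", "chisq", "p")]
}

#' Gini coefficient of spatial burden concentration
#'
#' G = (n - y1 - sum_{1<i<=n}(y_i + y_{i-1})) / n where y_i are cumulative
#' burden shares across demes sorted in increasing order (y_n = 1). G = 0 for
#' a uniformly distributed burden and (n-1)/n when it is concentrated in a
#' single deme.
#'
#' @param deme_totals Non-negative per-deme burden totals (>= 2 demes, not all
#'   zero).
#' @export
gini_coefficient <- function(deme_totals) {
  n <- length(deme_totals)
  if (n < 2L) stop("Gini needs at least two demes")
  if (any(deme_totals < 0)) stop("burdens must be non-negative")
  tot <- sum(deme_totals)
  if (tot == 0) stop("Gini is undefined when all deme burdens are zero")
  y <- cumsum(sort(deme_totals)) / tot
  (n - y[1] - sum(y[-1] + y[-n])) / n
}

#' Per-deme burden totals
#'
#' @param burden Per-individual burden (one gene).
#' @param demes Deme label per individual.
#' @export
deme_burden_totals <- function(burden, demes) {
  as.vector(tapply(burden, demes, sum))
}
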