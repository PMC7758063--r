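#!/usr/bin/env Rscript
# Sibling-based designs: pure sib-difference association, and the hybrid
# design (lead SNPs ascertained in a standard GWAS, effects reestimated in
# an independent set of sibling pairs), compared on residual-score bias and
# predictive accuracy (recent model, N = 4,320, 10 Mb, h2 = 0.8).

library(stratsim)
dir.create("results", showWarnings = FALSE)
seed <- 20201117

grid <- grid_spec(6, 6)
ds <- simulate_cohort(build_demography("recent", m = 0.05),
                      genome_calibration(), 120,
                      seed = derive_seed(seed, "sibcohort"))
by_deme <- split(seq_len(ds$n_individuals), ds$samples$deme)
train_ix <- sort(unlist(lapply(by_deme, `[`, 1:60)))
parent_ix <- sort(unlist(lapply(by_deme, `[`, 61:100)))
test_ix <- sort(unlist(lapply(by_deme, `[`, 101:120)))
h2 <- 0.8
env <- environment_spec("smooth", sqrt(1 - h2))

held <- lapply(seq_len(ds$genome$n_chromosomes), function(ch)
  get_dosages(ds, variants = ds$variants[ds$variants$chrom == ch, ]))
all_v <- do.call(rbind, lapply(held, attr, "variants"))
offs <- c(0L, cumsum(vapply(held, nrow, integer(1))))

tr_common <- do.call(rbind, lapply(held, function(X) {
  Xt <- X[, train_ix, drop = FALSE]
  dcnt <- rowSums(Xt); nh <- 2L * length(train_ix)
  Xt[pmin(dcnt, nh - dcnt) / nh > 0.05, , drop = FALSE]
}))
pcs <- pca(compute_grm(tr_common, "common"), k = 100)
rm(tr_common); invisible(gc(FALSE))

causal <- select_causal_variants(all_v, 1e5, seed = derive_seed(seed, "cz"))
crow <- match(paste(causal$chrom, causal$pos), paste(all_v$chrom, all_v$pos))
cd <- do.call(rbind, lapply(seq_along(held), function(ch)
  held[[ch]][crow[causal$chrom == ch] - offs[ch], , drop = FALSE]))
freqs <- rowMeans(cd[, train_ix, drop = FALSE]) / 2
ok <- freqs > 0 & freqs < 1
causal <- causal[ok, , drop = FALSE]; cd <- cd[ok, , drop = FALSE]
eff <- draw_effects(freqs[ok], -0.4, h2, seed = derive_seed(seed, "eff"))
g <- genetic_values(cd, eff$beta)
e <- make_environment(env, ds$samples, grid, seed = derive_seed(seed, "env"))
y <- g + e$values

ss <- do.call(rbind, lapply(seq_along(held), function(ch) {
  X <- held[[ch]][, train_ix, drop = FALSE]
  attr(X, "variants") <- attr(held[[ch]], "variants")
  gwas_linear(X, y[train_ix], covariates = pcs)
}))
lead <- ascertain_lead_snps(ss, causal, mode = "lead_snp")
cat("lead SNPs ascertained:", nrow(lead), "\n")

parents <- subset_individuals(ds, parent_ix)
svars <- all_v[sort(unique(c(
  match(paste(lead$chrom, lead$pos), paste(all_v$chrom, all_v$pos)),
  match(paste(causal$chrom, causal$pos), paste(all_v$chrom, all_v$pos))))), ]
sibs <- mate_within_deme(parents, svars, n_pairs_per_deme = 20,
                         seed = derive_seed(seed, "mate"))
c_in_s <- match(paste(causal$chrom, causal$pos),
                paste(sibs$variants$chrom, sibs$variants$pos))
sibs <- sib_phenotypes(sibs, c_in_s, eff$beta, env, grid,
                       seed = derive_seed(seed, "sphen"))

hybrid <- reestimate_effects(lead, "sib", sibs = sibs,
                             discovery_ids = ds$samples$id[train_ix],
                             second_ids = ds$samples$id[parent_ix])

score_of <- function(sel) {
  srow <- match(paste(sel$chrom, sel$pos), paste(all_v$chrom, all_v$pos))
  seld <- do.call(rbind, lapply(seq_along(held), function(ch)
    held[[ch]][srow[sel$chrom == ch] - offs[ch], test_ix, drop = FALSE]))
  attr(seld, "variants") <- all_v[srow, , drop = FALSE]
  compute_pgs(sel, seld)
}
summarize <- function(label, sel) {
  sc <- score_of(sel)
  map <- residual_map(sc, g[test_ix], ds$samples$deme[test_ix],
                      all_demes = grid$coords$deme)
  data.frame(design = label, n_variants = nrow(sel),
             gradient = map_gradient(map, grid),
             accuracy = prediction_accuracy(sc, g[test_ix]))
}
tab <- rbind(summarize("gwas_lead", lead),
             summarize("hybrid_sib_reestimated", hybrid))
print(tab, digits = 3)
write.table(tab, "results/sibling_designs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
unlink(ds$dir, recursive = TRUE)
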