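---
title: "Simulating residual population stratification in GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating residual population stratification in GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Association studies correct for population structure with principal
components (PCs) or mixed models built from a genetic relatedness matrix
(GRM), almost always computed from common variants. Whether that correction
works depends not only on how much structure there is — as summarized by
FST or the genomic inflation factor λ — but on *when* the structure arose.
Two populations can have identical FST while one acquired its structure
hundreds of generations ago and the other only a hundred generations ago
(roughly the bound that ancient-DNA population turnover places on
present-day British structure). Common variants are older than a recent
structure and barely record it; the recent history lives in rare variants
and long shared haplotypes. stratsim builds cohorts under explicit versions
of these histories and measures what each correction can and cannot remove
from association statistics, polygenic scores, sibling designs, and
gene-burden tests.

# Demographic models

All three models place demes on a 6×6 lattice with symmetric stepping-stone
(rook-adjacency) migration at per-generation rate *m* and 10,000 diploids
per deme; the ancestral population also has 10,000 diploids.

* **perpetual** — the grid extends indefinitely into the past.
* **recent** — all 36 demes collapse into one ancestral population
  τ = 100 generations ago.
* **complex** — demes are founded 100 generations ago by admixture between
  two source populations along a north–south cline; the sources exchange
  migrants at `m1 = 0.004` (calibrated to a between-source FST of roughly
  0.004) and merge further back. Deeper ancient layers
  (hunter-gatherer/farmer-style splits and mixtures) are accepted as a
  configurable event stack (`admixture_spec(ancient_layers = ...)`); no
  default deep history is imposed because those parameters are not part of
  the calibrated design. A shipped synthetic 35-region adjacency with
  non-uniform sampling weights (one Cornwall-like region sampled at 17
  rather than 250 individuals) supports irregular geographies; it is
  synthetic and not derived from any real administrative map.

Migration entries are the proportion of a deme replaced by migrants from
each neighbour per generation. The coalescent engine (msprime, driven
through a bundled Python script) uses backward-time rates; for a symmetric
matrix the numbers coincide, and that mapping is made in exactly one place
(the driver).

Calibration anchors the rates: with a 10 Mb genome (10 × 1 Mb chromosomes,
mutation and recombination 1e-8 per bp per generation) and 250 individuals
per deme, `run_calibration()` reports mean Weir–Cockerham FST on LD-pruned
common variants and the median inflation of a covariate-free GWAS on the
two grid coordinates. Rates of 0.05 (recent) and 0.07 (perpetual) reproduce
a UK-Biobank-like degree of structure (FST of a few 1e-4 and
λ~latitude~ ≈ 1.7 at N = 9,000, consistent with λ ≈ 13 at N = 300,000 under
the linear sample-size rescaling λ_N = (N/N0)(λ_N0 − 1) + 1).

Replicate genomes matter when comparing against any single reference
realization: across independent cohort seeds at m = 0.05 the realized mean
FST has a between-replicate standard deviation near 10% of its value (and
λ − 1 near 20%), which is comparable to a variant-resampling CI on one
genome. At the calibrated rates this package's rook-adjacency grid tends to
realize structure at the upper edge of the reference range; at m = 0.001
(drift-dominated) and for the perpetual model it sits squarely inside it.

## The perpetual model and its strong-migration closure

The exact τ = ∞ stepping-stone coalescent at these sizes has a
metapopulation TMRCA of order 1.4 million generations, and the engine must
simulate every migration event along the way; a single 1 Mb chromosome with
18,000 samples does not finish in tractable time. stratsim therefore closes
the perpetual model at a *horizon*: the stepping-stone system is simulated
exactly for the most recent `perpetual_horizon` generations (default 5,000)
and replaced beyond it by a single panmictic population of the total
metapopulation size (360,000 diploids). This is the standard
strong-migration limit: the grid's lineage-mixing time is about
n_demes/m ≈ 500 generations at the calibrated rate, so by 5,000 generations
lineage locations carry no information and the structured coalescent is
indistinguishable from panmixia at the metapopulation size. Diversity is
horizon-insensitive (doubling the horizon changes the number of segregating
sites by ~0.1%), and the test suite verifies on a small, fast system
(2×2 grid, Ne = 500) that exact τ = ∞ and horizon-closed runs agree in both
diversity and realized FST. `perpetual_horizon = Inf` requests the exact
model.

Because the deep metapopulation coalescent carries ~14× the diversity of
the recent model, perpetual-model analyses use a 10 × 100 kb genome: FST
and PC contrasts are per-variant quantities, and 1 Mb of perpetual sequence
already yields several times more common variants than the 10 Mb
recent-model design.

# The synthetic-data generator

`simulate_cohort()` runs one coalescent replicate per chromosome
(independent replicates with derived seeds — matching the "many independent
chromosomes" design and keeping memory bounded) and stores tree sequences,
per-variant derived-allele counts, and per-class dosage matrices. Mutations
are placed under an infinite-sites model, so every variant is biallelic
with ancestral state 0; positions are continuous 0-based internally and
1-based integers in VCF export. Dosage matrices are variants × individuals
with entries 0/1/2, extracted lazily per chromosome so that cohorts larger
than memory can be processed streaming. The stored genealogies provide
*exact* identity-by-descent segments (maximal intervals with a shared most
recent common ancestor); in real data an IBD detector would stand in this
slot, so IBD results here are an upper bound on what detection-based
pipelines can achieve.

Variant classes follow the study's definitions: *common* means minor allele
frequency strictly above 0.05; *rare* means minor allele count 2–4;
*ultra-rare* means derived frequency below 0.001. Classification is done in
the analyzed sample (e.g. the training half for GWAS-side steps).

What the generator emulates: frequency spectra under each demography,
geographic clustering of rare variants, linkage within chromosomes,
Hardy–Weinberg genotypes, exchangeable individuals within demes. What it
does not: genotyping error, array ascertainment, imputation artifacts,
assortative mating, selection, or real LD structure from variable
recombination maps. Passing tests therefore demonstrate properties of the
idealized sampling process, not robustness to those real-data features.

# Phenotypes

Non-heritable phenotypes are y ~ N(μ_j, σ²) with deme means μ_j either
*smooth* (linear in the grid row, anchored at 0 in the northernmost row and
rising to 2σ in the southernmost, so the north–south difference is two
residual standard deviations) or *sharp* (2σ in one affected deme, zero
elsewhere).

Heritable traits pick one causal variant uniformly at random per 100 kb
window (2,000 at the 200 Mb full design) and draw effects
β_k ~ N(0, σ_l²[2p_k(1−p_k)]^α) with α = −0.4 (a height-like coupling of
effect size to frequency) and σ_l² solved so that
σ_g² = σ_l² Σ[2p_k(1−p_k)]^{α+1} = h² (default 0.8). With this convention
the defining identity Var(Σβ_k x_k) = h² holds exactly in expectation; a
variant's dosage variance is 2p(1−p), so writing the β-variance with
p(1−p) instead (as sometimes printed) would inflate realized variance by
2^{−α}. The per-variant contribution to σ_g² is constant at α = −1 and
proportional to heterozygosity at α = 0. Environmental noise for heritable
traits uses σ = sqrt(1 − h²), expressing the 2σ structured shift relative
to the residual scale; the absolute scale of that shift is a design choice
since only relative magnitudes matter to every statistic downstream. All
components (g, deme mean, noise) are stored, never reconstructed.

# Association machinery

`gwas_linear()` is per-variant OLS with an intercept and arbitrary
covariates (the 100-PC sets, or 50 common- + 50 rare-PCs); covariates are
projected out once, and p-values use the t distribution with n − k − 2
degrees of freedom. `gwas_lmm_loco()` is a leave-one-chromosome-out mixed
model: for each chromosome the GRM is rebuilt from all other chromosomes
(avoiding proximal contamination), variance components are estimated by
restricted likelihood profiled on a one-dimensional heritability-ratio grid
in the GRM eigenbasis, and each variant is tested by generalized least
squares in that basis; forcing the ratio to zero reproduces OLS exactly.
`sib_difference_test()` regresses within-pair phenotype differences on
dosage differences without an intercept (Mendelian segregation makes
E[Δx] = 0; an intercept would only absorb noise), which cancels any
deme-level environment shared by siblings.

Genomic inflation λ_p divides the p-th percentile of the observed χ²
statistics by the χ²₁ quantile; the median (p = 0.5) is the standard
factor, and p = 0.999 is the tail variant that exposes local effects, which
move only the extreme statistics. FST is the multi-population
Weir–Cockerham (1984) estimator accumulated as a ratio of averages
(Σa / Σ(a+b+c)), with a block bootstrap over 1 Mb variant blocks for the
CI (nearby variants share genealogies, so an i.i.d. bootstrap would be
anti-conservative; the source study does not state its CI method). LD
pruning mirrors the quoted window/step/threshold parameters (100 variants,
step 10, r² > 0.1), removing the later-position variant of each correlated
pair.

# Polygenic scores and sibling designs

Lead-SNP ascertainment is clumping-and-thresholding: each tested variant
belongs to the nearest causal variant within ±50 kb (windows are centered
on causal variants, the natural reading of "a 100 kb window around" them);
per window the minimum-p variant is selected iff p < 5e-4, ties broken by
position, and the same threshold applies in "causal" mode. Scores are
Σβ̂x in a held-out test half; the *residual* score subtracts the true
simulated genetic value, isolating bias, and is mapped as per-deme means
(empty demes are missing, never zero). Sibling pairs are generated by
within-deme matings (parents drawn without replacement, two children per
pair); each child inherits one whole haplotype per chromosome from each
parent — transmission without recombination, applied per chromosome as the
biologically coherent unit. The hybrid design keeps GWAS ascertainment but
reestimates effects by sib-difference regression in an independent set of
individuals from the same simulated population (disjoint individuals, with
an explicit overlap guard); variants monomorphic in the second cohort get
effect zero and are counted.

# Gene burden

Genes have eight 160 bp exons; without recombination the 6,938 bp introns
are dropped (they cannot affect a non-recombining genealogy), with
recombination they are simulated as spacers. Each gene is an independent
coalescent replicate; replicate sample k is identified with cohort
individual k, which is valid because individuals are exchangeable within
demes across replicates. Burden is the count of derived alleles at exonic
variants below frequency 0.001 in the analyzed sample (strict inequality).
To compare spatial clustering across demographies without confounding by
variant counts, `match_variant_counts()` thins each perpetual-model gene to
a count drawn from N(16, 4²) — the recent-model mean and sd. Spatial
concentration uses the Gini coefficient on cumulative per-deme burden
shares sorted increasing, G = (n − y₁ − Σ_{1<i≤n}(y_i + y_{i−1}))/n, read
with y_n normalized to 1 (the only unit-consistent reading of the
formula): 0 for a uniform burden, (n−1)/n when one deme holds everything.
The stated gene geometry implies ~50 kb genes with introns, while the
"average gene" description suggests ~7 kb; the methods numbers are
implemented and the intron length left configurable rather than resolving
the discrepancy.

# Numerical choices

* Eigendecomposition operates on the n×n GRM (the IBD GRM has no variant
  matrix to SVD), after double-centering (removing the all-ones direction;
  plain column-centering would break symmetry). Eigenvector signs are fixed
  by making each column's largest-magnitude loading positive.
* For large n with k ≪ n, the top-k subspace comes from blocked orthogonal
  iteration (40 iterations, 10 oversampling columns, deterministic start),
  not a full eigendecomposition; the test suite checks agreement with the
  dense path on gapped spectra.
* IBD sharing between individuals sums segment lengths over the four
  haplotype pairings and divides by twice the haploid genome length, so a
  duplicated individual scores 1 and full siblings without recombination
  average 1/2 with per-chromosome sharing in {0, 1/2, 1}; entries are
  capped at 1.
* Stratified train/test splits give each deme `ceiling(fraction * n_j)`
  training individuals (the extra individual of an odd deme goes to
  training).
* Every stochastic stage derives its seed from a master seed and a stage
  name (`derive_seed()`), all below 2^31, so a single integer reproduces an
  entire experiment, including the study's 20 phenotype iterations.

# Problem sizes

The full published design (200 Mb genomes, 18,000 individuals, 10^5 genes,
10^5–10^6 PCA variants) is cluster-scale. The package's experiments,
tests and the acceptance script run the same machinery at desk scale, as
the package's own documented problem sizes:

* Calibration quantities (FST, λ_location): the full 10 Mb / 250-per-deme
  design, since they reproduce well there (the perpetual model at
  10 × 100 kb, see above).
* PC-contrast analyses: N = 9,000 with GRMs from up to 15,000 variants per
  class. At this scale the leading PCs of both common- and rare-variant
  GRMs sit *below* the spiked-eigenvalue detection threshold — structure is
  detectable only when FST·sqrt(n·M_eff) is well above 1 per spatial mode,
  which the full design exceeds roughly tenfold but no desk-scale design
  can reach (in the perpetual model LD further caps M_eff near 15,000 per
  Mb). Both variance-explained values therefore land near the regression
  floor k/n rather than at the full-scale contrast, and stratsim reports
  them as computed; the inflation and polygenic-score analyses do not
  depend on the PCs capturing structure (their headline effects come from
  the uncorrected confounding itself).
* Gene burden: 150–300 genes (the mean count's standard error is
  4/sqrt(n_genes), ample for a ±2 comparison); the engine's structured
  recent phase costs about a second per gene, which is what rules out
  10^5.
* Inflation and polygenic-score experiments: N = 4,320–4,500 cohorts,
  10 Mb genomes, 2–3 phenotype iterations instead of 20.

# Known limitations

* The perpetual model is exact only up to the strong-migration closure
  (validated, but a closure nonetheless) unless `perpetual_horizon = Inf`.
* Desk-scale PCA cannot exhibit the full-scale rare-vs-common PC contrast
  (see above); conclusions about PC-based corrections at full scale rest on
  the mechanism, not on desk-scale reproduction.
* Exact genealogical IBD replaces a detector; real-data users must
  substitute one and expect detection noise.
* No imputation, fine-mapping, array ascertainment, dominance, epistasis,
  or gene–environment interaction beyond additive structured means.
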