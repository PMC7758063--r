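Package: stratsim
Title: Simulating Population Stratification in GWAS Under Explicit Demographic Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent simulation of GWAS cohorts on stepping-stone deme grids under
    perpetual, recent, and complex (admixture-cline) demographic histories, with tools to
    measure how well common-variant, rare-variant, and identity-by-descent based
    corrections remove population stratification from association statistics, polygenic
    scores, sibling designs, and gene-burden tests. Includes Weir-Cockerham FST,
    percentile genomic inflation factors, frequency-stratified PCA of genetic relatedness
    matrices, LOCO mixed-model association, sibling-difference tests, lead-SNP polygenic
    score construction with residual bias maps, and Gini-based spatial clustering of
    rare-variant burden. Genotypes are generated with the msprime coalescent engine
    through a bundled Python driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
SystemRequirements: Python (>= 3.8) with msprime (>= 1.0), tskit, numpy, pyarrow available as 'python'
Config/testthat/edition: 3
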