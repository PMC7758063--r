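#' Genome specification for cohort simulation
#'
#' Chromosomes are simulated as independent coalescent replicates of the same
#' demography and concatenated. Rates are per base per generation.
#'
#' @param n_chromosomes,chromosome_length Number and length (bp) of chromosomes.
#' @param mutation_rate,recombination_rate Per-bp per-generation rates
#'   (default 1e-8 each, so 1 cM corresponds to 1 Mb).
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(n_chromosomes, chromosome_length,
                        mutation_rate = 1e-8, recombination_rate = 1e-8) {
  stopifnot(n_chromosomes >= 1, chromosome_length > 0,
            mutation_rate >= 0, recombination_rate >= 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = chromosome_length,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @details `genome_calibration()` is the 10 x 1 Mb migration-calibration
#'   preset; `genome_main()` is the 20 x 10 Mb preset used for the main
#'   experiments at full scale.
#' @export
genome_calibration <- function() genome_spec(10L, 1e6)

#' @rdname genome_spec
#' @export
genome_main <- function() genome_spec(20L, 1e7)

#' Simulate a genotyped cohort under a demographic model
#'
#' Runs the coalescent engine once per chromosome (with seeds derived from
#' `seed`) and stores tree sequences plus per-variant derived-allele counts in
#' `dir`. Genotype matrices are not loaded into memory here; extract them with
#' [get_dosages()] / [get_haplotypes()]. The stored genealogies back exact IBD
#' extraction ([ibd_sharing_grm()]).
#'
#' @param demography A [build_demography()] spec.
#' @param genome A [genome_spec()].
#' @param n_per_deme Diploid individuals sampled per deme, either a single
#'   count or a named vector (deme id -> count) for non-uniform sampling.
#' @param seed Integer master seed; the run is fully reproducible from it.
#' @param dir Directory for the simulation store (default: fresh tempdir).
#' @return A `genotype_dataset`: sample table (`samples`), variant table
#'   (`variants`: chrom, row, pos, dcount), haplotype count, and the store path.
#' @export
simulate_cohort <- function(demography, genome, n_per_deme, seed,
                            dir = tempfile("stratsim_")) {
  stopifnot(inherits(demography, "demography_spec"), inherits(genome, "genome_spec"))
  if (any(n_per_deme <= 0)) stop("n_per_deme must be positive")
  seed <- as.integer(seed)
  samples_cfg <- if (length(n_per_deme) == 1L && is.null(names(n_per_deme))) {
    as.integer(n_per_deme)
  } else {
    if (!all(names(n_per_deme) %in% demography$deme_ids))
      stop("named n_per_deme must use deme ids of the demography")
    as.list(round(n_per_deme))
  }
  cfg <- list(
    demography = jsonlite::fromJSON(demography_to_json(demography),
                                    simplifyVector = TRUE),
    genome = unclass(genome),
    samples = samples_cfg,
    seed = seed
  )
  cfg$demography$deme_ids <- I(cfg$demography$deme_ids)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config.json")
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                           null = "null")), cfg_path)
  run_driver(c("simulate", "--config", cfg_path, "--out", dir))

  samples <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(demography$grid)) {
    co <- demography$grid$coords
    samples$row <- co$row[match(samples$deme, co$deme)]
    samples$col <- co$col[match(samples$deme, co$deme)]
  }
  variants <- do.call(rbind, lapply(seq_len(genome$n_chromosomes), function(ch) {
    v <- as.data.frame(arrow::read_feather(
      file.path(dir, sprintf("variants_chr%d.feather", ch))))
    data.frame(chrom = rep(ch, nrow(v)), row = seq_len(nrow(v)),
               pos = v$pos, dcount = v$dcount)
  }))
  structure(list(dir = dir, samples = samples, variants = variants,
                 n_individuals = nrow(samples), n_haplotypes = 2L * nrow(samples),
                 individuals = seq_len(nrow(samples)),
                 genome = genome, demography = demography, seed = seed),
            class = "genotype_dataset")
}

#' Reopen an existing simulation store
#'
#' Rebuilds the `genotype_dataset` object from a directory written by
#' [simulate_cohort()] without re-running the engine (resume support).
#'
#' @param dir Simulation store directory.
#' @export
load_cohort <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- meta$config
  demography <- demography_from_json(jsonlite::toJSON(cfg$demography,
                                                      auto_unbox = TRUE, digits = NA,
                                                      null = "null"))
  genome <- genome_spec(cfg$genome$n_chromosomes, cfg$genome$chromosome_length,
                        cfg$genome$mutation_rate, cfg$genome$recombination_rate)
  samples <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(demography$grid)) {
    co <- demography$grid$coords
    samples$row <- co$row[match(samples$deme, co$deme)]
    samples$col <- co$col[match(samples$deme, co$deme)]
  }
  variants <- do.call(rbind, lapply(seq_len(genome$n_chromosomes), function(ch) {
    v <- as.data.frame(arrow::read_feather(
      file.path(dir, sprintf("variants_chr%d.feather", ch))))
    data.frame(chrom = rep(ch, nrow(v)), row = seq_len(nrow(v)),
               pos = v$pos, dcount = v$dcount)
  }))
  structure(list(dir = dir, samples = samples, variants = variants,
                 n_individuals = nrow(samples), n_haplotypes = 2L * nrow(samples),
                 individuals = seq_len(nrow(samples)),
                 genome = genome, demography = demography, seed = cfg$seed),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset>", length(x$individuals), "of", x$n_individuals,
      "individuals,", nrow(x$variants), "variants,",
      x$genome$n_chromosomes, "chromosomes\n")
  invisible(x)
}

#' Restrict a dataset to a subset of individuals
#'
#' Returns a view of the same simulation store restricted to `individuals`
#' (indices into the full sample table). Dosage/haplotype extraction and the
#' sample table respect the restriction; stored variant counts still refer to
#' the full cohort (recompute frequencies from extracted dosages when
#' classification must be relative to the subset).
#'
#' @param dataset A `genotype_dataset`.
#' @param individuals Integer indices (1-based, full-cohort numbering).
#' @export
subset_individuals <- function(dataset, individuals) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  individuals <- sort(unique(as.integer(individuals)))
  if (any(individuals < 1 | individuals > dataset$n_individuals))
    stop("individual indices out of range")
  dataset$individuals <- individuals
  dataset
}

#' Active sample table of a dataset view
#' @param dataset A `genotype_dataset`.
#' @export
sample_table <- function(dataset) dataset$samples[dataset$individuals, , drop = FALSE]

#' Classify variants by frequency
#'
#' Class boundaries follow the study's definitions: `common` is minor allele
#' frequency strictly greater than 0.05; `rare_mac` is minor allele count 2, 3
#' or 4; `ultra_rare` is derived-allele frequency below 0.001 (monomorphic
#' sites belong to no class).
#'
#' @param dataset A `genotype_dataset`, or a list with elements `variants`
#'   (data frame with `dcount`) and `n_haplotypes`.
#' @param class One of "common", "rare_mac", "ultra_rare".
#' @param counts Optional replacement derived counts (e.g. recomputed on a
#'   subset of individuals) aligned with the variant table.
#' @param n_haplotypes Haplotype count matching `counts` when supplied.
#' @return A `variant_set`: the variant-table rows of the class, with a
#'   `class` attribute.
#' @export
classify_variants <- function(dataset, class = c("common", "rare_mac", "ultra_rare"),
                              counts = NULL, n_haplotypes = NULL) {
  class <- match.arg(class)
  v <- dataset$variants
  if (nrow(v) == 0L) stop("dataset has no variants")
  nh <- if (is.null(n_haplotypes)) dataset$n_haplotypes else n_haplotypes
  dc <- if (is.null(counts)) v$dcount else counts
  stopifnot(length(dc) == nrow(v))
  freq <- dc / nh
  mac <- pmin(dc, nh - dc)
  keep <- switch(class,
    common = pmin(freq, 1 - freq) > 0.05,
    rare_mac = mac >= 2L & mac <= 4L,
    ultra_rare = dc > 0L & freq < 0.001
  )
  keep <- keep & dc > 0L & dc < nh
  out <- v[keep, , drop = FALSE]
  structure(out, class = c("variant_set", "data.frame"), variant_class = class)
}

#' Uniform subsample of a variant set
#'
#' @param set A `variant_set` (or variant-table data frame).
#' @param k Number of variants to keep (without replacement).
#' @param seed Integer seed; the draw is deterministic per seed.
#' @export
subsample_variants <- function(set, k, seed) {
  if (k > nrow(set)) stop("k exceeds the number of variants in the set")
  if (k == nrow(set)) return(set)
  seed <- as.integer(seed)  # force before the RNG state is saved
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    idx <- sort(sample.int(nrow(set), k))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    idx
  })
  out <- set[rng, , drop = FALSE]
  attr(out, "variant_class") <- attr(set, "variant_class")
  out
}

#' Stratified train/test split
#'
#' Splits the cohort into a training and a test view with each deme
#' contributing `fraction` of its individuals to training (the first
#' `ceiling(fraction * n_j)` individuals of each deme, so odd counts give the
#' extra individual to training).
#'
#' @param dataset A `genotype_dataset` (full cohort).
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @return List with `train` and `test` dataset views (disjoint, covering all
#'   individuals).
#' @export
split_train_test <- function(dataset, fraction = 0.5) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be strictly inside (0, 1)")
  tr <- unlist(lapply(split(seq_len(dataset$n_individuals), dataset$samples$deme),
                      function(ix) ix[seq_len(ceiling(fraction * length(ix)))]))
  tr <- sort(unname(tr))
  te <- setdiff(seq_len(dataset$n_individuals), tr)
  if (length(te) == 0L) stop("test set is empty")
  list(train = subset_individuals(dataset, tr),
       test = subset_individuals(dataset, te))
}

variant_indices_by_chrom <- function(variants) split(variants$row - 1L, variants$chrom)

export_cache_path <- function(dataset, key_parts) {
  tf <- tempfile()
  writeLines(paste(key_parts, collapse = "|"), tf)
  key <- unname(tools::md5sum(tf))
  unlink(tf)
  file.path(dataset$dir, paste0("cache_", key, ".feather"))
}

extract_matrix <- function(dataset, what, variants = NULL, class = NULL,
                           max_variants = NULL, subsample_seed = NULL) {
  chroms <- seq_len(dataset$genome$n_chromosomes)
  filt <- character(0)
  if (!is.null(class)) {
    nh <- dataset$n_haplotypes
    filt <- switch(class,
      common = c("--mafmin", "0.05"),
      rare_mac = c("--macmin", "2", "--macmax", "4"),
      ultra_rare = c("--dmin", "1", "--dmax",
                     as.character(max(1L, ceiling(0.001 * nh) - 1L))),
      all = character(0),
      stop("unknown class filter")
    )
  }
  per_chrom_cap <- if (!is.null(max_variants))
    ceiling(max_variants / length(chroms))
  idx_by_chrom <- if (!is.null(variants)) variant_indices_by_chrom(variants)
  # pass 1: make sure every per-chromosome export exists, count rows
  caches <- character(0); cache_ch <- integer(0)
  pre_tag <- if (what == "dosage" && is.null(variants) &&
                 !is.null(class) && class %in% c("common", "rare_mac")) {
    c(common = "common", rare_mac = "raremac")[[class]]
  }
  for (ch in chroms) {
    if (!is.null(pre_tag)) {
      pre <- file.path(dataset$dir, sprintf("pre_%s_chr%d.feather", pre_tag, ch))
      if (file.exists(pre)) {
        caches <- c(caches, pre); cache_ch <- c(cache_ch, ch)
        next
      }
    }
    args <- c("export", "--dir", dataset$dir, "--chrom", ch, "--what", what)
    key <- c(what, ch, filt)
    if (!is.null(variants)) {
      ix <- idx_by_chrom[[as.character(ch)]]
      if (is.null(ix) || length(ix) == 0L) next
      idxfile <- tempfile(fileext = ".txt")
      writeLines(format(ix, scientific = FALSE, trim = TRUE), idxfile)
      args <- c(args, "--indices", idxfile)
      key <- c(key, "idx", ix)
    } else {
      args <- c(args, filt)
      if (!is.null(per_chrom_cap)) {
        sseed <- if (is.null(subsample_seed)) 1L else subsample_seed + ch
        args <- c(args, "--max-variants", per_chrom_cap, "--subsample-seed", sseed)
        key <- c(key, "cap", per_chrom_cap, sseed)
      }
    }
    cache <- export_cache_path(dataset, key)
    if (!file.exists(cache)) run_driver(c(args, "--out", cache))
    if (!is.null(variants)) unlink(args[which(args == "--indices") + 1L])
    caches <- c(caches, cache); cache_ch <- c(cache_ch, ch)
  }
  n_keep <- length(dataset$individuals) * (if (what == "dosage") 1L else 2L)
  if (length(caches) == 0L)
    return(structure(matrix(integer(0), 0, n_keep),
                     variants = dataset$variants[0, ]))
  counts <- vapply(caches, function(f)
    nrow(arrow::read_feather(f, col_select = "pos")), integer(1))
  # when precomputed class exports are used, apply any variant cap here (the
  # exporter applies it itself on the slow path)
  rows_keep <- vector("list", length(caches))
  if (!is.null(pre_tag) && !is.null(per_chrom_cap)) {
    for (i in seq_along(caches)) {
      if (counts[i] > per_chrom_cap) {
        sseed <- if (is.null(subsample_seed)) 1L else subsample_seed + cache_ch[i]
        old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
        set.seed(sseed)
        rows_keep[[i]] <- sort(sample.int(counts[i], per_chrom_cap))
        if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
        counts[i] <- per_chrom_cap
      }
    }
  }
  keep_cols <- if (what == "dosage") dataset$individuals
               else sort(c(2L * dataset$individuals - 1L, 2L * dataset$individuals))
  full <- n_keep == (dataset$n_individuals * (if (what == "dosage") 1L else 2L))
  # pass 2: fill a preallocated matrix, freeing each piece as we go
  m <- matrix(0L, sum(counts), n_keep)
  info <- vector("list", length(caches))
  at <- 0L
  for (i in seq_along(caches)) {
    piece <- read_feather_matrix(caches[i], if (what == "dosage") "g" else "h")
    if (!is.null(rows_keep[[i]])) {
      piece$matrix <- piece$matrix[rows_keep[[i]], , drop = FALSE]
      piece$info <- piece$info[rows_keep[[i]], , drop = FALSE]
    }
    rows <- at + seq_len(counts[i])
    m[rows, ] <- if (full) piece$matrix else piece$matrix[, keep_cols, drop = FALSE]
    piece$matrix <- NULL
    info[[i]] <- data.frame(chrom = cache_ch[i], row = piece$info$vidx,
                            pos = piece$info$pos, dcount = piece$info$dcount)
    rm(piece)
    at <- at + counts[i]
  }
  structure(m, variants = do.call(rbind, info))
}

#' Extract genotype matrices from a simulated cohort
#'
#' Returns an integer matrix with one row per variant and one column per
#' (active) individual; entries are derived-allele dosages 0/1/2
#' (`get_haplotypes`: one column per haplotype, entries 0/1). The matching
#' variant table is attached as attribute `"variants"`.
#'
#' Exactly one of `variants` (explicit rows of the variant table, e.g. a
#' [classify_variants()] result) or `class` (filter evaluated in the exporter
#' over the full cohort: "common", "rare_mac", "ultra_rare", "all") is used;
#' `max_variants` uniformly subsamples a large class at export time.
#'
#' @param dataset A `genotype_dataset`.
#' @param variants Optional `variant_set` rows to extract.
#' @param class Optional class filter (full-cohort frequencies).
#' @param max_variants,subsample_seed Cap and seed for export-time subsampling.
#' @export
get_dosages <- function(dataset, variants = NULL, class = NULL,
                        max_variants = NULL, subsample_seed = NULL) {
  if (is.null(variants) && is.null(class)) class <- "all"
  extract_matrix(dataset, "dosage", variants, class, max_variants, subsample_seed)
}

#' @rdname get_dosages
#' @export
get_haplotypes <- function(dataset, variants = NULL, class = NULL,
                           max_variants = NULL, subsample_seed = NULL) {
  if (is.null(variants) && is.null(class)) class <- "all"
  extract_matrix(dataset, "haplotype", variants, class, max_variants, subsample_seed)
}

#' Write a cohort (or a variant subset) as VCF 4.2
#'
#' The derived allele is written as ALT (`A` ancestral / `T` derived,
#' placeholders since alleles are simulated), genotypes as unphased GT.
#' Internal positions are 0-based continuous coordinates; VCF positions are
#' `floor(pos) + 1` (1-based), so records keep the variant-table order and a
#' round-trip through [import_vcf_dosages()] reproduces the dosage matrix
#' exactly.
#'
#' @param dataset A `genotype_dataset`.
#' @param path Output path (plain text).
#' @param variants Optional `variant_set`; default all variants.
#' @export
export_vcf <- function(dataset, path, variants = NULL) {
  dos <- get_dosages(dataset, variants = variants,
                     class = if (is.null(variants)) "all")
  v <- attr(dos, "variants")
  ids <- sample_table(dataset)$id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=stratsim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  if (nrow(dos) > 0) {
    gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nrow(dos))
    body <- paste(v$chrom, floor(v$pos) + 1L, paste0("v", seq_len(nrow(dos))),
                  "A", "T", ".", "PASS", ".", "GT", sep = "\t")
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname export_vcf
#' @details `import_vcf_dosages()` reads a VCF back into a dosage matrix
#'   (variants x individuals) using the vcfR parser.
#' @param vcf_path Path to a VCF file.
#' @export
import_vcf_dosages <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("import_vcf_dosages requires the vcfR package")
  x <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  gt <- vcfR::extract.gt(x, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) {
    m <- matrix(integer(0), 0, 0)
  } else {
    m <- matrix(0L, nrow(gt), ncol(gt))
    m[gt == "0/1" | gt == "1/0" | gt == "0|1" | gt == "1|0"] <- 1L
    m[gt == "1/1" | gt == "1|1"] <- 2L
    dimnames(m) <- NULL
  }
  m
}

#' Export plain-text summary tables for a cohort
#'
#' Writes the sample table, the variant table and run metadata (seed,
#' parameters, engine version) to `dir` as TSV/JSON.
#'
#' @param dataset A `genotype_dataset`.
#' @param dir Output directory.
#' @export
export_summary_tables <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sample_table(dataset), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- jsonlite::fromJSON(file.path(dataset$dir, "meta.json"),
                             simplifyVector = TRUE)
  writeLines(as.character(jsonlite::toJSON(
    list(seed = dataset$seed, engine = meta$engine,
         genome = unclass(dataset$genome),
         model = dataset$demography$kind), auto_unbox = TRUE, digits = NA)),
    file.path(dir, "run_meta.json"))
  invisible(dir)
}
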