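#' Define a lattice grid of demes
#'
#' Describes a rectangular stepping-stone arrangement of demes. Row 0 is the
#' northernmost row; deme ids are assigned in row-major order ("d0", "d1", ...).
#'
#' @param n_rows,n_cols Grid dimensions (default 6 x 6).
#' @return A `grid_spec` object: list with `n_rows`, `n_cols`, `deme_ids`, and a
#'   data frame `coords` with 0-based `row` and `col` per deme.
#' @export
grid_spec <- function(n_rows = 6L, n_cols = 6L) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  n <- n_rows * n_cols
  idx <- seq_len(n) - 1L
  coords <- data.frame(
    deme = paste0("d", idx),
    row = idx %/% n_cols,
    col = idx %% n_cols,
    stringsAsFactors = FALSE
  )
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         deme_ids = coords$deme, coords = coords),
    class = "grid_spec"
  )
}

#' Stepping-stone migration matrix on a grid
#'
#' Builds the symmetric per-generation migration matrix for rook (4-neighbour)
#' adjacency on a lattice grid. Entries are the proportion of a deme replaced by
#' migrants from each neighbouring deme per generation; corner demes have two
#' nonzero entries, edge demes three, interior demes four.
#'
#' @param grid A [grid_spec()].
#' @param m Per-generation migration rate between adjacent demes (>= 0).
#' @return Square symmetric matrix with zero diagonal, dimnames = deme ids.
#' @export
build_grid_migration_matrix <- function(grid, m) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop("migration rate 'm' must be a single non-negative number")
  n <- length(grid$deme_ids)
  M <- matrix(0, n, n, dimnames = list(grid$deme_ids, grid$deme_ids))
  rows <- grid$coords$row; cols <- grid$coords$col
  for (i in seq_len(n)) {
    # south and east neighbours; symmetry fills the rest
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      r2 <- rows[i] + d[1]; c2 <- cols[i] + d[2]
      if (r2 < grid$n_rows && c2 < grid$n_cols) {
        j <- r2 * grid$n_cols + c2 + 1L
        M[i, j] <- M[j, i] <- m
      }
    }
  }
  M
}

#' Migration matrix from an adjacency list
#'
#' Builds a migration matrix for an arbitrary geography (e.g. administrative
#' regions): the rate is `m` where two demes abut and zero otherwise.
#'
#' @param adjacency Two-column matrix or data frame of deme-id pairs (character),
#'   interpreted as undirected edges.
#' @param m Per-generation migration rate for abutting demes.
#' @param deme_ids Optional full set of deme ids (so isolated demes appear);
#'   defaults to the ids present in `adjacency`.
#' @return Square symmetric matrix with zero diagonal.
#' @export
build_adjacency_migration_matrix <- function(adjacency, m, deme_ids = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m < 0)
    stop("migration rate 'm' must be a single non-negative number")
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L && length(adjacency) != 0L)
    stop("adjacency must have two columns")
  if (is.null(deme_ids)) deme_ids <- sort(unique(as.character(adjacency)))
  n <- length(deme_ids)
  M <- matrix(0, n, n, dimnames = list(deme_ids, deme_ids))
  if (nrow(adjacency) > 0) {
    a <- as.character(adjacency[, 1]); b <- as.character(adjacency[, 2])
    if (any(a == b)) stop("self-adjacency is not allowed")
    if (!all(c(a, b) %in% deme_ids)) stop("adjacency refers to unknown deme ids")
    for (k in seq_along(a)) {
      M[a[k], b[k]] <- m
      M[b[k], a[k]] <- m
    }
  }
  M
}

#' Linear north-south admixture cline over a grid
#'
#' Assigns each deme a proportion of ancestry from source population A,
#' interpolated linearly in the row index from `fraction_north` (row 0) to
#' `fraction_south` (last row); all demes in a row share a fraction.
#'
#' @param grid A [grid_spec()].
#' @param fraction_north,fraction_south Source-A ancestry fractions in [0, 1]
#'   at the northern and southern edges.
#' @return Named numeric vector of per-deme fractions.
#' @export
assign_admixture_cline <- function(grid, fraction_north, fraction_south) {
  stopifnot(inherits(grid, "grid_spec"))
  for (f in c(fraction_north, fraction_south))
    if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
      stop("admixture fractions must be in [0, 1]")
  if (grid$n_rows == 1L) {
    fr <- rep(fraction_north, length(grid$deme_ids))
  } else {
    rowfrac <- fraction_north +
      (fraction_south - fraction_north) * grid$coords$row / (grid$n_rows - 1L)
    fr <- rowfrac
  }
  names(fr) <- grid$deme_ids
  fr
}

#' Admixture component of the complex demographic model
#'
#' Describes an admixture event `admixture_time` generations ago in which each
#' deme is founded as a mixture of two source populations (A, B). The sources
#' exchange migrants at rate `m1` while they coexist, and merge into a single
#' ancestral population `source_split_time` generations ago. `ancient_layers`
#' optionally replaces that simple merge with a WHG/EHG/EF-style stack of
#' ancient splits and mergers; each layer is a list with `name`, `size`,
#' `split_time`, and for merges `sources` and `proportions`.
#'
#' @param fractions Per-deme source-A ancestry fractions, e.g. from
#'   [assign_admixture_cline()].
#' @param m1 Per-generation migration rate between the two sources (default
#'   0.004, calibrated to a source-population FST of about 0.004).
#' @param admixture_time Generations before present (default 100).
#' @param source_split_time Generations at which A and B merge into one
#'   ancestral population (default 3000).
#' @param ancient_layers Optional list describing deeper history (passed
#'   through to the simulation driver unchanged).
#' @return An `admixture_spec` object.
#' @export
admixture_spec <- function(fractions, m1 = 0.004, admixture_time = 100,
                           source_split_time = 3000, ancient_layers = NULL) {
  if (any(fractions < 0 | fractions > 1)) stop("admixture fractions must be in [0, 1]")
  stopifnot(m1 >= 0, admixture_time > 0, source_split_time > admixture_time)
  structure(
    list(fractions = fractions, m1 = m1, admixture_time = admixture_time,
         source_split_time = source_split_time, ancient_layers = ancient_layers),
    class = "admixture_spec"
  )
}

#' Build a demographic model specification
#'
#' Assembles the declarative description of one of the three demographic
#' histories consumed by the coalescent engine:
#' \describe{
#'   \item{perpetual}{stepping-stone structure extending indefinitely into the
#'     past (no collapse event).}
#'   \item{recent}{all demes collapse into a single ancestral population
#'     `collapse_time` generations ago (default 100).}
#'   \item{complex}{demes founded `admixture_time` generations ago by admixture
#'     between two source populations along a cline (requires `admixture`).}
#' }
#' All deme sizes and the ancestral size default to 10,000 diploids.
#'
#' Migration-rate semantics: entries of the migration matrix are the proportion
#' of a deme made up of new migrants from each neighbour per generation. The
#' coalescent engine uses the equivalent backward-time rate (the probability
#' per generation that a lineage now in deme i had its parent in deme j),
#' which for a symmetric matrix is numerically identical; the mapping is done
#' once in the simulation driver.
#'
#' @param kind One of "perpetual", "recent", "complex".
#' @param grid A [grid_spec()], or `NULL` when `migration` is supplied for an
#'   adjacency geography.
#' @param m Migration rate between adjacent demes (used to build the matrix
#'   when `migration` is not given).
#' @param deme_Ne,ancestral_Ne Diploid population sizes (default 10,000).
#' @param collapse_time Generations ago at which recent/complex structure
#'   originates (default 100; `Inf` for perpetual).
#' @param migration Optional pre-built migration matrix (overrides `grid` + `m`).
#' @param admixture An [admixture_spec()] (required for "complex").
#' @param perpetual_horizon For the perpetual model only: optional finite time
#'   (generations) at which the engine replaces the stepping-stone system by a
#'   single panmictic population of the total metapopulation size. This is the
#'   strong-migration closure of the same model: beyond a horizon much larger
#'   than the grid mixing time, lineage locations are equilibrated and the
#'   structured coalescent is indistinguishable from panmixia at the
#'   metapopulation size. `Inf` (default) simulates the structure exactly.
#' @return A `demography_spec` object.
#' @export
build_demography <- function(kind = c("perpetual", "recent", "complex"),
                             grid = grid_spec(), m = 0.05,
                             deme_Ne = 10000, ancestral_Ne = 10000,
                             collapse_time = 100, migration = NULL,
                             admixture = NULL, perpetual_horizon = Inf) {
  kind <- match.arg(kind)
  stopifnot(deme_Ne > 0, ancestral_Ne > 0)
  if (is.null(migration)) {
    if (is.null(grid)) stop("either 'grid' or 'migration' must be supplied")
    migration <- build_grid_migration_matrix(grid, m)
  }
  deme_ids <- rownames(migration)
  if (!isSymmetric(unname(migration)) || any(migration < 0) || any(diag(migration) != 0))
    stop("migration matrix must be symmetric, non-negative, zero-diagonal")
  if (kind == "complex") {
    if (is.null(admixture)) stop("the complex model requires an admixture_spec")
    if (!inherits(admixture, "admixture_spec")) stop("'admixture' must be an admixture_spec")
    if (!setequal(names(admixture$fractions), deme_ids))
      stop("admixture fractions must cover exactly the demes of the migration matrix")
    collapse_time <- admixture$admixture_time
  }
  if (kind == "perpetual") collapse_time <- Inf
  if (kind == "recent" && !is.finite(collapse_time))
    stop("the recent model requires a finite collapse time")
  structure(
    list(kind = kind, grid = grid, deme_ids = deme_ids,
         deme_Ne = deme_Ne, ancestral_Ne = ancestral_Ne,
         collapse_time = collapse_time, migration = migration,
         admixture = admixture,
         perpetual_horizon = if (kind == "perpetual") perpetual_horizon else NULL),
    class = "demography_spec"
  )
}

#' @export
print.demography_spec <- function(x, ...) {
  cat("<demography_spec>", x$kind, "model:", length(x$deme_ids), "demes,",
      "deme Ne", x$deme_Ne, "\n")
  if (x$kind == "recent") cat("  collapse at", x$collapse_time, "generations\n")
  if (x$kind == "complex")
    cat("  admixture at", x$admixture$admixture_time, "generations, m1 =",
        x$admixture$m1, "\n")
  invisible(x)
}

#' Serialize / deserialize a demography specification
#'
#' The JSON document records the model kind, geometry, sizes, rates and (for
#' the complex model) the admixture cline, and fully determines the model up to
#' the random seed passed at simulation time.
#'
#' @param spec A `demography_spec`.
#' @param path File path; if `NULL`, `demography_to_json` returns the JSON string.
#' @return `demography_to_json`: path or JSON string. `demography_from_json`:
#'   a `demography_spec`.
#' @export
demography_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "demography_spec"))
  doc <- list(
    kind = spec$kind,
    deme_ids = I(spec$deme_ids),
    grid = if (!is.null(spec$grid))
      list(n_rows = spec$grid$n_rows, n_cols = spec$grid$n_cols),
    deme_Ne = spec$deme_Ne,
    ancestral_Ne = spec$ancestral_Ne,
    collapse_time = if (is.finite(spec$collapse_time)) spec$collapse_time,
    migration = spec$migration,
    perpetual_horizon = if (!is.null(spec$perpetual_horizon) &&
                            is.finite(spec$perpetual_horizon)) spec$perpetual_horizon,
    admixture = if (!is.null(spec$admixture)) list(
      fractions = as.list(spec$admixture$fractions),
      m1 = spec$admixture$m1,
      admixture_time = spec$admixture$admixture_time,
      source_split_time = spec$admixture$source_split_time,
      ancient_layers = spec$admixture$ancient_layers
    )
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname demography_to_json
#' @param json JSON string or path to a JSON file.
#' @export
demography_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  grid <- if (!is.null(doc$grid)) grid_spec(doc$grid$n_rows, doc$grid$n_cols)
  M <- as.matrix(doc$migration)
  dimnames(M) <- list(doc$deme_ids, doc$deme_ids)
  adm <- NULL
  if (!is.null(doc$admixture)) {
    fr <- unlist(doc$admixture$fractions)
    adm <- admixture_spec(fr, m1 = doc$admixture$m1,
                          admixture_time = doc$admixture$admixture_time,
                          source_split_time = doc$admixture$source_split_time,
                          ancient_layers = doc$admixture$ancient_layers)
  }
  build_demography(doc$kind, grid = grid,
                   deme_Ne = doc$deme_Ne, ancestral_Ne = doc$ancestral_Ne,
                   collapse_time = if (is.null(doc$collapse_time)) Inf else doc$collapse_time,
                   migration = M, admixture = adm,
                   perpetual_horizon = if (is.null(doc$perpetual_horizon)) Inf
                                       else doc$perpetual_horizon)
}

#' Shipped synthetic England/Wales-style geography fixture
#'
#' Loads a 35-region adjacency list and non-uniform sampling-weight vector
#' shipped with the package. The geography is synthetic: it mimics the shape of
#' an administrative-region adjacency graph with one heavily down-weighted
#' south-western region (as Cornwall is in UK-Biobank sampling), and is not
#' derived from any real shapefile.
#'
#' @return List with `adjacency` (two-column data frame), `weights` (named
#'   numeric, sums to 1), and `deme_ids`.
#' @export
england_wales_fixture <- function() {
  path <- system.file("extdata", "synthetic_region_adjacency.tsv", package = "stratsim")
  wpath <- system.file("extdata", "synthetic_region_weights.tsv", package = "stratsim")
  adj <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  w <- utils::read.table(wpath, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  weights <- stats::setNames(w$weight, w$deme)
  list(adjacency = adj, weights = weights / sum(weights), deme_ids = w$deme)
}
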