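# shared simulated cohorts, built once per test run
.cohorts <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cohorts[[name]])) .cohorts[[name]] <- builder()
  .cohorts[[name]]
}

# small structured cohort: 2x2 grid, recent model, 2 chromosomes
tiny_cohort <- function() cached("tiny", function() {
  dem <- build_demography("recent", grid_spec(2, 2), m = 0.05)
  simulate_cohort(dem, genome_spec(2, 2e5), n_per_deme = 12, seed = 421)
})

# effectively panmictic: recent model collapsing one generation ago
panmictic_cohort <- function() cached("panmictic", function() {
  dem <- build_demography("recent", grid_spec(2, 2), m = 0.25, collapse_time = 1)
  simulate_cohort(dem, genome_spec(4, 5e5), n_per_deme = 12, seed = 422)
})

# strong two-deme structure (small demes, weak migration) for PCA separation
twopop_cohort <- function() cached("twopop", function() {
  dem <- build_demography("perpetual", grid_spec(1, 2), m = 0.0005,
                          deme_Ne = 500, perpetual_horizon = Inf)
  simulate_cohort(dem, genome_spec(1, 2e5), n_per_deme = 30, seed = 423)
})
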