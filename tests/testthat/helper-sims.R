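# Lazily cached simulations and experiments shared across test files, so the
# expensive 200-year runs are computed once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  .sim_cache[[key]]
}

# A bank of full-length preset simulations.
bank_sims <- function(species, n = 10, years = 200, seed = 7) {
  cached(paste("bank", species, n, years, seed), {
    lapply(seq_len(n), function(i) {
      simulate_pedigree(species_params(species), years,
                        seed = child_seed(seed, 77L, i))
    })
  })
}

# Short simulations for structural module tests.
short_sim <- function(species, years = 80, seed = 3) {
  cached(paste("short", species, years, seed), {
    simulate_pedigree(species_params(species), years, seed = seed)
  })
}

# Species comparison at the reduced study scale (30 populations x 30
# resamples, 30% sampling of 200-year populations).
species_cmp <- function() {
  cached("species_cmp", {
    run_species_comparison(scenario_config(
      sampling_grid = 0.3, n_populations = 30, n_resamples = 30,
      n_years = 200, seed = 101
    ))
  })
}

# Reduced fecundity x sampling grid (red deer demographics, fecundity SD 0).
fec_grid <- function() {
  cached("fec_grid", {
    run_fecundity_sweep(scenario_config(
      fecundity_grid = c(1, 4, 7, 10, 13),
      sampling_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
      n_populations = 20, n_resamples = 30, n_years = 200, seed = 202
    ))
  })
}

# Fecundity 6, SD 0, 50% sampling (the CKMR precision scenario).
fec6_run <- function() {
  cached("fec6_run", {
    run_fecundity_sweep(scenario_config(
      fecundity_grid = 6, sampling_grid = 0.5,
      n_populations = 30, n_resamples = 50, n_years = 200, seed = 303
    ))
  })
}

# Reduced fecundity-SD sweep at fecundity 7.
sd_run <- function() {
  cached("sd_run", {
    run_sd_sweep(scenario_config(
      fecundity_sd_grid = c(0, 2, 4), sampling_grid = c(0.2, 0.5, 0.8),
      n_populations = 6, n_resamples = 10, n_years = 200, seed = 404
    ))
  })
}
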