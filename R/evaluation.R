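# Experiment harness: replicated simulation x resampling grids, relative
# bias (N_hat / N) and coefficient-of-variation summaries. All randomness is
# derived from the config's root seed through child streams, so every
# experiment table is a pure function of its configuration.

#' Relative bias of estimates against the matching true sizes
#'
#' Divides each estimate by the true size of the population class it targets:
#' CKMR and CRE by the adult count, g-CMR by the total count, and the Moment
#' estimator by the breeding-female count. A relative bias of 1 means the
#' estimate matches the truth exactly; undefined estimates (or a zero truth)
#' yield a missing bias.
#'
#' @param estimates Tibble of estimates (rows as from [estimate_all()]).
#' @param truth One-row tibble from [truth_sizes()].
#' @return `estimates` with added columns `n_true` and `bias`.
#' @examples
#' est <- tibble::tibble(method = "CKMR", target = "adult",
#'                       n_hat = 90, defined = TRUE)
#' tru <- tibble::tibble(n_total = 200, n_adult = 100, n_breeding_females = 60)
#' relative_bias(est, tru)$bias
#' @export
relative_bias <- function(estimates, truth) {
  truth_of <- c(adult = truth$n_adult, total = truth$n_total,
                breeding_females = truth$n_breeding_females)
  n_true <- unname(truth_of[estimates$target])
  estimates %>%
    mutate(
      n_true = n_true,
      bias = ifelse(.data$defined & n_true > 0, .data$n_hat / n_true, NA_real_)
    )
}

#' Repeatedly sample one simulated population and estimate its size
#'
#' Draws `n_resamples` independent samples at the given intensity from the
#' standing population, applies all four estimators to each, and returns the
#' per-resample records including each sample's observed POP count. This
#' separates sampling noise (within a population) from process noise (between
#' replicate populations).
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @param fraction Sampling intensity in (0, 1].
#' @param n_resamples Number of independent samples.
#' @param seed Integer seed; resample `r` uses child stream `r`.
#' @return Tibble with `resample`, `fraction`, `method`, `target`, `n_hat`,
#'   `defined`, kin-count columns, `n_true`, `bias`
#'   (`4 * n_resamples` rows).
#' @examples
#' ped <- simulate_pedigree(species_params("wild_boar"), n_years = 40, seed = 1)
#' recs <- resample_population(ped, 0.3, n_resamples = 5, seed = 1)
#' nrow(recs)
#' @export
resample_population <- function(pedigree, fraction, n_resamples, seed) {
  stopifnot(n_resamples >= 1L)
  truth <- truth_sizes(pedigree)
  # sampling and pair detection only ever touch the standing population
  # (sampled parents are necessarily alive), so drop dead rows once up front
  living <- new_kin_pedigree(
    as_tibble(pedigree)[is.na(pedigree$death_year), ],
    params = ped_params(pedigree), final_year = ped_final_year(pedigree),
    seed = ped_seed(pedigree)
  )
  purrr::map_dfr(seq_len(n_resamples), function(r) {
    s <- draw_sample(living, fraction, seed = child_seed(seed, 3L, r))
    relative_bias(estimate_all(s, living), truth) %>%
      mutate(resample = r, fraction = fraction, .before = 1L)
  })
}

#' Summarise relative bias and precision over an experiment's records
#'
#' Aggregates per-resample records into one row per scenario cell and method:
#' the pooled mean and SD of the defined relative biases, the precision
#' `cv_pct` -- by default the per-population coefficient of variation of the
#' bias across resamples (SD/mean x 100), averaged over populations, with its
#' between-population SD -- counts of defined and undefined estimates, and the
#' mean POP count per sample.
#'
#' @param records Record tibble with at least `method`, `bias`, `defined`,
#'   `h_total` and (for the per-population CV) `population` columns.
#' @param ... Optional extra grouping columns (unquoted). By default any of
#'   `species`, `fecundity_mean`, `fecundity_sd`, `fraction` present in
#'   `records` are used alongside `method`.
#' @param pooled_cv If `TRUE`, compute the CV from all defined biases pooled
#'   across populations instead of per-population.
#' @return Tibble with `mean_bias`, `sd_bias`, `cv_pct`, `sd_cv_pct`,
#'   `n_defined`, `n_undefined`, `mean_pops` per group.
#' @export
summarize_bias <- function(records, ..., pooled_cv = FALSE) {
  extra <- sapply(enquos(...), as_name)
  keys <- if (length(extra)) extra else
    intersect(c("species", "fecundity_mean", "fecundity_sd", "fraction"),
              names(records))
  keys <- unique(c(keys, "method"))
  grouped <- records %>% group_by(!!!syms(keys))
  if (!pooled_cv && "population" %in% names(records)) {
    cv_tbl <- records %>%
      group_by(!!!syms(c(keys, "population"))) %>%
      summarise(
        cv = ifelse(sum(.data$defined) >= 2,
                    sd(.data$bias[.data$defined]) /
                      mean(.data$bias[.data$defined]) * 100,
                    NA_real_),
        .groups = "drop"
      ) %>%
      group_by(!!!syms(keys)) %>%
      summarise(cv_pct = mean(.data$cv, na.rm = TRUE),
                sd_cv_pct = sd(.data$cv, na.rm = TRUE), .groups = "drop")
  } else {
    cv_tbl <- grouped %>%
      summarise(
        cv_pct = ifelse(sum(.data$defined) >= 2,
                        sd(.data$bias[.data$defined]) /
                          mean(.data$bias[.data$defined]) * 100, NA_real_),
        sd_cv_pct = NA_real_, .groups = "drop"
      )
  }
  grouped %>%
    summarise(
      mean_bias = mean(.data$bias[.data$defined]),
      sd_bias = sd(.data$bias[.data$defined]),
      n_defined = sum(.data$defined),
      n_undefined = sum(!.data$defined),
      mean_pops = mean(.data$h_total),
      .groups = "drop"
    ) %>%
    left_join(cv_tbl, by = keys) %>%
    select(dplyr::all_of(keys), "mean_bias", "sd_bias", "cv_pct", "sd_cv_pct",
           "n_defined", "n_undefined", "mean_pops")
}

# Shared engine: simulate each scenario's populations once, then resample at
# every sampling intensity (samples depend on the fraction, simulations do
# not, so pedigrees are reused across fractions).
run_scenarios <- function(scen_tbl, sampling_grid, n_populations, n_resamples,
                          n_years, seed) {
  purrr::map_dfr(seq_len(nrow(scen_tbl)), function(si) {
    prm <- scen_tbl$params[[si]]
    labels <- scen_tbl[si, setdiff(names(scen_tbl), "params")]
    purrr::map_dfr(seq_len(n_populations), function(popi) {
      ped <- simulate_pedigree(prm, n_years,
                               seed = child_seed(seed, 10L, si, popi))
      purrr::map_dfr(seq_along(sampling_grid), function(fi) {
        resample_population(ped, sampling_grid[fi], n_resamples,
                            seed = child_seed(seed, 20L, si, popi, fi))
      }) %>%
        mutate(population = popi, .before = 1L)
    }) %>%
      dplyr::bind_cols(labels[rep(1L, nrow(.)), ]) %>%
      select(dplyr::all_of(setdiff(names(scen_tbl), "params")),
             dplyr::everything())
  })
}

new_kin_experiment <- function(records, config, kind) {
  structure(
    list(records = records, summary = summarize_bias(records),
         config = config, kind = kind),
    class = "kin_experiment"
  )
}

#' @export
print.kin_experiment <- function(x, ...) {
  cat("<kin_experiment> ", x$kind, ": ", nrow(x$records), " records, ",
      nrow(x$summary), " summary cells\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Compare the four estimators on the red deer and wild boar presets
#'
#' For each species preset, simulates `n_populations` replicate populations
#' and resamples each `n_resamples` times at the configured sampling
#' intensity (default 30%), then summarises the relative bias of each method.
#'
#' @param config A [scenario_config()]. `sampling_grid` defaults to 0.3 for
#'   this comparison.
#' @param species Character vector of presets to compare.
#' @return A `kin_experiment` with `$records` (one row per population x
#'   resample x method) and `$summary` (one row per species x method).
#' @export
run_species_comparison <- function(config = scenario_config(),
                                   species = c("red_deer", "wild_boar")) {
  scen <- tibble(
    species = species,
    params = purrr::map(species, species_params)
  )
  recs <- run_scenarios(scen, config$sampling_grid, config$n_populations,
                        config$n_resamples, config$n_years, config$seed)
  new_kin_experiment(recs, config, "species_comparison")
}

#' Fecundity x sampling-intensity sweep
#'
#' Holds the base species' demography fixed (red deer by default), sets the
#' fecundity SD to `fecundity_sd_fixed` (default 0), and runs the full
#' factorial of `fecundity_grid` means by `sampling_grid` intensities.
#'
#' @param config A [scenario_config()].
#' @param fecundity_sd_fixed Fecundity SD used across the sweep.
#' @return A `kin_experiment`; records carry `fecundity_mean`, `fraction`.
#' @export
run_fecundity_sweep <- function(config = scenario_config(),
                                fecundity_sd_fixed = 0) {
  base <- config$base_species
  scen <- tibble(
    fecundity_mean = config$fecundity_grid,
    fecundity_sd = fecundity_sd_fixed,
    params = purrr::map(config$fecundity_grid, function(f) {
      species_params(base$name, fecundity_mean = f,
                     fecundity_sd = fecundity_sd_fixed)
    })
  )
  recs <- run_scenarios(scen, config$sampling_grid, config$n_populations,
                        config$n_resamples, config$n_years, config$seed)
  new_kin_experiment(recs, config, "fecundity_sweep")
}

#' Fecundity-variance sweep
#'
#' Fixes the fecundity mean (default 7) and varies its standard deviation
#' over `fecundity_sd_grid` (default 0, 2, 4) across all sampling
#' intensities, to test the estimators' sensitivity to reproductive skew.
#'
#' @param config A [scenario_config()].
#' @param fecundity_fixed Fecundity mean used across the sweep.
#' @return A `kin_experiment`; records carry `fecundity_sd`, `fraction`.
#' @export
run_sd_sweep <- function(config = scenario_config(), fecundity_fixed = 7) {
  base <- config$base_species
  scen <- tibble(
    fecundity_mean = fecundity_fixed,
    fecundity_sd = config$fecundity_sd_grid,
    params = purrr::map(config$fecundity_sd_grid, function(s) {
      species_params(base$name, fecundity_mean = fecundity_fixed,
                     fecundity_sd = s)
    })
  )
  recs <- run_scenarios(scen, config$sampling_grid, config$n_populations,
                        config$n_resamples, config$n_years, config$seed)
  new_kin_experiment(recs, config, "sd_sweep")
}

#' Summarise bias by observed POP count
#'
#' Groups per-resample records into bins of the observed number of
#' parent-offspring pairs in each sample (default bin width 10, starting at
#' 0) and summarises the relative bias within each bin, per method and (when
#' present) per fecundity. Empty bins are omitted.
#'
#' @param records Record tibble carrying `h_total` per resample.
#' @param bin_width POP-count bin width.
#' @return Tibble with `pop_bin` (bin lower edge), grouping columns,
#'   `mean_bias`, `sd_bias`, `n_defined`, `n_undefined`.
#' @export
bin_by_pops <- function(records, bin_width = 10) {
  stopifnot(bin_width >= 1)
  keys <- intersect(c("fecundity_mean", "fecundity_sd"), names(records))
  records %>%
    mutate(pop_bin = floor(.data$h_total / bin_width) * bin_width) %>%
    group_by(!!!syms(c(keys, "method", "pop_bin"))) %>%
    summarise(
      mean_bias = mean(.data$bias[.data$defined]),
      sd_bias = sd(.data$bias[.data$defined]),
      n_defined = sum(.data$defined),
      n_undefined = sum(!.data$defined),
      .groups = "drop"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment into its summary table
#'
#' @param x A `kin_experiment`.
#' @param ... Unused.
#' @return The per-cell summary tibble (see [summarize_bias()]).
#' @method tidy kin_experiment
#' @export
tidy.kin_experiment <- function(x, ...) x$summary

#' One-row overview of an experiment
#'
#' @param x A `kin_experiment`.
#' @param ... Unused.
#' @return One-row tibble: experiment kind, scale, and the overall fraction
#'   of defined estimates.
#' @method glance kin_experiment
#' @export
glance.kin_experiment <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_cells = nrow(x$summary),
    n_populations = x$config$n_populations,
    n_resamples = x$config$n_resamples,
    n_records = nrow(x$records),
    prop_defined = mean(x$records$defined)
  )
}
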