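# Scenario configuration: a validated list driving the experiment harness.
# Defaults are the reduced desk scale (30 populations x 30 resamples); the
# full published scale (100 x 100) is a configuration choice.

config_fields <- c("species", "params", "fecundity_grid", "fecundity_sd_grid",
                   "sampling_grid", "n_populations", "n_resamples", "n_years",
                   "seed")

#' Build an experiment configuration
#'
#' Collects everything that determines an experiment: the base species (a
#' preset name plus optional demographic overrides), the fecundity mean and
#' SD grids, the sampling-intensity grid, the replication scale and the root
#' seed. The returned object is a plain validated list; the whole experiment
#' table is a pure function of it.
#'
#' @param species Base species preset name (`"red_deer"` or `"wild_boar"`).
#' @param params Named list of [species_params()] overrides for the base
#'   species.
#' @param fecundity_grid Fecundity means swept by [run_fecundity_sweep()].
#' @param fecundity_sd_grid Fecundity SDs swept by [run_sd_sweep()].
#' @param sampling_grid Sampling intensities in (0, 1].
#' @param n_populations Replicate populations per scenario.
#' @param n_resamples Samples drawn per population and intensity.
#' @param n_years Simulated years per population.
#' @param seed Root seed.
#' @return A list of class `"scenario_config"`; `$base_species` holds the
#'   resolved [species_params()].
#' @examples
#' scenario_config(species = "wild_boar", sampling_grid = 0.3)
#' @export
scenario_config <- function(species = "red_deer",
                            params = list(),
                            fecundity_grid = 1:14,
                            fecundity_sd_grid = c(0, 2, 4),
                            sampling_grid = 0.3,
                            n_populations = 30L,
                            n_resamples = 30L,
                            n_years = 200L,
                            seed = 1L) {
  cfg <- list(species = species, params = params,
              fecundity_grid = fecundity_grid,
              fecundity_sd_grid = fecundity_sd_grid,
              sampling_grid = sampling_grid,
              n_populations = as.integer(n_populations),
              n_resamples = as.integer(n_resamples),
              n_years = as.integer(n_years),
              seed = as.integer(seed))
  problems <- character(0)
  if (!length(cfg$fecundity_grid) || any(cfg$fecundity_grid < 0)) {
    problems <- c(problems, "fecundity_grid: must be non-empty, all >= 0")
  }
  if (!length(cfg$fecundity_sd_grid) || any(cfg$fecundity_sd_grid < 0)) {
    problems <- c(problems, "fecundity_sd_grid: must be non-empty, all >= 0")
  }
  if (!length(cfg$sampling_grid) ||
      any(cfg$sampling_grid <= 0 | cfg$sampling_grid > 1)) {
    problems <- c(problems, "sampling_grid: fractions must lie in (0, 1]")
  }
  for (f in c("n_populations", "n_resamples", "n_years")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      problems <- c(problems, paste0(f, ": must be a count >= 1"))
    }
  }
  if (length(problems)) {
    stop("invalid scenario configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg$base_species <- do.call(species_params, c(list(species), cfg$params))
  structure(cfg, class = "scenario_config")
}

#' Load an experiment configuration from YAML or JSON
#'
#' Reads a config file, checks it against the schema (unknown keys are an
#' error naming the offending fields), and applies [scenario_config()]
#' defaults to everything omitted. A minimal file may contain just
#' `species: wild_boar`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_fields)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, raw)
}

#' Write a configuration to YAML
#'
#' @param config A `scenario_config`.
#' @param path Output file path.
#' @return `path`, invisibly. `load_config(save_config(cfg, p))` reproduces
#'   `cfg`.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)[config_fields]
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out$params)) out$params <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> base species:", x$species, "\n")
  cat("  fecundity grid:", paste(x$fecundity_grid, collapse = " "), "\n")
  cat("  fecundity SD grid:", paste(x$fecundity_sd_grid, collapse = " "), "\n")
  cat("  sampling grid:", paste(x$sampling_grid, collapse = " "), "\n")
  cat("  scale:", x$n_populations, "populations x", x$n_resamples,
      "resamples,", x$n_years, "years, seed", x$seed, "\n")
  invisible(x)
}
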