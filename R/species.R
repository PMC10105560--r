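#' Demographic parameter sets for simulated species
#'
#' `species_params()` returns the full demographic parameterisation of a
#' simulated species, either one of the built-in presets (`"red_deer"`,
#' `"wild_boar"`) or a preset with individual fields overridden. The fields
#' drive every stage of the annual cycle in [simulate_pedigree()].
#'
#' The two presets describe contrasting life histories drawn from the
#' European ungulate literature: the red deer is long-lived (15 y), strictly
#' monandrous with a single calf per hind per year, while the wild boar is
#' shorter-lived (12 y), highly fecund (litters of 4.9 +/- 2.1), and 44% of
#' mature sows mate with more than one boar (partner count Poisson with mean
#' 2, truncated below at 2 so that "multiple" means at least two).
#'
#' `adult_mortality_ref` is not a rate applied by the simulator: density
#' dependence is a ceiling on total abundance (see [step_year()]), and this
#' field records the long-run realized adult mortality the preset is expected
#' to produce, used for calibration checks.
#'
#' @param species `"red_deer"` or `"wild_boar"`.
#' @param ... Named overrides for individual fields, e.g. `fecundity_mean = 7`.
#' @return A list of class `"species_params"` with fields `name`,
#'   `max_lifespan`, `female_maturity`, `male_maturity`, `fecundity_mean`,
#'   `fecundity_sd`, `newborn_mortality`, `yearling_mortality`,
#'   `adult_mortality_ref`, `multi_mate_fraction`, `partner_lambda`,
#'   `carrying_capacity`, `sex_ratio`.
#' @examples
#' species_params("red_deer")
#' species_params("red_deer", fecundity_mean = 7, fecundity_sd = 2)
#' @export
species_params <- function(species = c("red_deer", "wild_boar"), ...) {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% c("red_deer", "wild_boar")) {
    stop("unknown species preset: ", paste(deparse(species), collapse = ""),
         " (available: \"red_deer\", \"wild_boar\")", call. = FALSE)
  }
  base <- switch(species,
    red_deer = list(
      name                = "red_deer",
      max_lifespan        = 15L,
      female_maturity     = 2L,
      male_maturity       = 5L,
      fecundity_mean      = 1,
      fecundity_sd        = 0,
      newborn_mortality   = 0.2,
      yearling_mortality  = 0.335,
      adult_mortality_ref = 0.315,
      multi_mate_fraction = 0,
      partner_lambda      = 0,
      carrying_capacity   = 500L,
      sex_ratio           = 0.5
    ),
    wild_boar = list(
      name                = "wild_boar",
      max_lifespan        = 12L,
      female_maturity     = 1L,
      male_maturity       = 3L,
      fecundity_mean      = 4.9,
      fecundity_sd        = 2.1,
      newborn_mortality   = 0.539,
      yearling_mortality  = 0.585,
      adult_mortality_ref = 0.360,
      multi_mate_fraction = 0.44,
      partner_lambda      = 2,
      carrying_capacity   = 500L,
      sex_ratio           = 0.5
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown species_params fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    base[names(overrides)] <- overrides
  }
  validate_species_params(base)
}

validate_species_params <- function(p) {
  stopifnot(is.list(p))
  need <- c("name", "max_lifespan", "female_maturity", "male_maturity",
            "fecundity_mean", "fecundity_sd", "newborn_mortality",
            "yearling_mortality", "adult_mortality_ref", "multi_mate_fraction",
            "partner_lambda", "carrying_capacity", "sex_ratio")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("species_params missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probs <- c("newborn_mortality", "yearling_mortality", "adult_mortality_ref",
             "multi_mate_fraction", "sex_ratio")
  for (f in probs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("species_params$", f, " must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (p$max_lifespan < 1) stop("max_lifespan must be >= 1", call. = FALSE)
  for (f in c("female_maturity", "male_maturity")) {
    if (p[[f]] < 1 || p[[f]] > p$max_lifespan) {
      stop("species_params$", f, " must lie in [1, max_lifespan]",
           call. = FALSE)
    }
  }
  if (p$fecundity_mean < 0) stop("fecundity_mean must be >= 0", call. = FALSE)
  if (p$fecundity_sd < 0) stop("fecundity_sd must be >= 0", call. = FALSE)
  if (p$partner_lambda < 0) stop("partner_lambda must be >= 0", call. = FALSE)
  if (p$carrying_capacity < 2) {
    stop("carrying_capacity must be >= 2", call. = FALSE)
  }
  int_fields <- c("max_lifespan", "female_maturity", "male_maturity",
                  "carrying_capacity")
  p[int_fields] <- lapply(p[int_fields], function(x) as.integer(round(x)))
  structure(p, class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> ", x$name, "\n", sep = "")
  flds <- setdiff(names(x), "name")
  for (f in flds) cat("  ", format(f, width = 20), x[[f]], "\n", sep = " ")
  invisible(x)
}
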