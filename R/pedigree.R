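#' @import rlang
#' @importFrom dplyr %>% bind_rows group_by left_join mutate select summarise
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rpois runif sd setNames
NULL

# ---- internal mutable simulation state --------------------------------------
#
# The annual cycle is run on a growable set of parallel vectors held in an
# environment; the tidy tibble representation is only materialised at the end
# (or on demand by step_year()). Indices double as individual ids.

new_sim_state <- function(cap = 4096L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$female <- logical(cap)
  e$birth  <- integer(cap)
  e$death  <- rep(NA_integer_, cap)
  e$mother <- rep(NA_integer_, cap)
  e$father <- rep(NA_integer_, cap)
  e$alive  <- integer(0)
  e
}

state_grow <- function(e, need) {
  cap <- length(e$female)
  if (need <= cap) return(invisible(e))
  while (cap < need) cap <- cap * 2L
  e$female <- c(e$female, logical(cap - length(e$female)))
  pad <- function(v) c(v, rep(NA_integer_, cap - length(v)))
  e$birth  <- c(e$birth, integer(cap - length(e$birth)))
  e$death  <- pad(e$death)
  e$mother <- pad(e$mother)
  e$father <- pad(e$father)
  invisible(e)
}

state_add <- function(e, female, birth, mother = NA_integer_,
                      father = NA_integer_) {
  k <- length(female)
  if (k == 0L) return(integer(0))
  state_grow(e, e$n + k)
  idx <- e$n + seq_len(k)
  e$female[idx] <- female
  e$birth[idx]  <- birth
  e$mother[idx] <- mother
  e$father[idx] <- father
  e$n <- e$n + k
  e$alive <- c(e$alive, idx)
  idx
}

state_kill <- function(e, idx, year) {
  if (!length(idx)) return(invisible(e))
  e$death[idx] <- year
  e$alive <- e$alive[!e$alive %in% idx]
  invisible(e)
}

# Litter size: Normal draw rounded to the nearest integer, truncated at zero.
draw_litter <- function(n, mean, sd) {
  pmax(0L, as.integer(round(rnorm(n, mean, sd))))
}

# One annual cycle, in fixed order: births, newborn mortality, yearling
# mortality, ceiling regulation, senescence. Ages are implicit
# (age = year - birth), so survivors "age" simply because the year advances.
sim_step <- function(e, p, year) {
  al <- e$alive
  if (!length(al)) return(invisible(e))
  n_start <- length(al) # standing population before this year's births
  age <- year - e$birth[al]
  fem <- e$female[al]
  mf <- al[fem & age >= p$female_maturity]
  mm <- al[!fem & age >= p$male_maturity]

  # (1) mating and births: every mature female breeds iff a mature male exists
  if (length(mf) && length(mm)) {
    nf <- length(mf)
    nm <- length(mm)
    litter <- draw_litter(nf, p$fecundity_mean, p$fecundity_sd)
    tot <- sum(litter)
    if (tot > 0L) {
      mothers <- rep.int(mf, litter)
      # default: one uniform-random partner per female, shared by her litter
      partner1 <- mm[sample.int(nm, nf, replace = TRUE)]
      sires <- rep.int(partner1, litter)
      if (p$multi_mate_fraction > 0) {
        multi <- runif(nf) < p$multi_mate_fraction
        ends <- cumsum(litter)
        starts <- ends - litter + 1L
        for (j in which(multi & litter > 0L)) {
          k <- min(max(rpois(1L, p$partner_lambda), 2L), nm)
          partners <- if (k == nm) mm else mm[sample.int(nm, k)]
          span <- starts[j]:ends[j]
          sires[span] <- partners[sample.int(k, length(span), replace = TRUE)]
        }
      }
      newborn_female <- runif(tot) < p$sex_ratio
      state_add(e, newborn_female, year, mothers, sires)
    }
  }

  # (2) newborn mortality (age 0 = born this year)
  babies <- e$alive[e$birth[e$alive] == year]
  if (length(babies)) {
    state_kill(e, babies[runif(length(babies)) < p$newborn_mortality], year)
  }

  # (3) yearling mortality (age 1)
  yl <- e$alive[e$birth[e$alive] == (year - 1L)]
  if (length(yl)) {
    state_kill(e, yl[runif(length(yl)) < p$yearling_mortality], year)
  }

  # (4a) density-dependent adult mortality: adults (age >= 2) die at rate
  # adult_mortality_ref scaled by (N/K)^3, N the standing population at the
  # start of the year; the steep exponent keeps the equilibrium near K while
  # the realized long-run adult mortality averages near the reference rate
  m_ad <- min(1, p$adult_mortality_ref *
                   (n_start / p$carrying_capacity)^3)
  if (m_ad > 0) {
    ad <- e$alive[(year - e$birth[e$alive]) >= 2L]
    if (length(ad)) state_kill(e, ad[runif(length(ad)) < m_ad], year)
  }

  # (4b) ceiling on recruitment: any excess still above carrying capacity is
  # removed from newborns first, then yearlings, then adults, so density
  # dependence beyond the adult rate falls on juvenile survival
  excess <- length(e$alive) - p$carrying_capacity
  if (excess > 0L) {
    age_al <- year - e$birth[e$alive]
    for (pool in list(e$alive[age_al == 0L],
                      e$alive[age_al == 1L],
                      e$alive[age_al >= 2L])) {
      if (excess <= 0L) break
      take <- min(excess, length(pool))
      if (take > 0L) {
        state_kill(e, pool[sample.int(length(pool), take)], year)
        excess <- excess - take
      }
    }
  }

  # (5) senescence
  old <- e$alive[(year - e$birth[e$alive]) >= p$max_lifespan]
  state_kill(e, old, year)

  invisible(e)
}

state_to_pedigree <- function(e, params, final_year, seed) {
  idx <- seq_len(e$n)
  new_kin_pedigree(
    tibble(
      id         = idx,
      sex        = ifelse(e$female[idx], "F", "M"),
      birth_year = e$birth[idx],
      death_year = e$death[idx],
      mother_id  = e$mother[idx],
      father_id  = e$father[idx]
    ),
    params = params, final_year = final_year, seed = seed
  )
}

pedigree_to_state <- function(ped) {
  n <- nrow(ped)
  e <- new_sim_state(max(4096L, n))
  e$n <- n
  idx <- seq_len(n)
  e$female[idx] <- ped$sex == "F"
  e$birth[idx]  <- ped$birth_year
  e$death[idx]  <- ped$death_year
  e$mother[idx] <- ped$mother_id
  e$father[idx] <- ped$father_id
  e$alive <- idx[is.na(ped$death_year)]
  e
}

# ---- pedigree class ---------------------------------------------------------

#' Construct a pedigree from a data frame
#'
#' Wraps an individual table (columns `id`, `sex`, `birth_year`,
#' `death_year`, `mother_id`, `father_id`; `NA` death year = alive at
#' `final_year`, `NA` parent ids = founder) as a `kin_pedigree`, so that
#' externally supplied pedigrees can be fed to [draw_sample()],
#' [estimate_all()] and friends.
#'
#' @param tbl Data frame of individuals.
#' @param params A [species_params()] object (supplies the maturity ages used
#'   to classify adults and juveniles).
#' @param final_year The sampled year; defaults to the latest birth or death
#'   year in the table.
#' @param seed Root seed to record (informational for hand-built pedigrees).
#' @return A `kin_pedigree`.
#' @examples
#' tbl <- tibble::tibble(
#'   id = 1:3, sex = c("F", "M", "F"), birth_year = c(0, 0, 5),
#'   death_year = NA_integer_, mother_id = c(NA, NA, 1L),
#'   father_id = c(NA, NA, 2L)
#' )
#' ped <- kin_pedigree(tbl, species_params("red_deer"), final_year = 7)
#' truth_sizes(ped)
#' @export
kin_pedigree <- function(tbl, params, final_year = NULL, seed = NA_integer_) {
  stopifnot(is.data.frame(tbl))
  need <- c("id", "sex", "birth_year", "death_year", "mother_id", "father_id")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop("pedigree table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(final_year)) {
    final_year <- max(c(tbl$birth_year, tbl$death_year), na.rm = TRUE)
  }
  new_kin_pedigree(as_tibble(tbl)[need], validate_species_params(params),
                   final_year = final_year, seed = seed)
}

new_kin_pedigree <- function(tbl, params, final_year, seed) {
  stopifnot(is.data.frame(tbl))
  out <- as_tibble(tbl)
  attr(out, "params") <- params
  attr(out, "final_year") <- as.integer(final_year)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("kin_pedigree", class(out))
  out
}

#' Accessors for pedigree metadata
#'
#' A `kin_pedigree` is a tibble of individuals (columns `id`, `sex`,
#' `birth_year`, `death_year`, `mother_id`, `father_id`; `NA` death year means
#' alive at the final year, `NA` parent ids mark founders) carrying the
#' simulation parameters, final year and root seed as attributes.
#'
#' @param pedigree A `kin_pedigree`.
#' @return `ped_params()` the [species_params()]; `ped_final_year()` the last
#'   simulated year; `ped_seed()` the root seed.
#' @export
ped_params <- function(pedigree) attr(pedigree, "params")

#' @rdname ped_params
#' @export
ped_final_year <- function(pedigree) attr(pedigree, "final_year")

#' @rdname ped_params
#' @export
ped_seed <- function(pedigree) attr(pedigree, "seed")

#' @export
print.kin_pedigree <- function(x, ...) {
  p <- ped_params(x)
  alive <- sum(is.na(x$death_year))
  cat("<kin_pedigree> ", if (!is.null(p)) p$name else "custom",
      ": ", nrow(x), " individuals ever recorded, ",
      alive, " alive at year ", ped_final_year(x), "\n", sep = "")
  NextMethod()
}

# ---- user-facing demography operations --------------------------------------

#' Initialise a founder population
#'
#' Creates the year-zero population: exactly `carrying_capacity` founders with
#' ages drawn uniformly on `{1, ..., max_lifespan}` (the age each founder has
#' in the first simulated year) and sexes drawn independently with probability
#' `sex_ratio` of being female. Founders carry no parent links, so they can
#' never be members of a parent-offspring pair.
#'
#' @param params A [species_params()] object.
#' @param seed Integer root seed; initialisation uses a child stream derived
#'   from it, so the same seed always yields the same founder table.
#' @return A [kin_pedigree][ped_params] with `final_year = 0`.
#' @examples
#' ped <- init_population(species_params("red_deer"), seed = 1)
#' nrow(ped)
#' @export
init_population <- function(params, seed) {
  params <- validate_species_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  k <- params$carrying_capacity
  with_seed(child_seed(seed, 1L, 0L), {
    ages <- sample.int(params$max_lifespan, k, replace = TRUE)
    female <- runif(k) < params$sex_ratio
    e <- new_sim_state(max(4096L, k))
    state_add(e, female, 1L - ages)
    state_to_pedigree(e, params, final_year = 0L, seed = seed)
  })
}

#' Advance a pedigree by one annual cycle
#'
#' Executes one year of the demographic model, in fixed order: (1) mating and
#' births -- each mature female produces a litter drawn from a Normal
#' (`fecundity_mean`, `fecundity_sd`) rounded and truncated at zero, sired by
#' one uniform-random mature male, except that a `multi_mate_fraction` share
#' of females draw a Poisson(`partner_lambda`) partner count (truncated below
#' at 2) and each of their offspring picks its sire uniformly from the partner
#' set; (2) newborn mortality; (3) yearling mortality; (4) ceiling regulation
#' removing any excess above `carrying_capacity`, adults first; (5) senescence
#' at `max_lifespan`. Survivors age implicitly as the year advances.
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @param seed Optional integer seed for this year's randomness; by default a
#'   child stream of the pedigree's root seed indexed by the new year, which
#'   makes repeated `step_year()` calls reproduce [simulate_pedigree()]
#'   exactly.
#' @return The pedigree advanced by one year (`final_year` incremented).
#' @examples
#' ped <- init_population(species_params("wild_boar"), seed = 1)
#' ped1 <- step_year(ped)
#' ped_final_year(ped1)
#' @export
step_year <- function(pedigree, seed = NULL) {
  params <- ped_params(pedigree)
  year <- ped_final_year(pedigree) + 1L
  if (is.null(seed)) seed <- child_seed(ped_seed(pedigree), 2L, year)
  e <- pedigree_to_state(pedigree)
  with_seed(seed, sim_step(e, params, year))
  state_to_pedigree(e, params, final_year = year, seed = ped_seed(pedigree))
}

#' Simulate a multi-generation pedigree
#'
#' Runs [init_population()] followed by `n_years` annual cycles and returns
#' the complete pedigree: every individual ever alive, with parent links and
#' birth/death years. With the built-in presets the default 200 years lets the
#' population equilibrate at carrying capacity under ceiling regulation, so
#' the final standing population contains many coexisting cohorts.
#'
#' @param params A [species_params()] object.
#' @param n_years Number of annual cycles (default 200).
#' @param seed Integer root seed. Identical `(params, n_years, seed)` produce
#'   bit-identical pedigrees.
#' @return A [kin_pedigree][ped_params] with `final_year = n_years`.
#' @examples
#' ped <- simulate_pedigree(species_params("red_deer"), n_years = 25, seed = 1)
#' truth_sizes(ped)
#' @export
simulate_pedigree <- function(params, n_years = 200L, seed) {
  params <- validate_species_params(params)
  stopifnot(n_years >= 1L)
  e <- pedigree_to_state(init_population(params, seed))
  for (year in seq_len(n_years)) {
    with_seed(child_seed(seed, 2L, year), sim_step(e, params, year))
  }
  state_to_pedigree(e, params, final_year = as.integer(n_years), seed = seed)
}

#' True population sizes at the final year
#'
#' Counts the individuals alive at the pedigree's final year: the total, the
#' adults (sex-specific maturity age reached), and the breeding females. These
#' are the denominators the estimators are judged against -- CKMR and CRE
#' target the adult count, g-CMR the total, and the Moment estimator the
#' breeding-female count.
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @return One-row tibble with `n_total`, `n_adult`, `n_breeding_females`.
#' @export
truth_sizes <- function(pedigree) {
  p <- ped_params(pedigree)
  year <- ped_final_year(pedigree)
  alive <- is.na(pedigree$death_year)
  age <- year - pedigree$birth_year[alive]
  sex <- pedigree$sex[alive]
  mature <- ifelse(sex == "F", age >= p$female_maturity, age >= p$male_maturity)
  tibble(
    n_total = sum(alive),
    n_adult = sum(mature),
    n_breeding_females = sum(mature & sex == "F")
  )
}

#' Audit the structural invariants of a pedigree
#'
#' Checks every recorded individual against the model's hard constraints:
#' mothers are female and fathers male; each parent had reached its
#' sex-specific maturity age by the offspring's birth year; no lifespan
#' exceeds `max_lifespan`; all parent ids resolve; and the standing
#' population never exceeds carrying capacity at the final year.
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @return A tibble of violations (zero rows when the pedigree is valid),
#'   with columns `check` and `id`.
#' @export
audit_pedigree <- function(pedigree) {
  p <- ped_params(pedigree)
  bad <- list()
  idx <- seq_len(nrow(pedigree))
  note <- function(check, ids) {
    if (length(ids)) tibble(check = check, id = as.integer(ids)) else NULL
  }
  by_id <- function(col) match(pedigree[[col]], pedigree$id)
  mi <- by_id("mother_id"); fi <- by_id("father_id")
  has_m <- !is.na(pedigree$mother_id); has_f <- !is.na(pedigree$father_id)
  bad$unres_m <- note("mother_unresolved", pedigree$id[has_m & is.na(mi)])
  bad$unres_f <- note("father_unresolved", pedigree$id[has_f & is.na(fi)])
  ok_m <- has_m & !is.na(mi); ok_f <- has_f & !is.na(fi)
  bad$sex_m <- note("mother_not_female",
                    pedigree$id[ok_m][pedigree$sex[mi[ok_m]] != "F"])
  bad$sex_f <- note("father_not_male",
                    pedigree$id[ok_f][pedigree$sex[fi[ok_f]] != "M"])
  m_age <- pedigree$birth_year[idx] - pedigree$birth_year[mi]
  f_age <- pedigree$birth_year[idx] - pedigree$birth_year[fi]
  bad$mat_m <- note("mother_immature",
                    pedigree$id[ok_m][m_age[ok_m] < p$female_maturity])
  bad$mat_f <- note("father_immature",
                    pedigree$id[ok_f][f_age[ok_f] < p$male_maturity])
  span <- pedigree$death_year - pedigree$birth_year
  bad$life <- note("lifespan_exceeded",
                   pedigree$id[!is.na(span) & span > p$max_lifespan])
  if (anyDuplicated(pedigree$id)) {
    bad$dup <- note("duplicate_id", pedigree$id[duplicated(pedigree$id)])
  }
  if (sum(is.na(pedigree$death_year)) > p$carrying_capacity) {
    bad$cap <- note("over_capacity", NA_integer_)
  }
  dplyr::bind_rows(bad)
}

#' Realized annual adult mortality
#'
#' For each simulated year, the fraction of adults (age >= 2 at the start of
#' the year) that died during that year, from any cause (ceiling regulation or
#' senescence). Under the presets this emergent rate should match the
#' literature reference rates stored in `adult_mortality_ref` (0.315 red deer,
#' 0.360 wild boar).
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @param years Years to evaluate; defaults to the last 100 (or all if fewer).
#' @return Tibble with `year`, `n_adult`, `deaths`, `mortality`.
#' @export
realized_adult_mortality <- function(pedigree, years = NULL) {
  fy <- ped_final_year(pedigree)
  if (is.null(years)) years <- seq.int(max(1L, fy - 99L), fy)
  birth <- pedigree$birth_year
  death <- pedigree$death_year
  purrr::map_dfr(years, function(y) {
    adult <- (y - birth) >= 2L & (is.na(death) | death >= y)
    n <- sum(adult)
    d <- sum(adult & !is.na(death) & death == y)
    tibble(year = y, n_adult = n, deaths = d,
           mortality = if (n > 0) d / n else NA_real_)
  })
}
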