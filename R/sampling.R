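# Sampling of the standing population and parent-offspring pair tallies.
# "The sample" throughout is a uniform draw without replacement from every
# individual alive at the pedigree's final year -- all coexisting cohorts,
# mimicking an unbiased hunting bag.

#' Draw a uniform random sample of the standing population
#'
#' Samples `round(fraction * n_alive)` individuals (never fewer than 2)
#' uniformly without replacement from those alive at the pedigree's final
#' year.
#'
#' @param pedigree A [kin_pedigree][ped_params].
#' @param fraction Sampling intensity in (0, 1]: the fraction of the standing
#'   population genotyped.
#' @param seed Integer seed; draws are seeded-deterministic.
#' @return A `kin_sample`: tibble with column `id`, carrying `fraction`,
#'   `year` and `seed` attributes.
#' @examples
#' ped <- simulate_pedigree(species_params("wild_boar"), n_years = 30, seed = 1)
#' s <- draw_sample(ped, 0.3, seed = 2)
#' nrow(s)
#' @export
draw_sample <- function(pedigree, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  alive_ids <- pedigree$id[is.na(pedigree$death_year)]
  if (length(alive_ids) < 2L) {
    stop("fewer than 2 individuals alive at the final year", call. = FALSE)
  }
  size <- max(2L, as.integer(round(fraction * length(alive_ids))))
  ids <- with_seed(seed, alive_ids[sample.int(length(alive_ids), size)])
  out <- tibble(id = sort(ids))
  attr(out, "fraction") <- fraction
  attr(out, "year") <- ped_final_year(pedigree)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("kin_sample", class(out))
  out
}

#' Find all parent-offspring pairs within a sample
#'
#' Under the assumption of perfect pedigree reconstruction, returns every
#' directed (parent, offspring) pair with both members in the sample. Each
#' pair is tagged by parent sex (`mother`/`father`) and by class:
#' `adult-adult` when the offspring has itself reached its sex-specific
#' maturity age at the sampled year, `adult-juvenile` otherwise. With
#' overlapping generations adult-adult pairs are common, and an individual
#' can appear both as parent and as offspring.
#'
#' @param sample A `kin_sample` from [draw_sample()].
#' @param pedigree The pedigree the sample was drawn from.
#' @return Tibble with columns `parent_id`, `offspring_id`, `parent_sex`,
#'   `class`.
#' @export
find_pops <- function(sample, pedigree) {
  year <- ped_final_year(pedigree)
  p <- ped_params(pedigree)
  sampled <- as_tibble(pedigree)[pedigree$id %in% sample$id, ]
  mature_off <- ifelse(
    sampled$sex == "F",
    (year - sampled$birth_year) >= p$female_maturity,
    (year - sampled$birth_year) >= p$male_maturity
  )
  pair_tbl <- function(parent_ids, sex_tag) {
    hit <- !is.na(parent_ids) & parent_ids %in% sample$id
    tibble(
      parent_id = as.integer(parent_ids[hit]),
      offspring_id = as.integer(sampled$id[hit]),
      parent_sex = rep(sex_tag, sum(hit)),
      class = c("adult-juvenile", "adult-adult")[mature_off[hit] + 1L]
    )
  }
  dplyr::bind_rows(
    tibble(parent_id = integer(0), offspring_id = integer(0),
           parent_sex = character(0), class = character(0)),
    pair_tbl(sampled$mother_id, "mother"),
    pair_tbl(sampled$father_id, "father")
  )
}

#' Tally the kin counts consumed by the estimators
#'
#' Aggregates a sample and its parent-offspring pairs into the sufficient
#' statistics of the four estimators: sample composition by maturity and sex,
#' total / mother-side / father-side POP counts, and the number of
#' mother-daughter pairs (both members female, daughter of any age).
#' Maturity is judged at the sampled year with sex-specific maturity ages.
#'
#' @param sample A `kin_sample`.
#' @param pops Pair table from [find_pops()].
#' @param pedigree The pedigree both were derived from.
#' @return One-row tibble: `n`, `n_juv`, `n_adult`, `n_adult_f`, `n_adult_m`,
#'   `n_f`, `h_total`, `h_mother`, `h_father`, `k_md`.
#' @export
kin_counts <- function(sample, pops, pedigree) {
  year <- ped_final_year(pedigree)
  p <- ped_params(pedigree)
  rows <- match(sample$id, pedigree$id)
  sex <- pedigree$sex[rows]
  age <- year - pedigree$birth_year[rows]
  mature <- ifelse(sex == "F", age >= p$female_maturity, age >= p$male_maturity)
  off_sex <- pedigree$sex[match(pops$offspring_id, pedigree$id)]
  tibble(
    n = nrow(sample),
    n_juv = sum(!mature),
    n_adult = sum(mature),
    n_adult_f = sum(mature & sex == "F"),
    n_adult_m = sum(mature & sex == "M"),
    n_f = sum(sex == "F"),
    h_total = nrow(pops),
    h_mother = sum(pops$parent_sex == "mother"),
    h_father = sum(pops$parent_sex == "father"),
    k_md = sum(pops$parent_sex == "mother" & off_sex == "F")
  )
}
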