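# Independent oracles and hand-built fixtures shared across test files.

# Brute-force parent-offspring-pair detection: double loop over all ordered
# pairs of sampled individuals, checking the parent links directly.
brute_force_pops <- function(sample_ids, pedigree) {
  rows <- as.data.frame(pedigree[pedigree$id %in% sample_ids, ])
  out <- character(0)
  for (i in seq_len(nrow(rows))) {
    for (j in seq_len(nrow(rows))) {
      if (i == j) next
      p <- rows$id[i]
      if (!is.na(rows$mother_id[j]) && rows$mother_id[j] == p) {
        out <- c(out, paste(p, rows$id[j], "mother"))
      }
      if (!is.na(rows$father_id[j]) && rows$father_id[j] == p) {
        out <- c(out, paste(p, rows$id[j], "father"))
      }
    }
  }
  sort(out)
}

pop_keys <- function(pops) {
  sort(paste(pops$parent_id, pops$offspring_id, pops$parent_sex))
}

# Toy pedigree from the sampling examples: A mother of C and D, B father of
# C; A and B mature, C and D juvenile females; E an unrelated mature male.
toy_pedigree <- function() {
  kin_pedigree(
    tibble::tibble(
      id = 1:5,
      sex = c("F", "M", "F", "F", "M"),
      birth_year = c(3L, 2L, 9L, 9L, 1L),
      death_year = NA_integer_,
      mother_id = c(NA, NA, 1L, 1L, NA),
      father_id = c(NA, NA, 2L, NA, NA)
    ),
    species_params("red_deer"), final_year = 10, seed = 1
  )
}

toy_sample <- function(pedigree, ids, fraction = 0.5) {
  out <- tibble::tibble(id = sort(as.integer(ids)))
  attr(out, "fraction") <- fraction
  attr(out, "year") <- ped_final_year(pedigree)
  attr(out, "seed") <- 0L
  class(out) <- c("kin_sample", class(out))
  out
}

# Idealized generative populations in which each estimator's assumptions
# hold, used as unbiasedness oracles. Parameters with maturity 2 for both
# sexes; adults born 5 years before the final year, juveniles in the final
# year.
ideal_params <- function() {
  species_params("red_deer", male_maturity = 2, carrying_capacity = 10000)
}

# Two-generation population for CKMR/CRE: founder adults without parents,
# juveniles with both parents among the adults (all POPs adult-juvenile).
gen_two_generation <- function(n_f = 50, n_m = 50, n_juv = 200,
                               balanced = FALSE) {
  n_ad <- n_f + n_m
  mothers <- if (balanced) {
    sample(rep(seq_len(n_f), length.out = n_juv))
  } else {
    sample.int(n_f, n_juv, replace = TRUE)
  }
  fathers <- if (balanced) {
    sample(rep(n_f + seq_len(n_m), length.out = n_juv))
  } else {
    n_f + sample.int(n_m, n_juv, replace = TRUE)
  }
  kin_pedigree(
    tibble::tibble(
      id = seq_len(n_ad + n_juv),
      sex = c(rep("F", n_f), rep("M", n_m),
              sample(c("F", "M"), n_juv, replace = TRUE)),
      birth_year = c(rep(5L, n_ad), rep(10L, n_juv)),
      death_year = NA_integer_,
      mother_id = c(rep(NA_integer_, n_ad), mothers),
      father_id = c(rep(NA_integer_, n_ad), fathers)
    ),
    ideal_params(), final_year = 10, seed = 1
  )
}

# Closed-parentage population for g-CMR: every individual, adult or juvenile,
# has its mother among the adult females and its father among the adult
# males, so every sampled individual carries a detectable parentage mark.
gen_closed_parentage <- function(n_f = 100, n_m = 100, n_juv = 300) {
  n <- n_f + n_m + n_juv
  kin_pedigree(
    tibble::tibble(
      id = seq_len(n),
      sex = c(rep("F", n_f), rep("M", n_m),
              sample(c("F", "M"), n_juv, replace = TRUE)),
      birth_year = c(rep(5L, n_f + n_m), rep(10L, n_juv)),
      death_year = NA_integer_,
      mother_id = sample.int(n_f, n, replace = TRUE),
      father_id = n_f + sample.int(n_m, n, replace = TRUE)
    ),
    ideal_params(), final_year = 10, seed = 1
  )
}

# All-female closed population for the Moment estimator: every female's
# mother is a uniform draw among the other females, so any ordered pair of
# sampled females is a mother-daughter pair with probability 1/(N_F - 1).
gen_closed_females <- function(n_f = 200) {
  mothers <- vapply(seq_len(n_f), function(i) {
    sample(setdiff(seq_len(n_f), i), 1L)
  }, integer(1))
  kin_pedigree(
    tibble::tibble(
      id = seq_len(n_f),
      sex = "F",
      birth_year = 5L,
      death_year = NA_integer_,
      mother_id = mothers,
      father_id = NA_integer_
    ),
    ideal_params(), final_year = 10, seed = 1
  )
}

# Uniform sample of an idealized pedigree (all individuals alive).
ideal_sample <- function(pedigree, q) {
  n <- nrow(pedigree)
  toy_sample(pedigree, pedigree$id[sample.int(n, round(q * n))], fraction = q)
}
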