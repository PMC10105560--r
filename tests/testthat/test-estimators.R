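counts_of <- function(...) {
  defaults <- tibble::tibble(
    n = 0L, n_juv = 0L, n_adult = 0L, n_adult_f = 0L, n_adult_m = 0L,
    n_f = 0L, h_total = 0L, h_mother = 0L, h_father = 0L, k_md = 0L
  )
  args <- list(...)
  defaults[names(args)] <- args
  defaults
}

test_that("CKMR evaluates the Lincoln-Petersen form and flags degeneracy", {
  est <- estimate_ckmr(counts_of(n_juv = 20, n_adult = 30, h_total = 40))
  expect_true(est$defined)
  expect_equal(est$n_hat, 30)
  expect_equal(est$target, "adult")

  expect_false(estimate_ckmr(counts_of(n_juv = 5, n_adult = 5))$defined)
  expect_false(estimate_ckmr(counts_of(n_adult = 5, h_total = 3))$defined)
})

test_that("g-CMR combines per-sex estimates and inflates by adult fraction", {
  est <- estimate_gcmr(counts_of(n = 100, n_adult = 50, n_adult_f = 30,
                                 h_mother = 10, n_adult_m = 20, h_father = 5))
  expect_true(est$defined)
  expect_equal(est$n_hat_f, 300)
  expect_equal(est$n_hat_m, 400)
  expect_equal(est$n_hat, 1400)
  expect_equal(est$target, "total")

  expect_false(estimate_gcmr(counts_of(n = 100, n_adult = 50, n_adult_f = 30,
                                       h_mother = 10))$defined)
})

test_that("Moment estimator matches the mother-daughter pair frequency form", {
  est <- estimate_moment(counts_of(n_f = 11, k_md = 10))
  expect_true(est$defined)
  expect_equal(est$n_hat, 11)
  expect_equal(est$target, "breeding_females")

  expect_false(estimate_moment(counts_of(n_f = 11))$defined)
  expect_false(estimate_moment(counts_of(n_f = 1, k_md = 1))$defined)
})

test_that("CRE counts sampled breeders plus inferred unsampled mates", {
  # A (mother) x B (father) -> C; D unrelated
  ped <- kin_pedigree(
    tibble::tibble(
      id = 1:4, sex = c("F", "M", "F", "M"),
      birth_year = c(2L, 2L, 9L, 9L), death_year = NA_integer_,
      mother_id = c(NA, NA, 1L, NA), father_id = c(NA, NA, 2L, NA)
    ),
    species_params("red_deer", male_maturity = 2), final_year = 10, seed = 1
  )
  est <- estimate_cre(toy_sample(ped, c(1, 3, 4)), ped)
  expect_true(est$defined)
  expect_equal(est$n_hat, 2) # B_s = {A}, B_u = {B}
  expect_equal(est$target, "adult")

  expect_false(estimate_cre(toy_sample(ped, c(1, 2, 4)), ped)$defined)
})

test_that("census estimates are exact in assumption-satisfying populations", {
  withr::with_seed(11, {
    two_gen <- gen_two_generation(n_f = 50, n_m = 50, n_juv = 200)
    census <- toy_sample(two_gen, two_gen$id, fraction = 1)
    pops <- find_pops(census, two_gen)
    k <- kin_counts(census, pops, two_gen)
    expect_equal(estimate_ckmr(k)$n_hat, 100) # 2*200*100/400

    closed <- gen_closed_parentage(n_f = 100, n_m = 100, n_juv = 300)
    cs <- toy_sample(closed, closed$id, fraction = 1)
    kc <- kin_counts(cs, find_pops(cs, closed), closed)
    expect_equal(estimate_gcmr(kc)$n_hat, 500)

    fem <- gen_closed_females(n_f = 200)
    fs <- toy_sample(fem, fem$id, fraction = 1)
    kf <- kin_counts(fs, find_pops(fs, fem), fem)
    expect_equal(estimate_moment(kf)$n_hat, 199) # n_f - 1 at census

    # CRE census limit: exactly the number of distinct true parents
    cre <- estimate_cre(census, two_gen)
    expect_equal(cre$n_hat,
                 dplyr::n_distinct(c(two_gen$mother_id, two_gen$father_id),
                                   na.rm = TRUE))
  })
})

test_that("count-based estimators are scale-equivariant and monotone in POPs", {
  base <- counts_of(n = 120L, n_juv = 70L, n_adult = 50L, n_adult_f = 30L,
                    n_adult_m = 20L, n_f = 60L, h_total = 24L,
                    h_mother = 14L, h_father = 10L, k_md = 6L)
  # scaling the population by c at a fixed sampling fraction scales every
  # count, POPs included, by c and each estimate by c
  for (c_mult in c(2, 5)) {
    scaled <- base
    scaled[] <- lapply(base, function(x) x * c_mult)
    expect_equal(estimate_ckmr(scaled)$n_hat,
                 c_mult * estimate_ckmr(base)$n_hat)
    expect_equal(estimate_gcmr(scaled)$n_hat,
                 c_mult * estimate_gcmr(base)$n_hat)
    # Moment is exactly homogeneous up to its -1 finite-sample term
    expect_equal(estimate_moment(scaled)$n_hat,
                 (c_mult * base$n_f) * (c_mult * base$n_f - 1) /
                   (c_mult * base$k_md))
  }
  # scaling the sampling fraction by c scales linear counts by c and POP
  # counts by c^2, leaving each estimate unchanged (consistency across
  # sampling intensities)
  scaled <- base
  lin <- c("n", "n_juv", "n_adult", "n_adult_f", "n_adult_m", "n_f")
  quad <- c("h_total", "h_mother", "h_father", "k_md")
  scaled[lin] <- lapply(base[lin], function(x) x * 3)
  scaled[quad] <- lapply(base[quad], function(x) x * 9)
  expect_equal(estimate_ckmr(scaled)$n_hat, estimate_ckmr(base)$n_hat)
  expect_equal(estimate_gcmr(scaled)$n_hat, estimate_gcmr(base)$n_hat)
  for (h in c(25L, 30L, 40L)) {
    expect_lt(estimate_ckmr(counts_of(n_juv = 70, n_adult = 50, h_total = h))$n_hat,
              estimate_ckmr(counts_of(n_juv = 70, n_adult = 50, h_total = h - 1L))$n_hat)
  }
  expect_lt(estimate_moment(counts_of(n_f = 60, k_md = 7))$n_hat,
            estimate_moment(counts_of(n_f = 60, k_md = 6))$n_hat)
})

test_that("estimate_all fans out to all four methods consistently", {
  ped <- short_sim("wild_boar")
  s <- draw_sample(ped, 0.3, seed = 77)
  all4 <- estimate_all(s, ped)
  expect_equal(nrow(all4), 4L)
  expect_setequal(all4$method, c("CKMR", "gCMR", "Moment", "CRE"))

  pops <- find_pops(s, ped)
  k <- kin_counts(s, pops, ped)
  expect_equal(all4$n_hat[all4$method == "CKMR"], estimate_ckmr(k)$n_hat)
  expect_equal(all4$n_hat[all4$method == "gCMR"], estimate_gcmr(k)$n_hat)
  expect_equal(all4$n_hat[all4$method == "Moment"], estimate_moment(k)$n_hat)
  expect_equal(all4$n_hat[all4$method == "CRE"],
               estimate_cre(s, ped)$n_hat)

  # degenerate two-individual unrelated sample: all POP counts zero
  ped2 <- toy_pedigree()
  deg <- estimate_all(toy_sample(ped2, c(2, 5)), ped2)
  expect_equal(nrow(deg), 4L)
  expect_false(any(deg$defined))
})

test_that("CRE never exceeds its structural upper bound", {
  ped <- short_sim("red_deer")
  for (i in 1:10) {
    s <- draw_sample(ped, 0.4, seed = 600 + i)
    est <- estimate_cre(s, ped)
    rows <- ped[ped$id %in% s$id, ]
    parents_of_sampled <- dplyr::n_distinct(
      c(rows$mother_id, rows$father_id), na.rm = TRUE)
    if (est$defined) expect_lte(est$n_hat, parents_of_sampled)
  }
})
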