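test_that("relative bias divides each method by its own target truth", {
  truth <- tibble::tibble(n_total = 500, n_adult = 100,
                          n_breeding_females = 60)
  est <- tibble::tibble(
    method = c("CKMR", "CRE", "gCMR", "Moment"),
    target = c("adult", "adult", "total", "breeding_females"),
    n_hat = c(90, 100, 250, 90),
    defined = TRUE
  )
  out <- relative_bias(est, truth)
  expect_equal(out$bias, c(0.9, 1.0, 0.5, 1.5))
  expect_equal(out$n_true, c(100, 100, 500, 60))

  est$defined[2] <- FALSE
  expect_true(is.na(relative_bias(est, truth)$bias[2]))
})

test_that("resampling yields 4 records per draw, reproducibly", {
  ped <- short_sim("wild_boar")
  recs <- resample_population(ped, 0.3, n_resamples = 25, seed = 5)
  expect_equal(nrow(recs), 100L)
  expect_equal(as.integer(table(recs$method)), rep(25L, 4))
  expect_identical(recs, resample_population(ped, 0.3, 25, seed = 5))
  # undefined estimates carried as missing bias, never dropped rows
  expect_equal(sum(is.na(recs$bias)), sum(!recs$defined))
})

test_that("summary statistics match an independent from-scratch recomputation", {
  ped1 <- short_sim("wild_boar")
  ped2 <- short_sim("red_deer")
  recs <- dplyr::bind_rows(
    dplyr::mutate(resample_population(ped1, 0.4, 20, seed = 1),
                  population = 1L),
    dplyr::mutate(resample_population(ped2, 0.4, 20, seed = 2),
                  population = 2L)
  )
  s <- summarize_bias(recs)
  for (m in unique(s$method)) {
    sub <- recs[recs$method == m & recs$defined, ]
    row <- s[s$method == m, ]
    expect_equal(row$mean_bias, mean(sub$bias))
    expect_equal(row$sd_bias, sd(sub$bias))
    # per-population CV, averaged across populations
    cvs <- vapply(split(sub$bias, sub$population),
                  function(b) sd(b) / mean(b) * 100, numeric(1))
    expect_equal(row$cv_pct, mean(cvs))
    expect_equal(row$sd_cv_pct, sd(cvs))
    expect_equal(row$n_defined + row$n_undefined,
                 sum(recs$method == m))
  }
  pooled <- summarize_bias(recs, pooled_cv = TRUE)
  sub <- recs[recs$method == "CKMR" & recs$defined, ]
  expect_equal(pooled$cv_pct[pooled$method == "CKMR"],
               sd(sub$bias) / mean(sub$bias) * 100)
})

test_that("experiment grids have the expected cardinality and determinism", {
  cfg <- scenario_config(fecundity_grid = c(2, 5), sampling_grid = c(0.3, 0.6),
                         n_populations = 2, n_resamples = 3, n_years = 40,
                         seed = 14)
  ex <- run_fecundity_sweep(cfg)
  expect_s3_class(ex, "kin_experiment")
  expect_equal(nrow(ex$records), 2 * 2 * 2 * 3 * 4)
  expect_equal(nrow(ex$summary), 2 * 2 * 4) # fecundity x fraction x method
  expect_setequal(unique(ex$records$fecundity_mean), c(2, 5))
  ex2 <- run_fecundity_sweep(cfg)
  expect_identical(ex$records, ex2$records)

  sp <- run_species_comparison(scenario_config(
    sampling_grid = 0.3, n_populations = 2, n_resamples = 3, n_years = 40,
    seed = 15
  ))
  expect_equal(nrow(sp$summary), 2 * 4) # species x method
  expect_setequal(unique(sp$summary$species), c("red_deer", "wild_boar"))

  sd_ex <- run_sd_sweep(scenario_config(
    fecundity_sd_grid = c(0, 2), sampling_grid = 0.5,
    n_populations = 2, n_resamples = 2, n_years = 40, seed = 16
  ))
  expect_equal(nrow(sd_ex$summary), 2 * 4)
  expect_setequal(unique(sd_ex$records$fecundity_mean), 7)
})

test_that("missing-data accounting reconciles per cell", {
  ex <- run_fecundity_sweep(scenario_config(
    fecundity_grid = 1, sampling_grid = c(0.1, 0.5),
    n_populations = 3, n_resamples = 10, n_years = 60, seed = 21
  ))
  s <- ex$summary
  expect_true(all(s$n_defined + s$n_undefined == 3 * 10))
  expect_true(all(s$cv_pct >= 0 | is.na(s$cv_pct)))
})

test_that("POP-count binning matches a group-by oracle and omits empty bins", {
  recs <- tibble::tibble(
    method = "CKMR",
    h_total = c(5, 15, 25, 7, 15),
    bias = c(1, 2, 3, 2, 4),
    defined = TRUE
  )
  b <- bin_by_pops(recs, bin_width = 10)
  expect_equal(nrow(b), 3L)
  expect_setequal(b$pop_bin, c(0, 10, 20))
  expect_equal(b$mean_bias[b$pop_bin == 0], 1.5)
  expect_equal(b$mean_bias[b$pop_bin == 10], 3)

  ped <- short_sim("wild_boar")
  recs2 <- dplyr::mutate(resample_population(ped, 0.3, 20, seed = 3),
                         population = 1L)
  b2 <- bin_by_pops(recs2, bin_width = 10)
  oracle <- tapply(recs2$bias[recs2$defined],
                   list(floor(recs2$h_total[recs2$defined] / 10) * 10,
                        recs2$method[recs2$defined]), mean)
  for (i in seq_len(nrow(b2))) {
    expect_equal(b2$mean_bias[i],
                 unname(oracle[as.character(b2$pop_bin[i]), b2$method[i]]))
  }
})

test_that("tidy, glance and autoplot expose the experiment object", {
  ex <- run_species_comparison(scenario_config(
    sampling_grid = 0.3, n_populations = 2, n_resamples = 3, n_years = 40,
    seed = 15
  ))
  expect_identical(generics::tidy(ex), ex$summary)
  g <- generics::glance(ex)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_records, nrow(ex$records))
  expect_true(g$prop_defined >= 0 && g$prop_defined <= 1)
  expect_s3_class(ggplot2::autoplot(ex), "ggplot")
  expect_s3_class(plot_cv(ex$summary), "ggplot")
})
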