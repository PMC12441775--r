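test_that("generators are fully determined by the seed", {
  cfg <- trial_config()
  expect_identical(generate_structural(cfg, seed = 5),
                   generate_structural(cfg, seed = 5))
  expect_false(identical(generate_structural(cfg, seed = 5),
                         generate_structural(cfg, seed = 6)))
  t1 <- generate_mechanistic(cfg, seed = 5)
  t2 <- generate_mechanistic(cfg, seed = 5)
  expect_identical(t1$autumn_survey, t2$autumn_survey)
  expect_identical(t1$applications, t2$applications)
  expect_identical(t1$summer_biomass, t2$summer_biomass)
})

test_that("noise-free structural draws satisfy the path equations exactly", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 9, residual_scale = 0)
  for (g in cfg$groups) {
    d <- obs[obs$group == g, ]
    expect_equal(d$tfi,
                 cfg$alpha1[[g]] + cfg$coef$a[[g]] * d$d_aut +
                   cfg$coef$b[[g]] * d$logn_aut, tolerance = 1e-12)
    expect_equal(d$d_sum,
                 cfg$alpha2[[g]] + cfg$coef$c[[g]] * d$tfi +
                   cfg$coef$d[[g]] * d$d_aut +
                   cfg$coef$e[[g]] * d$logn_aut, tolerance = 1e-12)
  }
})

test_that("the exogenous correlation tracks the configured f", {
  cfg0 <- trial_config(
    n_fields = 5000L, groups = "DSSstd",
    tfi_mean = c(DSSstd = 1.37), dsum_mean = c(DSSstd = 9),
    std_coef = modifyList(weedpath:::.default_std_coef,
                          list(f = c(DSSstd = 0))))
  obs0 <- generate_structural(cfg0, seed = 1)
  expect_lt(abs(cor(obs0$d_aut, obs0$logn_aut)), 0.1)
  cfg54 <- trial_config(n_fields = 5000L, groups = "DSSstd",
                        tfi_mean = c(DSSstd = 1.37),
                        dsum_mean = c(DSSstd = 9))
  obs54 <- generate_structural(cfg54, seed = 1)
  expect_equal(cor(obs54$d_aut, obs54$logn_aut), 0.54, tolerance = 0.05)
})

test_that("non-positive-definite exogenous settings are rejected", {
  cfg <- trial_config()
  cfg$coef$f[] <- 10   # exceeds sd_d * sd_logn
  expect_error(generate_structural(cfg, seed = 1), "positive definite")
})

test_that("dose plans invert the dose-response curve at the target", {
  curves <- tibble::tibble(species = "VIOAR", product = "ProWheat500",
                           max_efficacy = 0.96, ed50 = 0.3, slope = 2.5)
  pf <- default_portfolio()
  plan <- dss_decide(c(VIOAR = 50), curves, c(VIOAR = 0.8), pf)
  x <- plan$plan$dose_fraction
  expect_equal(dose_response_efficacy(x, 0.3, 2.5, 0.96), 0.8,
               tolerance = 1e-10)
  expect_equal(plan$tfi, x)
  # analytic inversion oracle
  expect_equal(x, 0.3 * (0.8 / 0.16)^(1 / 2.5), tolerance = 1e-12)
  # empty field: no plan
  none <- dss_decide(c(VIOAR = 0), curves, c(VIOAR = 0.8), pf)
  expect_equal(none$tfi, 0)
  expect_equal(nrow(none$plan), 0L)
  # unreachable target names the species
  expect_error(dss_decide(c(VIOAR = 50), curves, c(VIOAR = 0.99), pf),
               "VIOAR")
})

test_that("efficacy is zero at dose zero and strictly increasing", {
  expect_equal(dose_response_efficacy(0, 0.3, 2.5, 0.9), 0)
  x <- seq(0.05, 1.5, by = 0.05)
  eff <- dose_response_efficacy(x, 0.3, 2.5, 0.9)
  expect_true(all(diff(eff) > 0))
  expect_true(all(eff < 0.9))
})

test_that("reduced target efficacies lower every target by 3 to 15 points and never raise the TFI", {
  pool <- default_species_pool()
  curves <- default_curves()
  dens <- setNames(rep(25, nrow(pool)), pool$species)
  t_std <- target_efficacies(dens, pool)
  t_red <- target_efficacies(dens, pool, reduced = TRUE)
  drop <- t_std - t_red
  expect_true(all(drop >= 0.03 - 1e-12 & drop <= 0.15 + 1e-12))
  cfg <- trial_config()
  for (s in 1:20) {
    tr <- generate_mechanistic(cfg, seed = s)
    tt <- tfi_table(tr$applications)
    w <- tidyr::pivot_wider(tt, names_from = "treatment",
                            values_from = "tfi")
    expect_true(all(w$DSSred <= w$DSSstd + 1e-12),
                label = paste("seed", s))
  }
})

test_that("mechanistic fields match the surveyed density and richness ranges", {
  cfg <- trial_config()
  in_range <- vapply(1:10, function(s) {
    tr <- generate_mechanistic(cfg, seed = 200 + s)
    per_field <- tapply(tr$field_density$density,
                        tr$field_density$field, sum)
    rich <- tapply(tr$field_density$density > 0,
                   tr$field_density$field, sum)
    mean(per_field >= 17 & per_field <= 662 &
           rich >= 6 & rich <= 14)
  }, numeric(1))
  expect_gte(mean(in_range), 0.9)
})

test_that("every treated group suppresses biomass relative to the untreated control", {
  cfg <- trial_config()
  means <- sapply(1:15, function(s) {
    tr <- generate_mechanistic(cfg, seed = 300 + s)
    bio <- dplyr::summarise(
      dplyr::group_by(tr$summer_biomass, .data$treatment),
      biomass = sum(.data$biomass), .groups = "drop")
    setNames(bio$biomass, bio$treatment)
  })
  untr <- means["Untreated", ]
  for (g in cfg$groups) {
    expect_lt(mean(means[g, ]), mean(untr))
  }
})

test_that("full-susceptibility plans eliminate the treated species", {
  curves <- tibble::tibble(
    species = c("AAA", "BBB"), product = "HerbUltra",
    max_efficacy = 1, ed50 = 1e-9, slope = 2, cost = 1)
  eff <- dose_response_efficacy(1, 1e-9, 2, 1)
  expect_equal(eff, 1, tolerance = 1e-12)
})
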