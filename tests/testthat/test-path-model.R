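test_that("near-noise-free structural data identify the generating coefficients", {
  # the TFI equation keeps a sliver of noise: with an exactly
  # deterministic TFI the summer equation's design is collinear
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 3,
                             residual_scale = c(1e-6, 0))
  fit <- fit_multigroup(obs)
  cf <- fit$coefficients
  for (g in cfg$groups) {
    for (pth in c("a", "b")) {
      expect_lt(abs(cf$estimate[cf$group == g & cf$path == pth] -
                      cfg$coef[[pth]][[g]]), 1e-6)
    }
    for (pth in c("c", "d", "e")) {
      expect_lt(abs(cf$estimate[cf$group == g & cf$path == pth] -
                      cfg$coef[[pth]][[g]]), 1e-7)
    }
  }
  r2 <- fit$r_squared
  expect_equal(r2$r_squared, rep(1, 8), tolerance = 1e-6)
})

test_that("the unconstrained ML fit equals per-group least squares", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 11)
  fit <- fit_multigroup(obs)
  for (g in cfg$groups) {
    d <- obs[obs$group == g, ]
    o1 <- coef(lm(tfi ~ d_aut + logn_aut, data = d))
    o2 <- coef(lm(d_sum ~ tfi + d_aut + logn_aut, data = d))
    cf <- fit$coefficients[fit$coefficients$group == g, ]
    expect_equal(cf$estimate[cf$path == "a"], unname(o1["d_aut"]),
                 tolerance = 1e-8)
    expect_equal(cf$estimate[cf$path == "b"], unname(o1["logn_aut"]),
                 tolerance = 1e-8)
    expect_equal(cf$estimate[cf$path == "c"], unname(o2["tfi"]),
                 tolerance = 1e-8)
    expect_equal(cf$estimate[cf$path == "d"], unname(o2["d_aut"]),
                 tolerance = 1e-8)
    expect_equal(cf$estimate[cf$path == "e"], unname(o2["logn_aut"]),
                 tolerance = 1e-8)
    # unconstrained f is reported as the unbiased sample covariance
    expect_equal(cf$estimate[cf$path == "f"],
                 cov(d$d_aut, d$logn_aut), tolerance = 1e-10)
  }
})

test_that("likelihood-ratio bookkeeping: identity, df counting, nesting", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 2)
  fit <- fit_multigroup(obs)
  self <- path_lrt(fit, fit)
  expect_equal(self$chi2, 0)
  expect_equal(self$df, 0L)
  expect_equal(self$p, 1)
  for (fam in c("a", "b", "c", "d", "e", "f")) {
    red <- fit_multigroup(obs, constrained = fam)
    lr <- path_lrt(fit, red)
    expect_equal(lr$df, 3L)             # 4 groups -> G - 1
    expect_gte(lr$chi2, 0)
    # adding a constraint never increases the log-likelihood
    expect_lte(red$loglik, fit$loglik + 1e-6)
  }
  red2 <- fit_multigroup(obs, constrained = c("a", "b"))
  reda <- fit_multigroup(obs, constrained = "a")
  expect_equal(path_lrt(reda, red2)$df, 3L)
  expect_error(path_lrt(red2, reda), "nested")
})

test_that("LRT p-values are approximately uniform when the constraint holds", {
  # per-group n of 60 keeps the chi-square reference accurate; at the
  # trial's n = 15 the ML likelihood-ratio test is visibly
  # anti-conservative, as expected for normal-theory ML without
  # small-sample correction (see the methods vignette)
  cfg <- shared_config()          # all families truly shared
  cfg$n_fields <- 60L
  ps <- vapply(1:150, function(s) {
    obs <- generate_structural(cfg, seed = 4000 + s)
    full <- fit_multigroup(obs)
    red <- fit_multigroup(obs, constrained = "e")
    path_lrt(full, red)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("standardized coefficients follow the sd ratio and f the Pearson correlation", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 13)
  fit <- fit_multigroup(obs)
  for (g in cfg$groups) {
    d <- obs[obs$group == g, ]
    cf <- fit$coefficients[fit$coefficients$group == g, ]
    expect_equal(cf$standardized[cf$path == "f"],
                 cor(d$d_aut, d$logn_aut), tolerance = 1e-10)
    expect_equal(cf$standardized[cf$path == "b"],
                 cf$estimate[cf$path == "b"] * sd(d$logn_aut) / sd(d$tfi),
                 tolerance = 1e-10)
    expect_equal(cf$standardized[cf$path == "c"],
                 cf$estimate[cf$path == "c"] * sd(d$tfi) / sd(d$d_sum),
                 tolerance = 1e-10)
  }
  # pre-standardizing the data reproduces the standardized coefficients
  zobs <- obs
  for (g in cfg$groups) {
    idx <- zobs$group == g
    for (v in c("d_aut", "logn_aut", "tfi", "d_sum")) {
      zobs[[v]][idx] <- as.numeric(scale(zobs[[v]][idx]))
    }
  }
  zfit <- fit_multigroup(zobs)
  expect_equal(zfit$coefficients$estimate[zfit$coefficients$path != "f"],
               fit$coefficients$standardized[fit$coefficients$path != "f"],
               tolerance = 1e-6)
})

test_that("mediation effects combine direct and product paths", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 17)
  fit <- fit_multigroup(obs)
  cf <- fit$coefficients
  for (g in cfg$groups) {
    eff <- path_effects(fit, g)
    b <- cf$estimate[cf$group == g & cf$path == "b"]
    cc <- cf$estimate[cf$group == g & cf$path == "c"]
    e <- cf$estimate[cf$group == g & cf$path == "e"]
    expect_equal(eff$direct, e)
    expect_equal(eff$indirect, b * cc, tolerance = 1e-12)
    expect_equal(eff$total, e + b * cc, tolerance = 1e-12)
  }
  expect_equal(total_effect(1.5, 0), 1.5)
  expect_error(path_effects(fit, "nope"), "unknown group")
})

test_that("stepwise selection keeps truly shared families and frees heterogeneous ones", {
  # all families shared: everything should be constrained
  cfg_all <- shared_config()
  obs <- generate_structural(cfg_all, seed = 31)
  sw <- stepwise_constrain(obs)
  expect_gte(length(sw$constrained), 5L)
  expect_equal(sum(sw$trail$accepted), length(sw$constrained))
  # only b heterogeneous: b should stay free on this seed
  cfg_b <- shared_config(vary = "b")
  obs_b <- generate_structural(cfg_b, seed = 8)
  sw_b <- stepwise_constrain(obs_b)
  expect_false("b" %in% sw_b$constrained)
  expect_gte(length(intersect(c("a", "c", "d", "e", "f"),
                              sw_b$constrained)), 4L)
  # determinism: identical data give an identical trail
  sw_b2 <- stepwise_constrain(obs_b)
  expect_identical(sw_b$trail, sw_b2$trail)
  # single group: nothing to constrain
  single <- obs_b[obs_b$group == "DSSstd", ]
  sw_s <- stepwise_constrain(single)
  expect_identical(sw_s$constrained, character(0))
  expect_equal(nrow(sw_s$trail), 0L)
})

test_that("shared parameters are identical across groups in the output", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 23)
  fit <- fit_multigroup(obs, constrained = c("b", "e", "f"))
  cf <- fit$coefficients
  for (pth in c("b", "e", "f")) {
    expect_equal(length(unique(cf$estimate[cf$path == pth])), 1L)
    expect_true(all(cf$shared[cf$path == pth]))
  }
  expect_gt(length(unique(cf$estimate[cf$path == "a"])), 1L)
})

test_that("degenerate inputs raise informative errors", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 29)
  bad <- obs
  bad$tfi[bad$group == "AdvSer"] <- 1.5   # constant TFI in one group
  expect_error(fit_multigroup(bad), "AdvSer")
  bad2 <- obs
  bad2$d_aut[bad2$group == "DSSstd"] <- 7
  expect_error(fit_multigroup(bad2), "zero-variance")
  expect_error(fit_multigroup(obs, constrained = "q"), "unknown")
})

test_that("R-squared separates explained groups from pure-noise responses", {
  cfg <- trial_config()
  obs <- generate_structural(cfg, seed = 37)
  withr::with_seed(99, {
    obs$d_sum <- rnorm(nrow(obs))   # response unrelated to predictors
  })
  fit <- fit_multigroup(obs)
  r2 <- path_r_squared(fit)
  expect_true(all(r2$r_squared >= 0 & r2$r_squared <= 1))
  # pure-noise R2 stays modest at n = 15 with 3 predictors
  expect_lt(mean(r2$r_squared[r2$response == "d_sum"]), 0.45)
})
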