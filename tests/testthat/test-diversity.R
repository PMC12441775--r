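test_that("species proportions normalize, drop absent species, and reject degenerate input", {
  expect_equal(unname(species_proportions(c(A = 2, B = 2))), c(0.5, 0.5))
  expect_equal(unname(species_proportions(c(A = 5, B = 0))), 1)
  expect_equal(unname(species_proportions(c(A = 7, B = 2, C = 1))),
               c(0.7, 0.2, 0.1))
  expect_equal(sum(species_proportions(rlnorm(20))), 1, tolerance = 1e-12)
  expect_error(species_proportions(c(A = 0, B = 0)), "empty community")
  expect_error(species_proportions(c(A = -1, B = 2)), "nonnegative")
  expect_error(species_proportions(numeric(0)))
})

test_that("Hill diversity matches closed forms and analytic limits", {
  # uniform community of S species has diversity S at every order
  for (S in c(2, 5, 9)) {
    p <- rep(1 / S, S)
    expect_equal(hill_diversity(p, c(0, 0.5, 1, 2, 4, Inf)),
                 rep(S, 6), tolerance = 1e-12)
  }
  expect_equal(hill_diversity(c(0.5, 0.5), 2), 2, tolerance = 1e-12)
  # order-1 limit equals the exponential of the entropy sum (oracle:
  # direct numeric evaluation of the sum)
  p <- c(0.7, 0.2, 0.1)
  oracle1 <- exp(0.7 * log(1 / 0.7) + 0.2 * log(1 / 0.2) +
                   0.1 * log(1 / 0.1))
  expect_equal(hill_diversity(p, 1), oracle1, tolerance = 1e-12)
  expect_equal(hill_diversity(p, Inf), 1 / 0.7, tolerance = 1e-12)
  expect_error(hill_diversity(p, -0.5), "nonnegative")
})

test_that("Shannon entropy is the log of order-1 Hill diversity", {
  expect_equal(shannon_index(c(A = 3)), 0)
  expect_equal(shannon_index(rep(1, 4)), log(4), tolerance = 1e-12)
  p <- c(0.7, 0.2, 0.1)
  expect_equal(shannon_index(p), -sum(p * log(p)), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    x <- random_community()
    expect_equal(exp(shannon_index(x)), hill_diversity(x, 1),
                 tolerance = 1e-12)
  }
})

test_that("diversity profiles are monotone with exact limits over random communities", {
  set.seed(101)
  orders <- c(0, 0.5, 1, 2, 4, Inf)
  for (i in 1:500) {
    x <- random_community()
    prof <- diversity_profile(x, orders)$diversity
    expect_true(all(diff(prof) <= 1e-10))
    expect_identical(prof[1], as.numeric(length(x)))
    p <- species_proportions(x)
    expect_equal(prof[6], 1 / max(p), tolerance = 1e-12)
    expect_true(all(prof >= 1 - 1e-12 & prof <= length(x) + 1e-12))
    # continuity across the order-1 limit
    expect_lt(abs(hill_diversity(x, 1 + 1e-6) - hill_diversity(x, 1)),
              1e-4)
    expect_lt(abs(hill_diversity(x, 1 - 1e-6) - hill_diversity(x, 1)),
              1e-4)
  }
  # dominance structure gives a strictly decreasing profile
  prof <- diversity_profile(c(A = 90, B = 9, C = 1), orders)$diversity
  expect_true(all(diff(prof) < 0))
})

test_that("Hill diversity agrees with an established Renyi implementation", {
  set.seed(5)
  x <- matrix(rlnorm(8 * 6, 1, 1), 1)
  scales <- c(0, 0.5, 1, 2, 4)
  ref <- exp(as.numeric(vegan::renyi(x, scales = scales)))
  expect_equal(hill_diversity(as.numeric(x), scales), ref,
               tolerance = 1e-8)
})

test_that("alpha/gamma partitioning pools before normalizing and averages per field", {
  same <- list(f1 = c(A = 3, B = 1), f2 = c(A = 3, B = 1))
  ag <- alpha_gamma(same, a = 1)
  expect_equal(ag$gamma, ag$alpha, tolerance = 1e-12)
  ag0 <- alpha_gamma(list(c(A = 1), c(B = 2)), a = 0)
  expect_equal(ag0$gamma, 2)
  expect_equal(ag0$alpha, 1)
  ag1 <- alpha_gamma(list(c(A = 1, B = 1), c(B = 1, C = 1)), a = 0)
  expect_equal(ag1$gamma, 3)
  expect_equal(ag1$alpha, 2)
  # alpha <= gamma at a = 0 over random field sets
  set.seed(21)
  for (i in 1:25) {
    fields <- replicate(4, random_community(), simplify = FALSE)
    ag <- alpha_gamma(fields, a = 0)
    expect_lte(ag$alpha, ag$gamma + 1e-12)
  }
})

test_that("survey profiles pool blocks within field x treatment and enforce one basis", {
  survey <- data.frame(
    field = c(1, 1, 1, 1), treatment = "T1",
    species = c("A", "B", "A", "B"), quantity = c(3, 1, 1, 3),
    block = c(1, 1, 2, 2))
  prof <- survey_profiles(survey, orders = c(0, 2))
  expect_equal(nrow(prof), 2L)
  # pooled community is (4, 4): even pair
  expect_equal(prof$diversity[prof$order_a == 2], 2, tolerance = 1e-12)
  survey$basis <- c("counts", "counts", "biomass", "counts")
  expect_error(survey_profiles(survey), "mixed")
})
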