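grid <- make_observation_grid()

test_that("relative spread is the interquartile distance over the median, in percent", {
  expect_equal(relative_spread(1000, 2000, 4000), 150)
  expect_equal(relative_spread(1500, 2000, 1500), 0)
  expect_error(relative_spread(1, -1, 2), "positive")
  # for a probit fit it depends only on sigma: closed form at sigma = 0.3
  z75 <- norm_quantile_oracle(0.75)
  expected <- 100 * (10^(z75 * 0.3) - 10^(-z75 * 0.3))
  for (mu in c(2.8, 3.3, 3.9)) {
    lt <- lethal_times(fake_probit_fit(mu, 0.3, grid))
    expect_equal(relative_spread(lt$lt25, lt$lt50, lt$lt75), expected,
                 tolerance = 1e-9)
  }
  # invariant to the time unit
  set.seed(2)
  for (i in 1:20) {
    lt50 <- runif(1, 800, 5000)
    lt25 <- lt50 / runif(1, 1.1, 3)
    lt75 <- lt50 * runif(1, 1.1, 3)
    expect_equal(relative_spread(lt25, lt50, lt75),
                 relative_spread(lt25 / 60, lt50 / 60, lt75 / 60))
  }
})

test_that("sensitivity labels follow the strict cohort-median rules", {
  cohort <- c(1000, 1500, 2000, 3000, 4000)  # median 2000
  expect_identical(classify_sensitivity(lt25 = 900, lt75 = 1800, cohort),
                   "critically_sensitive")
  expect_identical(classify_sensitivity(lt25 = 2500, lt75 = 5000, cohort),
                   "safely_tolerant")
  expect_identical(classify_sensitivity(lt25 = 1500, lt75 = 2500, cohort),
                   "intermediate")
  # boundary ties resolve to intermediate (strict inequalities)
  expect_identical(classify_sensitivity(lt25 = 2000, lt75 = 2000, cohort),
                   "intermediate")
  expect_error(classify_sensitivity(1, 2, cohort_lt50s = 3), ">= 2 masses")
})

test_that("critically sensitive and safely tolerant are mutually exclusive, order-invariant", {
  study <- simulate_study(simulation_config(n_masses = 9, seed = 61))
  cl <- classify_cohort(fit_all_masses(study$eggs, study$grid))
  # a mass can never satisfy both rules since LT25 <= LT75
  expect_true(all(cl$lt25 <= cl$lt75))
  med <- attr(cl, "median_lt50")
  expect_false(any(cl$lt75 < med & cl$lt25 > med))
  # permuting the input masses leaves every per-mass label unchanged
  perm <- sample(nrow(cl))
  cl2 <- classify_cohort(fit_all_masses(study$eggs, study$grid)[perm, ])
  m <- match(cl$mass_id, cl2$mass_id)
  expect_identical(cl$sensitivity_label, cl2$sensitivity_label[m])
  expect_equal(cl$relative_spread, cl2$relative_spread[m])
})

test_that("the quadratic spread model recovers exact curvature and rejects flat cohorts", {
  x <- seq(2.9, 3.7, length.out = 8)
  curved <- data.frame(lt50 = 10^x,
                       relative_spread = 200 - 150 * (x - 3.3)^2,
                       extrapolated = FALSE)
  fit <- fit_spread_vs_lt50(curved)
  expect_equal(unname(fit$coefficients[3]), -150, tolerance = 1e-6)
  expect_true(fit$inverted_u)
  expect_lt(fit$p_one_sided, 1e-6)
  flat <- data.frame(lt50 = 10^x, relative_spread = 120, extrapolated = FALSE)
  ffit <- fit_spread_vs_lt50(flat)
  expect_false(ffit$inverted_u)
  expect_lt(abs(ffit$quadratic_coef), 1e-8)
  expect_error(fit_spread_vs_lt50(curved[1:3, ]), ">= 4")
})

test_that("Spearman correlation matches the rank formula on tie-free data", {
  up <- data.frame(lt50 = 1:6, relative_spread = c(10, 20, 30, 40, 50, 60))
  expect_equal(spearman_lt50_spread(up)$rho, 1)
  down <- data.frame(lt50 = 1:6, relative_spread = c(60, 50, 40, 30, 20, 10))
  expect_equal(spearman_lt50_spread(down)$rho, -1)
  toy <- data.frame(lt50 = c(1000, 1400, 2100, 2500, 3300, 4100),
                    relative_spread = c(40, 25, 160, 90, 130, 55))
  expect_equal(spearman_lt50_spread(toy)$rho,
               rank_rho_oracle(toy$lt50, toy$relative_spread))
})

test_that("the Mann-Whitney season comparison counts pairwise wins", {
  a <- data.frame(lt50 = c(1, 2, 3))
  b <- data.frame(lt50 = c(10, 11, 12))
  sep <- compare_seasons(a, b, "lt50")
  expect_equal(sep$U, 0)
  expect_lt(sep$p, 0.1)
  same <- compare_seasons(a, a, "lt50")
  expect_gt(same$p, 0.99)
  x <- data.frame(lt50 = c(1200, 1900, 2500, 3100, 4800))
  y <- data.frame(lt50 = c(900, 2100, 2600, 3900, 5200))
  expect_equal(compare_seasons(x, y, "lt50")$U,
               u_count_oracle(x$lt50, y$lt50))
  expect_error(compare_seasons(x, data.frame(lt50 = NA_real_), "lt50"),
               "both cohorts")
})
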