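grid <- make_observation_grid()

test_that("deaths split across symmetric intervals centre the LT50 on the grid", {
  # equal deaths in (720,1017] and (4048,5719]: likelihood symmetry forces
  # the location to the log-midpoint of the schedule, LT50 ~ 2029 min
  eggs <- eggs_from_cells(c(0, 10, 0, 0, 0, 0, 10, 0), grid)
  fit <- fit_interval_probit(eggs, grid)
  expect_true(fit$converged)
  lt50 <- lethal_times(fit)$lt50
  expect_lt(abs(lt50 / 2029 - 1), 0.01)
})

test_that("the MLE matches the exhaustive grid-search oracle on a fixed mass", {
  # 10 eggs: 2 in (720,1017], 3 in (1436,2029], 3 in (2029,2866], 2 censored
  counts <- c(0, 2, 0, 3, 3, 0, 0, 2)
  eggs <- eggs_from_cells(counts, grid)
  fit <- fit_interval_probit(eggs, grid)
  oracle <- probit_grid_oracle(counts, grid)
  expect_lt(abs(fit$mu - oracle["mu"]), 2e-3)
  expect_lt(abs(fit$sigma - oracle["sigma"]), 2e-3)
  expect_gte(fit$loglik, oracle["loglik"] - 1e-6)
})

test_that("boundary masses yield degenerate bound-only fits", {
  # all dead before the first checkpoint
  all_first <- eggs_from_cells(c(20, rep(0, 7)), grid)
  f1 <- fit_interval_probit(all_first, grid)
  expect_true(f1$degenerate)
  expect_identical(f1$bound, "upper")
  lt1 <- lethal_times(f1)
  expect_true(lt1$extrapolated)
  expect_equal(lt1$lt50, 720)
  expect_error(lethal_quantile(f1, 0.5), "degenerate")
  # no deaths at all
  none <- eggs_from_cells(c(rep(0, 7), 20), grid)
  f2 <- fit_interval_probit(none, grid)
  expect_true(f2$degenerate)
  expect_identical(f2$bound, "lower")
  expect_equal(lethal_times(f2)$lt50, 5719)
  # single interior interval: exact zero-spread fit at the log-midpoint
  mid <- eggs_from_cells(c(0, 0, 0, 15, 0, 0, 0, 0), grid)
  f3 <- fit_interval_probit(mid, grid)
  expect_false(f3$degenerate)
  expect_equal(f3$mu, (log10(1436) + log10(2029)) / 2)
  lt3 <- lethal_times(f3)
  expect_equal(lt3$lt25, lt3$lt75, tolerance = 1e-3)  # sigma at the floor
})

test_that("lethal quantiles follow the closed form with an independent normal quantile", {
  fit <- fake_probit_fit(mu = 3.0, sigma = 0.3, grid)
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_equal(lethal_quantile(fit, p),
                 10^(3.0 + 0.3 * norm_quantile_oracle(p)), tolerance = 1e-9)
  }
  expect_equal(lethal_quantile(fit, 0.5), 10^3.0)
  # zero-spread limit: every quantile collapses onto the median
  flat <- fake_probit_fit(mu = 3.2, sigma = 1e-4, grid)
  expect_equal(lethal_quantile(flat, 0.9) / lethal_quantile(flat, 0.1), 1,
               tolerance = 1e-3)
  expect_error(lethal_quantile(fit, 1), "strictly between")
})

test_that("quantile symmetry and monotonicity hold on fitted masses", {
  set.seed(21)
  tol_range <- function() tolerance_model(mu_S = 2.0,
                                          mu_T = runif(1, 2.9, 3.7),
                                          sigma_within = runif(1, 0.1, 0.4))
  for (i in 1:25) {
    eggs <- simulate_egg_mass("TT", "TT", 40, "dominant", tol_range(), grid)
    fit <- fit_interval_probit(eggs, grid)
    if (fit$degenerate) next
    lt <- lethal_times(fit)
    expect_lt(abs((log10(lt$lt75) - log10(lt$lt50)) -
                    (log10(lt$lt50) - log10(lt$lt25))), 1e-9)
    if (fit$sigma > fit$sigma_floor) {
      q <- lethal_quantile(fit, c(0.2, 0.4, 0.6, 0.8))
      expect_true(all(diff(q) > 0))
    }
  }
})

test_that("the fit is invariant to the order of the egg records", {
  set.seed(13)
  eggs <- simulate_egg_mass("ST", "ST", 60, "incomplete",
                            tolerance_model(), grid)
  fit1 <- fit_interval_probit(eggs, grid)
  fit2 <- fit_interval_probit(eggs[sample(nrow(eggs)), ], grid)
  expect_identical(fit1$mu, fit2$mu)
  expect_identical(fit1$sigma, fit2$sigma)
})

test_that("the cohort fitter assembles one summary row per mass", {
  study <- simulate_study(simulation_config(n_masses = 5, seed = 17))
  s <- fit_all_masses(study$eggs, study$grid)
  expect_equal(nrow(s), 5)
  expect_identical(s$mass_id, study$masses$mass_id)
  expect_equal(s$n_eggs, study$masses$n_eggs)
  expect_true(all(s$lt25 <= s$lt50 & s$lt50 <= s$lt75))
})
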