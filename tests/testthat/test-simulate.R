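grid <- make_observation_grid()

test_that("zero within-genotype spread censors deterministically onto the grid", {
  # mean strictly between checkpoints 1436 and 2029 -> all deaths in (1436, 2029]
  tol <- tolerance_model(mu_S = 2.0, mu_T = log10(1500), sigma_within = 0)
  set.seed(1)
  eggs <- simulate_egg_mass("TT", "TT", 25, "dominant", tol, grid)
  expect_true(all(eggs$censored == 0))
  expect_true(all(eggs$interval_left_min == 1436))
  expect_true(all(eggs$interval_right_min == 2029))
  # mean beyond the last checkpoint -> all right-censored
  tol2 <- tolerance_model(mu_S = 2.0, mu_T = 3.8, sigma_within = 0)
  eggs2 <- simulate_egg_mass("TT", "TT", 25, "dominant", tol2, grid)
  expect_true(all(eggs2$censored == 1))
  expect_true(all(is.na(eggs2$interval_right_min)))
  # a latent time exactly on a checkpoint belongs to that checkpoint's interval
  tol3 <- tolerance_model(mu_S = 2.0, mu_T = log10(1017), sigma_within = 0)
  eggs3 <- simulate_egg_mass("TT", "TT", 5, "dominant", tol3, grid)
  expect_true(all(eggs3$interval_right_min == 1017))
})

test_that("censoring is order-preserving across well-separated genotypes", {
  # with negligible within-genotype noise, no tolerant egg can be recorded
  # in an earlier interval than any sensitive egg
  tol <- tolerance_model(mu_S = 3.0, mu_T = 3.6, sigma_within = 0.01)
  set.seed(7)
  for (i in 1:10) {
    eggs <- simulate_egg_mass("ST", "TT", 60, "recessive", tol, grid)
    sens <- eggs[eggs$genotype != "TT", ]
    tolr <- eggs[eggs$genotype == "TT", ]
    expect_true(max(sens$interval_right_min) <=
                  min(c(tolr$interval_right_min, Inf), na.rm = TRUE))
  }
})

test_that("a study is byte-identical when re-simulated from the same seed", {
  cfg <- simulation_config(n_masses = 4, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$eggs, s2$eggs)
  expect_identical(s1$masses, s2$masses)
})

test_that("dominant and recessive are the d = 1 and d = 0 limits of incomplete dominance", {
  base <- list(n_masses = 3, seed = 123)
  s_dom <- simulate_study(do.call(simulation_config,
            c(base, list(mode = inheritance_mode("dominant")))))
  s_d1 <- simulate_study(do.call(simulation_config,
            c(base, list(mode = inheritance_mode("incomplete", d = 1)))))
  expect_identical(s_dom$eggs, s_d1$eggs)
  s_rec <- simulate_study(do.call(simulation_config,
            c(base, list(mode = inheritance_mode("recessive")))))
  s_d0 <- simulate_study(do.call(simulation_config,
            c(base, list(mode = inheritance_mode("incomplete", d = 0)))))
  expect_identical(s_rec$eggs, s_d0$eggs)
})

test_that("parental genotypes follow Hardy-Weinberg at the configured allele frequency", {
  study <- simulate_study(simulation_config(n_masses = 5000,
                                            eggs_per_mass = c(1, 1),
                                            allele_freq_T = 0.5, seed = 31))
  parents <- c(study$masses$parent1, study$masses$parent2)
  obs <- table(factor(parents, levels = c("SS", "ST", "TT")))
  chi <- chisq.test(obs, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.01)
  # boundary frequency: no tolerance allele at all
  s0 <- simulate_study(simulation_config(n_masses = 10, allele_freq_T = 0,
                                         eggs_per_mass = c(5, 5), seed = 4))
  expect_true(all(s0$masses$parent1 == "SS" & s0$masses$parent2 == "SS"))
  expect_true(all(s0$eggs$genotype == "SS"))
})

test_that("offspring genotype frequencies pass a Mendelian goodness-of-fit screen", {
  # chi-square GOF against the exact 1:2:1 should be retained (alpha = 0.01)
  # in at least 95% of seeds
  set.seed(55)
  keep <- replicate(50, {
    g <- draw_offspring_genotypes("ST", "ST", 200)
    obs <- table(factor(g, levels = c("SS", "ST", "TT")))
    chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value > 0.01
  })
  expect_gte(mean(keep), 0.95)
})

test_that("simulated mass sizes and controls respect the study design", {
  study <- simulate_study(simulation_config(n_masses = 12, seed = 8))
  expect_true(all(study$masses$n_eggs >= 80 & study$masses$n_eggs <= 120))
  expect_true(all(study$masses$n_control_eggs == 20))
  expect_true(all(study$masses$control_survival == 1))
  expect_identical(unique(study$eggs$mass_id), study$masses$mass_id)
})
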