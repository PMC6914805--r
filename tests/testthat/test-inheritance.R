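grid <- make_observation_grid()

full_modes <- c("dominant", "recessive", "overdominant", "underdominant")
crosses <- list(c("SS", "SS"), c("SS", "ST"), c("SS", "TT"),
                c("ST", "ST"), c("ST", "TT"), c("TT", "TT"))

test_that("expected F1 patterns are exactly Mendelian for every mode and cross", {
  for (m in full_modes) {
    sens <- sensitive_genotypes(m)
    for (cr in crosses) {
      pat <- expected_pattern(m, cr[1], cr[2])
      oracle_frac <- sum(mendel_enum_oracle(cr[1], cr[2])[sens])
      expect_equal(pat$expected_sensitive_fraction, oracle_frac)
      expect_true(pat$expected_sensitive_fraction %in% c(0, 0.25, 0.5, 0.75, 1))
      expect_identical(pat$modality,
                       if (oracle_frac > 0 && oracle_frac < 1) "bimodal"
                       else "unimodal")
    }
  }
  # headline cases
  p1 <- expected_pattern("recessive", "ST", "TT")
  expect_identical(p1$modality, "bimodal")
  expect_equal(p1$expected_sensitive_fraction, 0.5)
  p2 <- expected_pattern("dominant", "TT", "TT")
  expect_identical(p2$modality, "unimodal")
  expect_identical(p2$skew, "right")
  expect_equal(p2$expected_sensitive_fraction, 0)
  p3 <- expected_pattern("recessive", "ST", "ST")
  expect_identical(p3$modality, "bimodal")
  expect_equal(p3$expected_sensitive_fraction, 0.75)  # Mendelian 3:1
  # incomplete dominance with heterozygotes present is unimodal/broad
  p4 <- expected_pattern(inheritance_mode("incomplete", d = 0.5), "ST", "ST")
  expect_identical(p4$modality, "unimodal")
})

test_that("recessivity categories encode the four diagnostic patterns", {
  expect_identical(
    assign_recessivity_category("unimodal", "critically_sensitive", 40, 1)$category, "i")
  expect_identical(
    assign_recessivity_category("unimodal", "safely_tolerant", 60, 0)$category, "ii")
  expect_identical(
    assign_recessivity_category("bimodal", "intermediate", 450, 0.5)$category, "iii")
  expect_identical(
    assign_recessivity_category("bimodal", "intermediate", 450, 0.75)$category, "iv")
  # the windows touch at 0.65: the boundary belongs to (iii)
  expect_identical(
    assign_recessivity_category("bimodal", "intermediate", 450, 0.65)$category, "iii")
  # large spread is required for the bimodal categories
  expect_identical(
    assign_recessivity_category("bimodal", "intermediate", 120, 0.5)$category, "none")
  # broad unimodal masses match nothing
  expect_identical(
    assign_recessivity_category("unimodal", "intermediate", 220, 0.4)$category, "none")
  expect_identical(
    assign_recessivity_category("unimodal", "critically_sensitive", NA, 1)$category, "none")
})

test_that("simulated diagnostic crosses land in their recessivity categories", {
  # a recessive-tolerance cohort balanced so the cohort median LT50 sits
  # inside the observation window (as in a real mid-lethality assay)
  cfg <- simulation_config(
    n_masses = 6, eggs_per_mass = c(110, 120),
    crosses = list(c("SS", "SS"), c("ST", "TT"), c("ST", "ST"),
                   c("TT", "TT"), c("TT", "TT"), c("ST", "TT")),
    mode = inheritance_mode("recessive"), seed = 19)
  study <- simulate_study(cfg)
  cl <- classify_cohort(fit_all_masses(study$eggs, study$grid))
  inh <- evaluate_inheritance(study$eggs, cl, study$grid)
  cat_of <- setNames(inh$category, inh$mass_id)
  # A: SS x SS, all highly sensitive, tight -> category i
  expect_identical(unname(cat_of["A"]), "i")
  # B: ST x TT, ~50:50 split with very large spread -> category iii
  expect_identical(unname(cat_of["B"]), "iii")
  expect_identical(inh$modality[inh$mass_id == "B"], "bimodal")
  # C: ST x ST, ~3:1 sensitive excess -> category iv
  expect_identical(unname(cat_of["C"]), "iv")
  expect_gt(inh$sensitive_fraction[inh$mass_id == "C"], 0.65)

  # an incompletely dominant ST x ST mass whose genotype means overlap is a
  # broad unimodal distribution and matches no recessivity category
  cfg2 <- simulation_config(
    n_masses = 4, eggs_per_mass = c(110, 120),
    crosses = list(c("SS", "SS"), c("ST", "ST"), c("ST", "ST"),
                   c("TT", "TT")),
    mode = inheritance_mode("incomplete", d = 0.5),
    tolerance = tolerance_model(mu_S = 3.0, mu_T = 3.6, sigma_within = 0.2),
    seed = 23)
  study2 <- simulate_study(cfg2)
  cl2 <- classify_cohort(fit_all_masses(study2$eggs, study2$grid))
  inh2 <- evaluate_inheritance(study2$eggs, cl2, study2$grid)
  expect_identical(inh2$modality[inh2$mass_id == "B"], "unimodal")
  expect_identical(inh2$category[inh2$mass_id == "B"], "none")
})

test_that("hypothesis tallies follow the category support rules", {
  inh <- data.frame(
    mass_id = c("A", "B", "C", "D", "E"),
    treatment = "AMD60",
    modality = c("unimodal", "unimodal", "unimodal", "bimodal", "unimodal"),
    category = c("i", "none", "none", "iv", "ii"),
    stringsAsFactors = FALSE)
  tally <- tally_hypothesis_support(inh)
  sup <- setNames(tally$n_support, tally$mode)
  # every unimodal mass is compatible with some degree of dominance
  expect_equal(unname(sup["incomplete"]), 4)
  # categories i-iv support full recessivity
  expect_equal(unname(sup["recessive"]), 3)
  # categories i-iii support dominance / over / underdominance (iv does not)
  expect_equal(unname(sup["dominant"]), 2)
  expect_equal(unname(sup["overdominant"]), 2)
  expect_equal(unname(sup["underdominant"]), 2)
  expect_identical(attr(tally, "full_recessive_only"), "D")
  expect_true(all(tally$fraction >= 0 & tally$fraction <= 1))

  # all broad unimodal masses: incomplete dominance fraction 1, nothing in iv
  allu <- data.frame(mass_id = letters[1:4], treatment = "Cu9",
                     modality = "unimodal", category = "none",
                     stringsAsFactors = FALSE)
  t2 <- tally_hypothesis_support(allu)
  expect_equal(t2$fraction[t2$mode == "incomplete"], 1)
  expect_length(attr(t2, "full_recessive_only"), 0)
})

test_that("an end-to-end mixed cohort tallies its known generating structure", {
  # 6 incompletely dominant masses with overlapping genotype means (broad
  # unimodal) + 2 recessive ST x TT masses (bimodal)
  base <- simulate_study(simulation_config(
    n_masses = 6, seed = 303,
    tolerance = tolerance_model(mu_S = 3.0, mu_T = 3.6, sigma_within = 0.2)))
  rec <- simulate_study(simulation_config(
    n_masses = 2, crosses = list(c("ST", "TT"), c("ST", "TT")),
    mode = inheritance_mode("recessive"), seed = 304))
  rec$eggs$mass_id <- paste0("R", rec$eggs$mass_id)
  eggs <- rbind(base$eggs, rec$eggs)
  cl <- classify_cohort(fit_all_masses(eggs, grid))
  inh <- evaluate_inheritance(eggs, cl, grid)
  # the recessive masses drive the bimodality; the broad unimodal cohort may
  # contribute at most the detector's known few-percent false-positive rate
  expect_lte(sum(inh$modality[!grepl("^R", inh$mass_id)] == "bimodal"), 1)
  expect_gte(sum(inh$modality[grepl("^R", inh$mass_id)] == "bimodal"), 1)
  tally <- tally_hypothesis_support(inh)
  expect_equal(tally$n_support[tally$mode == "incomplete"],
               sum(inh$modality == "unimodal"))
})

test_that("the cohort likelihood is maximised, and mode fits nest as expected", {
  tol <- tolerance_model(mu_S = 2.95, mu_T = 3.65, sigma_within = 0.15)
  study <- simulate_study(simulation_config(n_masses = 6, seed = 881,
                                            mode = inheritance_mode("dominant"),
                                            tolerance = tol))
  fits <- lapply(c("dominant", "recessive", "incomplete"), function(m)
    fit_inheritance_mode(study$eggs, study$grid, m))
  names(fits) <- c("dominant", "recessive", "incomplete")
  # incomplete dominance nests full dominance: its maximum cannot be lower
  expect_gte(fits$incomplete$loglik, fits$dominant$loglik - 0.5)
  # the generating mode beats the recessive misfit outright
  expect_gt(fits$dominant$loglik, fits$recessive$loglik)
  # and wins on BIC thanks to parsimony
  r <- rank_inheritance_modes(study$eggs, study$grid,
                              modes = c("dominant", "recessive", "incomplete"))
  expect_identical(attr(r, "top_mode"), "dominant")
  expect_true(all(diff(r$bic) >= 0))
})
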