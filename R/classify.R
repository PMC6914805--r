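# Per-mass statistics and cohort-level classification and tests.

#' Relative spread of an egg mass
#'
#' The within-mass variability statistic: the interquartile distance of
#' lethal times divided by their median, expressed as a percentage,
#' `100 * (LT75 - LT25) / LT50`. It is invariant to the time unit (minutes
#' or hours) and, for a probit fit, depends only on the scale:
#' `100 * (10^(z_.75 * sigma) - 10^(-z_.75 * sigma))`.
#'
#' @param lt25,lt50,lt75 lethal-time quartiles, minutes (vectors allowed).
#' @return Relative spread in percent.
#' @examples
#' relative_spread(1000, 2000, 4000)  # 150
#' @export
relative_spread <- function(lt25, lt50, lt75) {
  ok <- !is.na(lt50)
  if (any(lt50[ok] <= 0)) stop("'lt50' must be positive")
  100 * (lt75 - lt25) / lt50
}

#' Sensitivity label of a mass relative to its cohort
#'
#' A mass is critically sensitive when its LT75 falls strictly below the
#' cohort median of LT50 values (even its most tolerant quartile dies before
#' the typical mass's median), and safely tolerant when its LT25 lies
#' strictly above that median. All other masses, including boundary ties,
#' are intermediate.
#'
#' @param lt25,lt75 the mass's lethal-time quartiles (vectors allowed).
#' @param cohort_lt50s LT50 values of all masses in the cohort (>= 2).
#' @return Character vector: `"critically_sensitive"`, `"safely_tolerant"`
#'   or `"intermediate"`.
#' @examples
#' classify_sensitivity(lt25 = 900, lt75 = 1800,
#'                      cohort_lt50s = c(1000, 1500, 2000, 3000, 4000))
#' @export
classify_sensitivity <- function(lt25, lt75, cohort_lt50s) {
  if (length(cohort_lt50s) < 2) stop("the cohort must contain >= 2 masses")
  med <- median(cohort_lt50s)
  ifelse(lt75 < med, "critically_sensitive",
         ifelse(lt25 > med, "safely_tolerant", "intermediate"))
}

#' Classify every mass of a fitted cohort
#'
#' Adds the per-mass statistics to a mass summary table (see
#' [fit_all_masses()]): relative spread, sensitivity label against the
#' cohort median LT50, the descriptive >= 300% spread flag, and the rank of
#' each mass from most sensitive to most tolerant. Degenerate (bound-only)
#' masses keep their bound value as the LT50 stand-in for the cohort median
#' — an upper bound below the median still implies critical sensitivity and
#' a lower bound above it safe tolerance — but their relative spread is
#' reported as `NA`.
#'
#' @param mass_summary data frame from [fit_all_masses()].
#' @param spread_small small-spread threshold, percent (recorded for
#'   downstream category assignment).
#' @param spread_large large-spread threshold, percent; also used for the
#'   descriptive `spread_flag_300` marker.
#' @return The input with columns `relative_spread`, `sensitivity_label`,
#'   `spread_flag_300`, `tolerance_rank` added; the cohort median LT50 and
#'   the thresholds are attached as attributes `median_lt50` and
#'   `thresholds`.
#' @examples
#' study <- simulate_study(simulation_config(n_masses = 5, seed = 3))
#' classify_cohort(fit_all_masses(study$eggs, study$grid))
#' @export
classify_cohort <- function(mass_summary, spread_small = 100,
                            spread_large = 300) {
  if (nrow(mass_summary) < 2) stop("the cohort must contain >= 2 masses")
  out <- mass_summary
  spread <- relative_spread(out$lt25, out$lt50, out$lt75)
  spread[out$degenerate] <- NA_real_
  out$relative_spread <- spread
  out$sensitivity_label <-
    classify_sensitivity(out$lt25, out$lt75, out$lt50)
  out$spread_flag_300 <- !is.na(spread) & spread >= spread_large
  out$tolerance_rank <- rank(out$lt50, ties.method = "first")
  attr(out, "median_lt50") <- median(out$lt50)
  attr(out, "thresholds") <- list(spread_small = spread_small,
                                  spread_large = spread_large)
  out
}

#' Quadratic fit of relative spread against log10 LT50
#'
#' Tests the inverted-U prediction: if tolerance is inherited at a single
#' locus, the most sensitive and most tolerant masses should be genetically
#' uniform (small spread) while intermediate masses mix phenotypes (large
#' spread). Fits `relative_spread ~ log10(LT50) + log10(LT50)^2` by least
#' squares and performs a one-sided test of the quadratic coefficient being
#' negative.
#'
#' @param classified data frame from [classify_cohort()].
#' @param exclude_extrapolated drop masses whose LT50 is extrapolated beyond
#'   the observation window before fitting.
#' @param alpha significance level of the one-sided quadratic test.
#' @return List: `coefficients` (intercept, linear, quadratic),
#'   `quadratic_coef`, `p_one_sided`, `inverted_u` (verdict), `n_used`,
#'   `model` (the `lm` fit).
#' @export
fit_spread_vs_lt50 <- function(classified, exclude_extrapolated = TRUE,
                               alpha = 0.05) {
  d <- classified[!is.na(classified$relative_spread), , drop = FALSE]
  if (exclude_extrapolated) d <- d[!d$extrapolated, , drop = FALSE]
  if (nrow(d) < 4)
    stop("need >= 4 usable masses to fit the spread-LT50 curve (have ",
         nrow(d), ")")
  x <- log10(d$lt50)
  y <- d$relative_spread
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  # an exactly quadratic cohort is a legitimate input; summary() warns about
  # the perfect fit but the coefficient and verdict are still well defined
  sm <- suppressWarnings(summary(fit))$coefficients
  c2 <- unname(cf[3])
  if (is.na(c2) || abs(c2) < 1e-8) {
    # flat (or rank-deficient) curvature: no inverted U
    p1 <- NA_real_
    verdict <- FALSE
  } else {
    tval <- sm["I(x^2)", "t value"]
    p1 <- pt(tval, df = fit$df.residual)  # lower tail: tests curvature < 0
    verdict <- isTRUE(c2 < 0 && !is.na(p1) && p1 < alpha)
  }
  list(coefficients = cf, quadratic_coef = c2, p_one_sided = p1,
       inverted_u = verdict, n_used = nrow(d), model = fit)
}

#' Spearman rank correlation of LT50 and relative spread
#'
#' @param classified data frame from [classify_cohort()].
#' @return List with `rho`, `p` (two-sided) and `n`.
#' @export
spearman_lt50_spread <- function(classified) {
  ok <- !is.na(classified$lt50) & !is.na(classified$relative_spread)
  if (sum(ok) < 3) stop("need >= 3 masses with spread values")
  ct <- cor.test(classified$lt50[ok], classified$relative_spread[ok],
                 method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Mann-Whitney comparison of two sampling seasons
#'
#' Two-sided Mann-Whitney U test of a per-mass metric (LT50 or relative
#' spread) between two cohorts, e.g. masses collected in different breeding
#' seasons. The reported `U` counts pairs in which the first cohort's value
#' exceeds the second's, so complete separation with the first cohort lower
#' gives `U = 0`.
#'
#' @param masses_a,masses_b classified mass tables (or any data frames
#'   holding the metric column).
#' @param metric `"lt50"` or `"relative_spread"`.
#' @return List with `U`, `p`, `n_a`, `n_b`.
#' @export
compare_seasons <- function(masses_a, masses_b,
                            metric = c("lt50", "relative_spread")) {
  metric <- match.arg(metric)
  va <- masses_a[[metric]]
  vb <- masses_b[[metric]]
  va <- va[!is.na(va)]
  vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0)
    stop("both cohorts must contain masses with the chosen metric")
  wt <- wilcox.test(va, vb, alternative = "two.sided", exact = FALSE,
                    correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(va), n_b = length(vb))
}
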