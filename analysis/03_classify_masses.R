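#!/usr/bin/env Rscript
# Cohort-level classification: sensitivity labels against the cohort median
# LT50, relative spread, the 300% spread marker, the inverted-U test of
# spread against log10 LT50, the Spearman correlation, and (for copper) the
# Mann-Whitney season comparison.

library(eggtol)

for (cohort in c("amd", "cu")) {
  summ <- read.csv(sprintf("results/mass_summary_%s.csv", cohort),
                   na.strings = c("", "NA"))
  cl <- classify_cohort(summ)
  write.csv(cl, sprintf("results/classification_%s.csv", cohort),
            row.names = FALSE, na = "")
  cat(sprintf("\n== %s ==\n", toupper(cohort)))
  cat("median LT50:", round(attr(cl, "median_lt50")), "min\n")
  print(table(cl$sensitivity_label))
  cat("masses with relative spread >= 300%:",
      paste(cl$mass_id[cl$spread_flag_300], collapse = ", "), "\n")

  sf <- fit_spread_vs_lt50(cl, exclude_extrapolated = TRUE)
  cat(sprintf("spread ~ log10 LT50 quadratic coef: %.1f (one-sided p = %.4g); inverted U: %s\n",
              sf$quadratic_coef, sf$p_one_sided, sf$inverted_u))
  sp <- spearman_lt50_spread(cl)
  cat(sprintf("Spearman LT50 vs spread: rho = %.3f, p = %.3g\n", sp$rho, sp$p))

  if (cohort == "cu") {
    a <- cl[cl$season == 2014, ]
    b <- cl[cl$season == 2016, ]
    for (metric in c("lt50", "relative_spread")) {
      ct <- compare_seasons(a, b, metric)
      cat(sprintf("season 2014 vs 2016, %s: U = %.1f, p = %.3f\n",
                  metric, ct$U, ct$p))
    }
  }
}
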