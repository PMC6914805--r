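#!/usr/bin/env Rscript
# Inheritance-pattern evaluation: per-mass modality and recessivity
# category, the tally of masses compatible with each dominance hypothesis,
# and the cohort-level maximum-likelihood comparison of the five modes.

library(eggtol)

grid <- make_observation_grid()

for (cohort in c("amd", "cu")) {
  eggs <- read_egg_table(sprintf("results/eggs_%s.csv", cohort), grid)
  summ <- read.csv(sprintf("results/mass_summary_%s.csv", cohort),
                   na.strings = c("", "NA"))
  cl <- classify_cohort(summ)
  inh <- evaluate_inheritance(eggs, cl, grid)
  write.csv(inh, sprintf("results/inheritance_%s.csv", cohort),
            row.names = FALSE, na = "")

  cat(sprintf("\n== %s ==\n", toupper(cohort)))
  cat("modality:", sum(inh$modality == "bimodal"), "bimodal /",
      nrow(inh), "masses\n")
  print(table(factor(inh$category, levels = c("i", "ii", "iii", "iv", "none"))))
  tally <- tally_hypothesis_support(inh)
  write.csv(tally, sprintf("results/hypothesis_support_%s.csv", cohort),
            row.names = FALSE)
  print(tally)
  iv <- attr(tally, "full_recessive_only")
  cat("masses uniquely supporting full recessivity (category iv):",
      if (length(iv)) paste(iv, collapse = ", ") else "none", "\n")

  ranking <- rank_inheritance_modes(eggs, grid)
  write.csv(as.data.frame(ranking),
            sprintf("results/mode_ranking_%s.csv", cohort), row.names = FALSE)
  print(ranking)
}
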