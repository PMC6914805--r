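#!/usr/bin/env Rscript
# Simulate the three egg-mass cohorts the downstream analyses consume: one
# AMD-like cohort (21 masses, one season) and two copper-like cohorts
# (20 masses each, two seasons), all under incomplete dominance (d = 0.5)
# with parents drawn at Hardy-Weinberg equilibrium (freq(T) = 0.5) and the
# default genotype-to-phenotype model. Writes egg-level CSVs to results/.

library(eggtol)

dir.create("results", showWarnings = FALSE)

amd <- simulate_study(simulation_config(
  n_masses = 21, treatment = "AMD60", season = "2013", seed = 20130401))
write_egg_table(amd, "results/eggs_amd.csv")
write.csv(amd$masses, "results/masses_truth_amd.csv", row.names = FALSE)

cu14 <- simulate_study(simulation_config(
  n_masses = 20, treatment = "Cu9", season = "2014", seed = 20140301))
cu16 <- simulate_study(simulation_config(
  n_masses = 20, treatment = "Cu9", season = "2016", seed = 20160301))
cu16$eggs$mass_id <- paste0(cu16$eggs$mass_id, "16")
cu16$masses$mass_id <- paste0(cu16$masses$mass_id, "16")
cu14$eggs$mass_id <- paste0(cu14$eggs$mass_id, "14")
cu14$masses$mass_id <- paste0(cu14$masses$mass_id, "14")
cu_eggs <- rbind(cu14$eggs, cu16$eggs)
write_egg_table(cu_eggs, "results/eggs_cu.csv")
write.csv(rbind(cu14$masses, cu16$masses), "results/masses_truth_cu.csv",
          row.names = FALSE)

cat("AMD cohort:", nrow(amd$masses), "masses,", nrow(amd$eggs), "eggs\n")
cat("Cu cohorts:", nrow(cu14$masses) + nrow(cu16$masses), "masses,",
    nrow(cu_eggs), "eggs\n")
cat("True parental crosses (AMD):\n")
print(table(paste(amd$masses$parent1, amd$masses$parent2, sep = "x")))
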