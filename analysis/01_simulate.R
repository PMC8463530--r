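#!/usr/bin/env Rscript
# Generate the study's synthetic inputs: two-sample GWAS summary statistics
# for a protein exposure with two downstream lipid mediators and a binary
# cardiovascular outcome, a reference dosage panel for LD estimation, and a
# four-compound randomized-trial dataset. Everything downstream (02-05)
# reads the files this writes under results/data/.

library(targetmr)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

cfg <- sim_config(
  m = 50, ld_rho = 0.8,
  n_exposure = 10000, n_outcome = 50000, n_reference = 5000,
  theta = 0.15, outcome_prevalence = 0.1,
  mediation = list(HDL = list(alpha = -0.5, beta_med = -0.2, gamma = numeric(50)),
                   LDL = list(alpha = 0.4, beta_med = 0.4, gamma = numeric(50))),
  seed = seed)
sim <- gen_two_sample_summary(cfg)

write_summary_stats(sim$exposure, file.path(out, "protein_pqtl.tsv"))
write_summary_stats(sim$outcome, file.path(out, "cvd_gwas.tsv"))
for (nm in names(sim$mediators)) {
  write_summary_stats(sim$mediators[[nm]],
                      file.path(out, paste0(tolower(nm), "_gwas.tsv")))
}
write_dosages(sim$reference, file.path(out, "reference_dosages.tsv"))

trials <- gen_trialset(trial_sim_config(seed = seed + 1))
write.csv(trials, file.path(out, "trials.csv"), row.names = FALSE)

cat("Simulated", nrow(sim$exposure$records), "cis variants;",
    "protein GWAS n =", cfg$n_exposure, "; outcome GWAS n =", cfg$n_outcome,
    "(prevalence", cfg$outcome_prevalence, ")\n")
cat("Trial set:", length(unique(trials$study_id)), "trials,",
    length(unique(trials$compound)), "compounds,",
    nrow(trials), "outcome rows -> results/data/\n")
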