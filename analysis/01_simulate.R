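#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
# 2,013 enrolled postmenopausal subjects, ten vitamin-D-pathway SNPs in HWE
# (three in high LD with instruments), log-25OHD driven by weak per-allele
# effects, a seasonal cosine and a latent confounder, and outcomes with a
# null causal effect but real confounding. Writes the cohort, the dosage
# matrix and the truth sidecar (never read by later stages).

library(vitdmr)

seed <- as.integer(Sys.getenv("VITDMR_SEED", "42"))
dir.create("results", showWarnings = FALSE)

cfg <- default_config(n_subjects = 2013, seed = seed)
sim <- simulate_cohort(cfg)

write_cohort_tsv(sim$cohort, "results/cohort_enrolled.tsv")
write_dosage_tsv(sim$genotypes, "results/genotypes.tsv")
write_truth_tsv(sim$truth, "results/truth_sidecar.tsv")

cat(sprintf("Simulated %d subjects x %d SNPs (seed %d).\n",
            nrow(sim$cohort), ncol(sim$genotypes), seed))
cat(sprintf("Flagged for exclusion: %d disease/medication, %d abnormal-lab.\n",
            sum(sim$cohort$excl_disease_medication),
            sum(sim$cohort$excl_abnormal_lab)))
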