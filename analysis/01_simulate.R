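#!/usr/bin/env Rscript

# Stage 1: simulate the EMR-style cohort.
#
# The generator's defaults are calibrated to the reference inpatient
# osteoporosis cohort: 13,359 patients aged 50-101 (mean 69.9, SD 10.2),
# 80.2% female, the 16 common multimorbidities at their published
# prevalences, positive latent associations for hypertension-diabetes and
# hypertension-atherosclerosis, and a logistic emotional-distress (CSAD)
# model in sex, age, widowhood and multimorbidity count.

suppressPackageStartupMessages(library(comorbnet))

seed <- 101L
cfg <- default_config(seed = seed)
message("simulating cohort: n = ", cfg$n_patients, ", seed = ", seed)
cohort <- generate_cohort(cfg, seed = seed)

paths <- write_cohort(cohort, "results/cohort")
message("wrote ", paths[["patients"]], " and ", paths[["diagnoses"]])

realized <- colMeans(cohort$truth$present)
worst <- max(abs(realized - cfg$disease_specs$prevalence))
message(sprintf("realized prevalences within %.4f of targets", worst))
message(sprintf("CSAD rate: %.1f%%; mean multimorbidity count: %.2f",
                100 * mean(cohort$truth$csad),
                mean(rowSums(cohort$truth$present))))
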