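#!/usr/bin/env Rscript
# Stage 1: simulate the two virtual study cohorts.
#
# Builds a calibration-style cohort (n = 189, per-histology growth
# rates, 29% responders, uniform +/-0.1 burden noise) and a
# validation-style cohort (n = 64, per-patient alpha with pretreatment
# scans, 39% responders), then writes the burden-level CSVs, the
# lesion-level CSV for the validation cohort, truth tables and YAML
# metadata under results/.

suppressPackageStartupMessages(library(icikin))

seed <- 1L
dir.create("results", showWarnings = FALSE)

cal <- generate_cohort(cohort_config(189, responder_fraction = 0.29,
                                     noise = 0.1), seed)
val <- generate_cohort(cohort_config(64, responder_fraction = 0.39,
                                     noise = 0.1, style = "validation",
                                     lesions = TRUE), seed + 1L)

write_burden_csv(cal$cohort, "results/cohort_calibration.csv")
write_burden_csv(val$cohort, "results/cohort_validation.csv")
write_lesion_csv(val$lesions, "results/lesions_validation.csv")
utils::write.csv(cal$truth, "results/truth_calibration.csv",
                 row.names = FALSE)
utils::write.csv(val$truth, "results/truth_validation.csv",
                 row.names = FALSE)

for (g in list(cal, val)) {
  hist <- lapply(g$cohort$patients, `[[`, "histology")
  write_cohort_metadata(
    list(name = g$config$style, seed = g$seed, histology = hist),
    sprintf("results/metadata_%s.yaml", g$config$style))
}

cat(sprintf("calibration: %d patients, %.0f%% responders, %d-%d visits\n",
            length(cal$cohort), 100 * mean(cal$truth$responder),
            min(cal$truth$n_visits), max(cal$truth$n_visits)))
cat(sprintf("validation:  %d patients, %.0f%% responders, %d-%d lesions\n",
            length(val$cohort), 100 * mean(val$truth$responder),
            min(val$truth$lesion_count), max(val$truth$lesion_count)))
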