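#!/usr/bin/env Rscript
# Stage 3: stability of the fitted parameters.
#
# Three analyses on the calibration cohort: (i) refits on data
# truncated at t < 30/60/120/200 days with Spearman stability of
# Lambda and mu and the projected-label misclassification rate;
# (ii) refits after uniform +/-0.1 perturbation of the burdens;
# (iii) +/-10% parameter perturbation of each fit, evaluated at 200 d.
# Writes truncation.csv and sensitivity.csv.

suppressPackageStartupMessages(library(icikin))

seed <- 1L
cal <- read_burden_csv("results/cohort_calibration.csv",
                       read_cohort_metadata("results/metadata_calibration.yaml"))$cohort
# per-histology reference rates, as in stage 2's primary fits
ref <- calibration_growth_rates()
hist <- vapply(cal$patients, `[[`, character(1), "histology")
al <- setNames(ref$alpha[match(hist, ref$histology)],
               names(cal$patients))

ta <- truncation_analysis(cal, al, windows = c(30, 60, 120, 200))
utils::write.csv(cbind(ta$table, comparison = ta$comparison,
                       convention = ta$convention),
                 "results/truncation.csv", row.names = FALSE)
print(ta$table, digits = 3)

pd <- perturb_data_refit(cal, al, amplitude = 0.1, seed = seed + 10L,
                         fits = ta$full_fits)
pp <- vapply(ta$full_fits, function(f)
  as.numeric(perturb_parameters(f, 0.10, 200)), numeric(1))
sens <- data.frame(
  analysis = c("data_perturbation_spearman_lambda",
               "data_perturbation_spearman_mu",
               "median_abs_param_perturbation_delta_rho"),
  value = c(pd$spearman_lambda, pd$spearman_mu, median(pp)))
utils::write.csv(sens, "results/sensitivity.csv", row.names = FALSE)

cat(sprintf("\ndata perturbation: Spearman Lambda %.3f, mu %.3f\n",
            pd$spearman_lambda, pd$spearman_mu))
cat(sprintf("mu stays rank-stable at early windows while Lambda drifts:\n"))
cat(sprintf("  t<60: mu %.3f vs Lambda %.3f\n",
            ta$table$spearman_mu[ta$table$window == 60],
            ta$table$spearman_lambda[ta$table$window == 60]))
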