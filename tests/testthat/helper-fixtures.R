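# Shared fixtures: noise-free series generated straight from the
# closed-form model, and small utilities used across test files.

make_noiseless_series <- function(alpha, lam, mu, times, id = "p1") {
  m <- trajectory_model(model_parameters(alpha, lam, mu))
  patient_series(id, times, predict_burden(m, times))
}

rel_err <- function(est, tru) abs(est - tru) / pmax(abs(tru), 1e-12)

# standard small synthetic cohorts (fixed seeds, generated once per run)
noiseless_cohort_small <- function(n = 40, seed = 101)
  generate_cohort(cohort_config(n, noise = 0), seed)

truth_alphas <- function(g) stats::setNames(g$truth$alpha, g$truth$patient_id)
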