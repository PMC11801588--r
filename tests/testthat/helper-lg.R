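# small shared fixtures, built in code

# the 45 gastric-cancer survival times (phase-I reference data), 9 subgroups of 5
survival_mat <- function() lg_survival_data()
survival_vec <- function() as.numeric(t(lg_survival_data()))

# phase-II stream, 6 subgroups of 5
phase2_mat <- function() lg_phase2_data()

# parameter grid used by several property tests
param_grid <- expand.grid(theta = c(0.25, 0.5, 0.75, 2),
                          p = c(0, 0.25, 0.5, 0.75, 0.95))

# central finite-difference gradient of the log-likelihood
numeric_score <- function(x, theta, p, h = 1e-6) {
  c((lg_loglik(x, theta + h, p) - lg_loglik(x, theta - h, p)) / (2 * h),
    (lg_loglik(x, theta, p + h) - lg_loglik(x, theta, p - h)) / (2 * h))
}
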