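# paired tumor/normal beta-binomial generator on the logit scale, used by
# the regression and calibration tests
sim_bb_pairs <- function(n_pairs, trials, beta0 = 0, beta_cond = 0,
                         rho = 0.05, patient_sd = 0.3, seed = 1) {
  set.seed(seed)
  patient <- rep(sprintf("p%02d", seq_len(n_pairs)), each = 2)
  condition <- rep(c("normal", "tumor"), n_pairs)
  pat_eff <- rep(stats::rnorm(n_pairs, 0, patient_sd), each = 2)
  eta <- beta0 + beta_cond * (condition == "tumor") + pat_eff
  mu <- stats::plogis(eta)
  p <- if (rho > 0) stats::rbeta(length(mu), mu * (1 - rho) / rho,
                                 (1 - mu) * (1 - rho) / rho) else mu
  data.table::data.table(k = stats::rbinom(length(mu), trials, p),
                         n = trials, condition = condition,
                         patient_id = patient)
}

# one null-simulation LRT p-value through the package's testing route
bb_null_pvalue <- function(seed, n_pairs = 10, trials = 50, rho = 0.02,
                           beta0 = qlogis(0.4), patient_sd = 0.3,
                           beta_cond = 0) {
  d <- sim_bb_pairs(n_pairs, trials, beta0 = beta0, beta_cond = beta_cond,
                    rho = rho, patient_sd = patient_sd, seed = seed)
  rho_cr <- estimate_dispersion_cr(d$k, d$n, d$condition, d$patient_id)
  full <- fit_bb_regression(d$k, d$n, d$condition, d$patient_id,
                            rho = rho_cr)
  red <- fit_bb_regression(d$k, d$n, d$condition, d$patient_id,
                           with_condition = FALSE, rho = rho_cr)
  lrt_condition(full, red)$p_value
}
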