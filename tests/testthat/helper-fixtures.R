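# shared fixtures: realistic generating curves for each family (medians in
# the 9-23 month range typical of advanced-TNBC PFS/OS) and small helpers

recovery_truth <- list(
  exponential = list(lambda = 0.08,   gamma = NULL),
  weibull     = list(lambda = 0.06,   gamma = 1.3),
  gompertz    = list(lambda = 0.05,   gamma = 0.08),
  lognormal   = list(lambda = 0.045,  gamma = 0.9),
  loglogistic = list(lambda = 0.0432, gamma = 0.533)
)

make_params <- function(family, truth = recovery_truth[[family]]) {
  surv_params(family, truth$lambda, truth$gamma)
}

rel_err <- function(est, truth) abs(est / truth - 1)

# a 30%-administratively-censored sample of size n from a family
censored_sample <- function(family, n, seed = 1L, censor_frac = 0.30) {
  truth <- recovery_truth[[family]]
  pars <- make_params(family)
  simulate_ipd(sim_spec(family, truth$lambda, truth$gamma, n = n,
                        admin_censor_months = surv_quantile(pars, censor_frac),
                        seed = seed))
}

# KM survival of `ipd` evaluated at given times
km_at <- function(ipd, times) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  summary(fit, times = times, extend = TRUE)$surv
}
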