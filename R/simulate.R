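#' Specification for a synthetic right-censored survival dataset
#'
#' Describes a cohort whose event times follow one of the five parametric
#' families, with right-censoring from the earlier of an administrative
#' cutoff and exponential dropout. Defaults mimic the scale of a modern
#' phase-III metastatic breast-cancer trial arm; they are synthetic sizes,
#' not the source trial's (which are not printed in the parameter tables
#' this model is built from).
#'
#' @param family One of [SURV_FAMILIES].
#' @param lambda,gamma Curve parameters, see [surv_params()].
#' @param n Number of subjects.
#' @param admin_censor_months Administrative cutoff (months); `Inf` disables.
#' @param dropout_rate Per-month exponential dropout hazard; 0 disables.
#' @param seed Integer RNG seed; the simulation is fully reproducible.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(family, lambda, gamma = NULL, n = 300,
                     admin_censor_months = Inf, dropout_rate = 0, seed = 1L) {
  params <- surv_params(family, lambda, gamma %||% 1)
  if (n < 1) stop("`n` must be >= 1")
  if (admin_censor_months <= 0) stop("`admin_censor_months` must be > 0")
  if (dropout_rate < 0) stop("`dropout_rate` must be >= 0")
  structure(
    list(params = params, n = as.integer(n),
         admin_censor_months = admin_censor_months,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate right-censored individual patient data
#'
#' Event times are drawn by inverse-CDF from the family's closed-form
#' survival quantile ([surv_quantile()]); the censoring time is the minimum
#' of the administrative cutoff and an exponential dropout time. The record
#' is `(min(T, C), T <= C)`.
#'
#' @param spec A [sim_spec()].
#' @return Data frame with columns `time` (months) and `event` (0/1).
#' @examples
#' ipd <- simulate_ipd(sim_spec("exponential", lambda = 0.1, n = 500, seed = 7))
#' @export
simulate_ipd <- function(spec) {
  if (!inherits(spec, "sim_spec")) stop("`spec` must be a `sim_spec`")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  t_event <- surv_quantile(spec$params, stats::runif(spec$n))
  cens <- rep(spec$admin_censor_months, spec$n)
  if (spec$dropout_rate > 0) {
    cens <- pmin(cens, stats::rexp(spec$n, rate = spec$dropout_rate))
  }
  data.frame(
    time = pmin(t_event, cens),
    event = as.integer(t_event <= cens)
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Kaplan-Meier curve with number-at-risk table
#'
#' Product-limit estimate of a right-censored sample (via
#' [survival::survfit()]) packaged as the digitized-curve object the
#' pseudo-IPD reconstruction consumes: survival coordinates at `(0, 1)` and
#' every event time, plus the number at risk at requested times.
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @param risk_times Times (months) at which the number at risk is tabulated;
#'   must start at 0.
#' @return A [km_curve()] object.
#' @export
km_from_ipd <- function(ipd, risk_times) {
  ipd <- validate_ipd(ipd)
  if (nrow(ipd) == 0L) stop("`ipd` is empty")
  if (length(risk_times) < 1 || risk_times[1] != 0) {
    stop("`risk_times` must start at 0")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  drop_idx <- which(fit$n.event > 0)
  pts <- data.frame(
    time = c(0, fit$time[drop_idx]),
    survival = c(1, fit$surv[drop_idx])
  )
  sm <- summary(fit, times = risk_times, extend = TRUE)
  risk <- data.frame(time = sm$time, n_at_risk = sm$n.risk)
  km_curve(points = pts, risk_table = risk, total_events = sum(ipd$event))
}
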