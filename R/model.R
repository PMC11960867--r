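DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Cohort model configuration
#'
#' Structural settings of the three-state (progression-free / progressed /
#' dead) cohort model and the accrual conventions that the published inputs
#' leave open. The defaults are the shipped base case: 21-day cycles over a
#' 5-year horizon (87 cycles, the last truncated so the horizon ends at
#' exactly 60 months), 5% annual discounting, a $100,000/QALY
#' willingness-to-pay threshold, a 2-year treatment cap and a 35-week
#' post-progression subsequent-therapy window.
#'
#' The under-specified accrual details are exposed as calibration flags:
#' `counting` (whether state membership is valued at cycle start, cycle end,
#' or their average, i.e. a half-cycle correction),
#' `nabpac_admin_per_cycle` (nab-paclitaxel administrations per 21-day
#' cycle), `vial_rounding` (round each administration up to whole 100-mg
#' vials) and `monitor_every_n_cycles` (cadence of CT + tumor imaging;
#' laboratory testing is charged every cycle). Their defaults are the
#' combination under which the model best reproduces the published
#' base-case table; see the methods vignette.
#'
#' @param cycle_days Markov cycle length in days.
#' @param horizon_years Model horizon in years.
#' @param discount_rate_annual Annual discount rate for costs and outcomes.
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param treatment_cap_years First-line treatment duration cap in years.
#' @param subsequent_therapy_weeks Maximum subsequent-therapy duration after
#'   progression, in weeks.
#' @param counting `"start"`, `"end"` or `"half"` cycle counting.
#' @param nabpac_admin_per_cycle nab-paclitaxel administrations per cycle.
#' @param vial_rounding Round each nab-paclitaxel dose up to whole vials?
#' @param monitor_every_n_cycles CT/imaging restaging cadence in cycles.
#' @return A `model_config` list with derived fields `n_cycles`,
#'   `cycle_months` and `horizon_months`.
#' @export
model_config <- function(cycle_days = 21,
                         horizon_years = 5,
                         discount_rate_annual = 0.05,
                         wtp_per_qaly = 1e5,
                         treatment_cap_years = 2,
                         subsequent_therapy_weeks = 35,
                         counting = c("start", "end", "half"),
                         nabpac_admin_per_cycle = 3,
                         vial_rounding = TRUE,
                         monitor_every_n_cycles = 1) {
  counting <- match.arg(counting)
  stopifnot(cycle_days > 0, horizon_years > 0, discount_rate_annual >= 0,
            wtp_per_qaly > 0, treatment_cap_years > 0,
            subsequent_therapy_weeks >= 0, nabpac_admin_per_cycle >= 1,
            monitor_every_n_cycles >= 1)
  structure(
    list(
      cycle_days = cycle_days,
      horizon_years = horizon_years,
      discount_rate_annual = discount_rate_annual,
      wtp_per_qaly = wtp_per_qaly,
      treatment_cap_years = treatment_cap_years,
      subsequent_therapy_weeks = subsequent_therapy_weeks,
      counting = counting,
      nabpac_admin_per_cycle = nabpac_admin_per_cycle,
      vial_rounding = vial_rounding,
      monitor_every_n_cycles = monitor_every_n_cycles,
      n_cycles = as.integer(ceiling(horizon_years * DAYS_PER_YEAR / cycle_days)),
      cycle_months = cycle_days / DAYS_PER_MONTH,
      horizon_months = horizon_years * 12
    ),
    class = "model_config"
  )
}

stopifnot_config <- function(config) {
  if (!inherits(config, "model_config")) stop("`config` must be a `model_config`")
  invisible(config)
}

# cycle boundary times in months, the final cycle truncated to the horizon
cycle_boundaries <- function(config) {
  pmin(0:config$n_cycles * config$cycle_months, config$horizon_months)
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of leaving the curve's state during cycle `cycle_index`
#' (0-based), conditional on being in it at the cycle start:
#' `1 - S((t+1) u) / S(t u)` with `u` the cycle length in months. When the
#' survivor function has already vanished the state is absorbing and the
#' probability is 1.
#'
#' @param params A [surv_params()] curve.
#' @param cycle_index 0-based cycle index (vectorized).
#' @param config A [model_config()].
#' @return Probabilities in `[0, 1]`.
#' @export
transition_probability <- function(params, cycle_index, config) {
  stopifnot_config(config)
  if (any(cycle_index < 0)) stop("`cycle_index` must be >= 0")
  u <- config$cycle_months
  s0 <- surv_prob(params, cycle_index * u)
  s1 <- surv_prob(params, (cycle_index + 1) * u)
  ifelse(s0 <= 0, 1, pmin(1, pmax(0, 1 - s1 / s0)))
}

#' Run the three-state cohort trace
#'
#' Computes per-cycle state occupancy by partitioned survival: the
#' progression-free occupancy is `S_pfs(t)`, the dead compartment is
#' `1 - S_os(t)` and progressed disease is the difference. Incident deaths
#' are the per-cycle increments of the dead compartment; incident
#' progressions are the PFS outflow net of the share of deaths apportioned
#' to PFS by previous-cycle occupancy. Occupancy of the progressed state is
#' additionally book-kept in a tunnel indexed by cycles since progression
#' (needed to cap subsequent-therapy costs), with attrition applied
#' proportionally across tunnel positions.
#'
#' @param pfs,os [surv_params()] curves for progression-free and overall
#'   survival of one arm. They must satisfy `S_pfs <= S_os + 0.02` at every
#'   cycle boundary (small digitization-induced crossings are clamped).
#' @param config A [model_config()].
#' @return A `cohort_trace`: data frame with one row per cycle boundary
#'   (`cycle` 0..n) and columns `time_months, pfs, pd, dead, new_prog,
#'   new_death`, with the tunnel occupancy matrix in `attr(, "tunnel")`
#'   (rows = cycle boundaries, columns = cycles since progression).
#' @export
run_trace <- function(pfs, os, config) {
  stopifnot_params(pfs); stopifnot_params(os); stopifnot_config(config)
  tb <- cycle_boundaries(config)
  n <- config$n_cycles
  Sp <- surv_prob(pfs, tb)
  So <- surv_prob(os, tb)
  cross <- which(Sp > So + 0.02)
  if (length(cross)) {
    stop(sprintf(
      "model-inconsistency error: PFS exceeds OS by more than 0.02 at cycle %d (t = %.2f months)",
      cross[1] - 1L, tb[cross[1]]))
  }
  pfs_occ <- pmin(Sp, So)         # clamp digitization slack to conserve mass
  dead <- 1 - So
  pd <- So - pfs_occ

  new_death <- c(0, diff(dead))
  alive_prev <- c(1, So[1:n])
  pfs_prev <- c(1, pfs_occ[1:n])
  pfs_share <- ifelse(alive_prev > 0, pfs_prev / alive_prev, 0)
  new_prog <- pmax(0, c(0, -diff(pfs_occ)) - new_death * pfs_share)
  new_prog[new_prog < 1e-14] <- 0  # floating-point dust from the subtraction

  tunnel <- matrix(0, nrow = n + 1, ncol = n + 1,
                   dimnames = list(cycle = 0:n, age = 0:n))
  for (i in seq_len(n)) {
    prev <- tunnel[i, ]
    entry <- min(new_prog[i + 1], pd[i + 1])
    aged_total <- pd[i + 1] - entry
    prev_total <- sum(prev)
    aged <- if (prev_total > 0) {
      c(0, prev[1:n]) * (aged_total / prev_total)
    } else {
      rep(0, n + 1)
    }
    aged[1] <- aged[1] + entry
    if (prev_total == 0 && aged_total > 0) aged[1] <- aged[1] + aged_total
    tunnel[i + 1, ] <- aged
  }

  out <- data.frame(
    cycle = 0:n, time_months = tb,
    pfs = pfs_occ, pd = pd, dead = dead,
    new_prog = new_prog, new_death = new_death
  )
  structure(out, tunnel = tunnel, config = config, class = c("cohort_trace", "data.frame"))
}

#' Export a cohort trace as CSV
#'
#' Columns `cycle,pfs,pd,dead,new_prog,new_death`.
#'
#' @param trace A [run_trace()] result.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(cycle = trace$cycle, pfs = trace$pfs, pd = trace$pd,
               dead = trace$dead, new_prog = trace$new_prog,
               new_death = trace$new_death),
    path, row.names = FALSE
  )
  invisible(path)
}
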