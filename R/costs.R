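# Canonical economic parameter table: base value, range and distribution
# family for every cost (2022 USD), utility and grade >= 3 adverse-event
# input of the model. Ranges are the published ones (mostly +/- 20-25%;
# neutropenia management cost and the PD-state utility have asymmetric
# printed ranges).
econ_param_table <- function() {
  tab <- rbind(
    data.frame(name = "cost_toripalimab_cycle", base = 8892.03, low = 7113.62, high = 10670.44, dist = "gamma"),
    data.frame(name = "cost_nabpac_100mg",      base = 1447.14, low = 1157.71, high = 1736.57,  dist = "gamma"),
    data.frame(name = "cost_subsequent_cycle",  base = 6533.66, low = 5226.93, high = 7840.40,  dist = "gamma"),
    data.frame(name = "cost_lab",               base = 16.36,   low = 13.09,   high = 19.63,    dist = "gamma"),
    data.frame(name = "cost_ct",                base = 152.62,  low = 122.09,  high = 183.14,   dist = "gamma"),
    data.frame(name = "cost_imaging",           base = 105,     low = 84,      high = 126,      dist = "gamma"),
    data.frame(name = "cost_terminal",          base = 85904,   low = 68723,   high = 103085,   dist = "gamma"),
    data.frame(name = "cost_carboplatin_mg",    base = 0.06,    low = 0.04,    high = 0.07,     dist = "gamma"),
    data.frame(name = "cost_gemcitabine_mg",    base = 0.02,    low = 0.02,    high = 0.03,     dist = "gamma"),
    data.frame(name = "bsa",                    base = 1.84,    low = 1.78,    high = 1.90,     dist = "normal"),
    data.frame(name = "cost_leukopenia",        base = 57.21,   low = 45.76,   high = 68.65,    dist = "gamma"),
    data.frame(name = "cost_neutropenia",       base = 24376,   low = 12188,   high = 49913,    dist = "gamma"),
    data.frame(name = "u_pfs",                  base = 0.76,    low = 0.61,    high = 0.91,     dist = "beta"),
    data.frame(name = "u_pd",                   base = 0.55,    low = 0.36,    high = 0.55,     dist = "beta"),
    data.frame(name = "disutil_leukopenia",     base = 0.09,    low = 0.07,    high = 0.10,     dist = "beta"),
    data.frame(name = "disutil_neutropenia",    base = 0.10,    low = 0.09,    high = 0.11,     dist = "beta"),
    data.frame(name = "inc_leukopenia_combo",   base = 0.25,    low = 0.20,    high = 0.30,     dist = "beta"),
    data.frame(name = "inc_neutropenia_combo",  base = 0.26,    low = 0.21,    high = 0.31,     dist = "beta"),
    data.frame(name = "inc_leukopenia_placebo", base = 0.23,    low = 0.18,    high = 0.28,     dist = "beta"),
    data.frame(name = "inc_neutropenia_placebo", base = 0.28,   low = 0.22,    high = 0.34,     dist = "beta")
  )
  rownames(tab) <- tab$name
  tab
}

#' Economic model inputs
#'
#' All cost, utility and adverse-event inputs of the model with their
#' published base values. Any value can be overridden by name; each input
#' also carries its published (low, high) range and sampling distribution
#' family, used by the one-way and probabilistic sensitivity analyses and
#' available through `attr(x, "param_table")`.
#'
#' Costs are USD: `cost_toripalimab_cycle` per 240-mg dose (one per cycle),
#' `cost_nabpac_100mg` per 100-mg vial, `cost_subsequent_cycle` per cycle of
#' post-progression therapy, `cost_lab`/`cost_ct`/`cost_imaging` per
#' monitoring item, `cost_terminal` once per death,
#' `cost_leukopenia`/`cost_neutropenia` per managed grade >= 3 episode, and
#' carboplatin/gemcitabine unit prices per mg (inputs to the
#' subsequent-therapy costing, retained for sensitivity analysis; the base
#' case uses the published aggregate per-cycle subsequent cost). `bsa` is
#' body surface area in m^2; `u_pfs`/`u_pd` are state utilities;
#' `disutil_*` are per-episode utility decrements applied for one cycle;
#' `inc_*` are per-arm adverse-event incidences.
#'
#' @param ... Named overrides of any parameter in the table.
#' @return An `econ_inputs` list.
#' @examples
#' econ_inputs(cost_toripalimab_cycle = 0) # price-negotiation scenario
#' @export
econ_inputs <- function(...) {
  tab <- econ_param_table()
  vals <- as.list(stats::setNames(tab$base, tab$name))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), tab$name)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    for (nm in names(dots)) vals[[nm]] <- as.numeric(dots[[nm]])
  }
  validate_econ_inputs(vals)
  structure(vals, param_table = tab, class = "econ_inputs")
}

validate_econ_inputs <- function(vals) {
  costs <- grep("^cost_", names(vals), value = TRUE)
  for (nm in costs) {
    if (!is.finite(vals[[nm]]) || vals[[nm]] < 0) stop("`", nm, "` must be a non-negative cost")
  }
  for (nm in grep("^(u_|disutil_|inc_)", names(vals), value = TRUE)) {
    if (!is.finite(vals[[nm]]) || vals[[nm]] < 0 || vals[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]")
    }
  }
  if (!is.finite(vals$bsa) || vals$bsa <= 0) stop("`bsa` must be positive")
  invisible(vals)
}

stopifnot_inputs <- function(inputs) {
  if (!inherits(inputs, "econ_inputs")) stop("`inputs` must be an `econ_inputs` object")
  invisible(inputs)
}

check_arm <- function(arm) {
  if (!is.character(arm) || length(arm) != 1L || !arm %in% c("combo", "placebo")) {
    stop("`arm` must be \"combo\" or \"placebo\"")
  }
  arm
}

# nab-paclitaxel cost of one administration (125 mg/m^2), optionally rounded
# up to whole 100-mg vials (wastage included)
nabpac_admin_cost <- function(inputs, config) {
  mg <- 125 * inputs$bsa
  if (config$vial_rounding) {
    ceiling(mg / 100) * inputs$cost_nabpac_100mg
  } else {
    mg / 100 * inputs$cost_nabpac_100mg
  }
}

#' Per-cycle first-line drug acquisition cost
#'
#' While on treatment (cycle start before the treatment cap) the combination
#' arm pays one 240-mg toripalimab dose plus the nab-paclitaxel
#' administrations of the cycle; the control arm pays nab-paclitaxel only.
#' Zero after the cap.
#'
#' @param arm `"combo"` or `"placebo"`.
#' @param cycle_index 0-based cycle index.
#' @param inputs An [econ_inputs()].
#' @param config A [model_config()].
#' @return Cost in USD for one cohort member in the progression-free state.
#' @export
drug_cost_cycle <- function(arm, cycle_index, inputs, config) {
  check_arm(arm); stopifnot_inputs(inputs); stopifnot_config(config)
  if (any(cycle_index < 0) || any(cycle_index >= config$n_cycles)) {
    stop("`cycle_index` must lie within the model horizon")
  }
  on_trt <- cycle_index * config$cycle_days < config$treatment_cap_years * DAYS_PER_YEAR
  nabp <- nabpac_admin_cost(inputs, config) * config$nabpac_admin_per_cycle
  per_cycle <- if (arm == "combo") inputs$cost_toripalimab_cycle + nabp else nabp
  ifelse(on_trt, per_cycle, 0)
}

#' First-cycle adverse-event burden
#'
#' All grade >= 3 adverse-event costs and disutilities are charged once, in
#' the first cycle: cost `sum(incidence * episode cost)` and QALY decrement
#' `sum(incidence * disutility) * cycle length in years`.
#'
#' @inheritParams drug_cost_cycle
#' @return List with elements `cost` (USD) and `qaly_loss` (QALYs).
#' @export
ae_burden_first_cycle <- function(arm, inputs, config) {
  check_arm(arm); stopifnot_inputs(inputs); stopifnot_config(config)
  inc <- if (arm == "combo") {
    c(inputs$inc_leukopenia_combo, inputs$inc_neutropenia_combo)
  } else {
    c(inputs$inc_leukopenia_placebo, inputs$inc_neutropenia_placebo)
  }
  list(
    cost = sum(inc * c(inputs$cost_leukopenia, inputs$cost_neutropenia)),
    qaly_loss = sum(inc * c(inputs$disutil_leukopenia, inputs$disutil_neutropenia)) *
      config$cycle_days / DAYS_PER_YEAR
  )
}

#' Per-cycle discount factor
#'
#' `(1 + r)^(-t * cycle_days / 365.25)` for 0-based cycle index `t` —
#' continuous-in-cycles compounding of the annual rate.
#'
#' @param cycle_index 0-based cycle index (vectorized).
#' @param config A [model_config()].
#' @return Discount factors in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, config) {
  stopifnot_config(config)
  if (any(cycle_index < 0)) stop("`cycle_index` must be >= 0")
  (1 + config$discount_rate_annual)^(-cycle_index * config$cycle_days / DAYS_PER_YEAR)
}

# subsequent-therapy tunnel weights: full cost for tunnel ages covering the
# first 35 weeks after progression (11 full cycles), the 12th prorated 2/3
subsequent_weights <- function(config) {
  win <- config$subsequent_therapy_weeks * 7 / config$cycle_days
  full <- floor(win)
  w <- numeric(config$n_cycles + 1)
  w[seq_len(min(full, length(w)))] <- 1
  if (full + 1 <= length(w)) w[full + 1] <- win - full
  w
}

#' Accrue discounted costs, life years and QALYs over a cohort trace
#'
#' Per cycle: drug acquisition cost on progression-free occupancy while on
#' treatment; laboratory monitoring on alive occupancy every cycle and
#' CT + tumor imaging at the restaging cadence; subsequent-therapy cost on
#' progressed occupancy within 35 weeks of progression (tunnel-weighted,
#' final cycle prorated); terminal care on incident deaths; the
#' adverse-event burden once in the first cycle. QALYs weight occupancy by
#' the state utilities. Everything is multiplied by the cycle's discount
#' factor; life years are discounted alive-occupancy time. State membership
#' is valued at cycle start, end, or mid according to `config$counting`,
#' and the truncated final cycle contributes proportionally less time.
#'
#' @param trace A [run_trace()] result.
#' @param arm `"combo"` or `"placebo"`.
#' @param inputs An [econ_inputs()].
#' @param config The [model_config()] the trace was built with.
#' @return An `accrual` list: `total_cost`, `ly`, `qaly`, `arm` and a
#'   `components` breakdown (drug, subsequent, monitoring, terminal,
#'   adverse-event cost).
#' @export
accrue <- function(trace, arm, inputs, config) {
  check_arm(arm); stopifnot_inputs(inputs); stopifnot_config(config)
  if (!inherits(trace, "cohort_trace")) stop("`trace` must be a `cohort_trace`")
  n <- config$n_cycles
  if (nrow(trace) != n + 1L) stop("trace/config cycle-count mismatch")

  occ <- function(x) switch(config$counting,
    start = x[1:n], end = x[2:(n + 1)], half = (x[1:n] + x[2:(n + 1)]) / 2)
  ci <- 0:(n - 1)
  d <- discount_factor(ci, config)
  dt_months <- diff(trace$time_months)          # truncated final cycle
  dt_years <- dt_months / 12
  cycle_frac <- dt_months / config$cycle_months # 1 except the last cycle

  pfs_o <- occ(trace$pfs); pd_o <- occ(trace$pd)
  alive_o <- pfs_o + pd_o
  new_death <- trace$new_death[2:(n + 1)]

  tunnel <- attr(trace, "tunnel")
  w <- subsequent_weights(config)
  sub_b <- as.numeric(tunnel %*% w)             # weighted occupancy at boundaries
  sub_o <- occ(sub_b)

  drug <- sum(d * drug_cost_cycle(arm, ci, inputs, config) * pfs_o)
  subsequent <- sum(d * inputs$cost_subsequent_cycle * sub_o)
  monitoring <- sum(d * alive_o *
                      (inputs$cost_lab +
                         (inputs$cost_ct + inputs$cost_imaging) *
                         (ci %% config$monitor_every_n_cycles == 0)))
  terminal <- sum(d * inputs$cost_terminal * new_death)
  ae <- ae_burden_first_cycle(arm, inputs, config)

  ly <- sum(d * alive_o * dt_years)
  qaly <- sum(d * (inputs$u_pfs * pfs_o + inputs$u_pd * pd_o) * dt_years) - ae$qaly_loss

  structure(
    list(
      arm = arm,
      total_cost = drug + subsequent + monitoring + terminal + ae$cost,
      ly = ly, qaly = qaly,
      components = c(drug = drug, subsequent = subsequent,
                     monitoring = monitoring, terminal = terminal,
                     adverse_events = ae$cost)
    ),
    class = "accrual"
  )
}

#' @export
print.accrual <- function(x, ...) {
  cat(sprintf("<accrual> %s arm: cost $%s, %.3f LY, %.3f QALY\n",
              x$arm, format(round(x$total_cost, 2), big.mark = ","), x$ly, x$qaly))
  invisible(x)
}
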