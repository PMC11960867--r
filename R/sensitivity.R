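#' One-way sensitivity of the ICER to a single parameter
#'
#' Reruns the full base case with the named economic parameter set to its
#' published low and high bound, everything else fixed, and reports both
#' ICERs and their absolute spread (the tornado bar width).
#'
#' @param param_name A parameter of [econ_inputs()].
#' @param inputs Base-case [econ_inputs()].
#' @param config A [model_config()].
#' @param survival Curve set, see [default_survival()].
#' @return One-row data.frame `parameter, low, high, low_icer, high_icer,
#'   spread`.
#' @export
one_way <- function(param_name, inputs = econ_inputs(),
                    config = model_config(), survival = default_survival()) {
  stopifnot_inputs(inputs)
  tab <- attr(inputs, "param_table")
  if (!param_name %in% tab$name) stop("unknown parameter: ", param_name)
  rng <- tab[param_name, ]
  icer_at <- function(v) {
    mod <- inputs
    mod[[param_name]] <- v
    run_base_case(survival, mod, config)$icer
  }
  lo <- icer_at(rng$low); hi <- icer_at(rng$high)
  data.frame(parameter = param_name, low = rng$low, high = rng$high,
             low_icer = lo, high_icer = hi, spread = abs(hi - lo))
}

#' One-way (tornado) sensitivity analysis over all parameters
#'
#' Applies [one_way()] to every parameter in the economic input table and
#' returns the results sorted by decreasing ICER spread.
#'
#' @inheritParams one_way
#' @return Data frame as in [one_way()], one row per parameter, sorted by
#'   `spread`.
#' @export
owsa <- function(inputs = econ_inputs(), config = model_config(),
                 survival = default_survival()) {
  stopifnot_inputs(inputs)
  tab <- attr(inputs, "param_table")
  out <- do.call(rbind, lapply(tab$name, one_way,
                               inputs = inputs, config = config,
                               survival = survival))
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Method-of-moments sampler for a sensitivity distribution
#'
#' Builds a sampling function with mean equal to the base value and standard
#' deviation `(high - low) / 3.92`, i.e. the published range read as a 95%
#' interval. Gamma: `shape = mean^2/sd^2`, `scale = sd^2/mean`; beta:
#' `alpha = mean * nu`, `beta = (1 - mean) * nu` with `nu` solved from the
#' variance; normal: `(mean, sd)`. The sampler draws from R's RNG stream,
#' so it is reproducible under `set.seed()`.
#'
#' @param base Base value (distribution mean).
#' @param low,high Range bounds, `low <= base <= high`, `low < high`.
#' @param family `"gamma"`, `"beta"` or `"normal"`.
#' @return `function(n)` returning `n` draws.
#' @export
build_distribution <- function(base, low, high, family = c("gamma", "beta", "normal")) {
  family <- match.arg(family)
  if (low > base || base > high) stop("need low <= base <= high")
  sd <- (high - low) / 3.92
  if (sd <= 0) stop("zero-width range gives sd <= 0; no distribution can be built")
  switch(family,
    gamma = {
      if (base <= 0) stop("gamma requires a positive mean")
      shape <- base^2 / sd^2; scale <- sd^2 / base
      function(n) stats::rgamma(n, shape = shape, scale = scale)
    },
    beta = {
      if (base <= 0 || base >= 1) stop("beta requires mean in (0, 1)")
      v <- sd^2
      if (v >= base * (1 - base)) stop("variance too large for a beta distribution")
      nu <- base * (1 - base) / v - 1
      function(n) stats::rbeta(n, shape1 = base * nu, shape2 = (1 - base) * nu)
    },
    normal = function(n) stats::rnorm(n, mean = base, sd = sd)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Each iteration draws every economic parameter from its published
#' distribution (survival parameters stay fixed at base values, as their
#' published ranges are not reported), reruns both arms and records the
#' incremental cost and QALYs. The cohort traces do not depend on the
#' economic draws and are computed once. A cost-effectiveness acceptability
#' curve is tabulated over a WTP grid as the fraction of draws with
#' non-negative incremental net monetary benefit.
#'
#' @param inputs Base-case [econ_inputs()].
#' @param config A [model_config()].
#' @param survival Curve set.
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Integer seed; the full run is reproducible.
#' @param wtp_grid WTP grid (USD/QALY) for the acceptability curve.
#' @return A `psa_result` list: `draws` (one row per iteration: sampled
#'   parameters, `delta_cost`, `delta_qaly`), `ceac` (`wtp, prob_combo_ce,
#'   prob_placebo_ce`), `n_failed` (failed iterations, excluded), `means`.
#' @export
psa <- function(inputs = econ_inputs(), config = model_config(),
                survival = default_survival(), n_iter = 2000, seed = 1L,
                wtp_grid = seq(0, 1.2e6, by = 1e4)) {
  stopifnot_inputs(inputs); stopifnot_config(config)
  if (n_iter < 1) stop("`n_iter` must be >= 1")
  tab <- attr(inputs, "param_table")
  validate_survival_set(survival)
  traces <- lapply(list(combo = "combo", placebo = "placebo"), function(a) {
    run_trace(survival[[a]]$pfs, survival[[a]]$os, config)
  })

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  samplers <- lapply(seq_len(nrow(tab)), function(i) {
    build_distribution(tab$base[i], tab$low[i], tab$high[i], tab$dist[i])
  })
  names(samplers) <- tab$name
  draw_mat <- vapply(samplers, function(s) s(n_iter), numeric(n_iter))
  if (n_iter == 1L) draw_mat <- matrix(draw_mat, nrow = 1, dimnames = list(NULL, tab$name))

  dc <- dq <- rep(NA_real_, n_iter)
  n_failed <- 0L
  for (i in seq_len(n_iter)) {
    res <- tryCatch({
      mod <- inputs
      for (nm in tab$name) mod[[nm]] <- draw_mat[i, nm]
      co <- accrue(traces$combo, "combo", mod, config)
      pl <- accrue(traces$placebo, "placebo", mod, config)
      c(co$total_cost - pl$total_cost, co$qaly - pl$qaly)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else { dc[i] <- res[1]; dq[i] <- res[2] }
  }
  ok <- !is.na(dc)
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_combo_ce = vapply(wtp_grid, function(w) mean(w * dq[ok] - dc[ok] >= 0), numeric(1))
  )
  ceac$prob_placebo_ce <- 1 - ceac$prob_combo_ce
  structure(
    list(
      draws = cbind(as.data.frame(draw_mat), delta_cost = dc, delta_qaly = dq)[ok, , drop = FALSE],
      ceac = ceac, n_failed = n_failed, seed = seed, n_iter = n_iter,
      means = c(delta_cost = mean(dc[ok]), delta_qaly = mean(dq[ok]))
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  at <- function(w) x$ceac$prob_combo_ce[which.min(abs(x$ceac$wtp - w))]
  cat(sprintf("<psa_result> %d iterations (%d failed): mean dC $%s, mean dQ %.4f\n",
              x$n_iter, x$n_failed,
              format(round(x$means[["delta_cost"]]), big.mark = ","),
              x$means[["delta_qaly"]]))
  cat(sprintf("  P(combination cost-effective) = %.3f at $100,000/QALY\n", at(1e5)))
  invisible(x)
}
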