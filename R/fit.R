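#' Akaike information criterion
#'
#' `AIC = 2k - 2 loglik`, with `k` the number of free parameters (1 for the
#' exponential family, 2 otherwise).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters, `k >= 1`.
#' @return The AIC value.
#' @examples
#' aic(-180.9583, 2) # 365.9166
#' @export
aic <- function(loglik, k) {
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1")
  2 * k - 2 * loglik
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop("`ipd` must be a data.frame with columns `time` and `event`")
  }
  if (any(!is.finite(ipd$time)) || any(ipd$time < 0)) {
    stop("`ipd$time` must be non-negative and finite (months)")
  }
  ev <- ipd$event
  if (is.logical(ev)) ev <- as.integer(ev)
  if (!all(ev %in% c(0L, 1L))) stop("`ipd$event` must be 0/1 or logical")
  data.frame(time = as.numeric(ipd$time), event = as.integer(ev))
}

# flexsurv distribution names and the map from its natural parameters to the
# (lambda, gamma) rate/shape convention used throughout this package.
flexsurv_dist <- function(family) {
  switch(family,
    weibull     = "weibull",
    gompertz    = "gompertz",
    lognormal   = "lnorm",
    loglogistic = "llogis",
    stop("no flexsurv mapping for family '", family, "'")
  )
}

flexsurv_to_params <- function(family, est) {
  switch(family,
    weibull     = c(lambda = 1 / est[["scale"]],      gamma = est[["shape"]]),
    gompertz    = c(lambda = est[["rate"]],           gamma = est[["shape"]]),
    lognormal   = c(lambda = exp(-est[["meanlog"]]),  gamma = 1 / est[["sdlog"]]),
    loglogistic = c(lambda = 1 / est[["scale"]],      gamma = est[["shape"]])
  )
}

#' Fit an accelerated-failure-time family to right-censored data
#'
#' Maximizes the censored log-likelihood `sum[events] log f(t) +
#' sum[censored] log S(t)`. The exponential rate has the closed-form MLE
#' `events / total exposure`, used directly; the two-parameter families are
#' fitted with [flexsurv::flexsurvreg()] and the estimates mapped onto the
#' package's rate/shape convention. The fit is deterministic given the data.
#'
#' @param ipd Data frame with columns `time` (months) and `event` (0/1 or
#'   logical; 1 = event observed, 0 = right-censored).
#' @param family One of [SURV_FAMILIES].
#' @return An `aft_fit` list with elements `params` ([surv_params()]),
#'   `loglik`, `aic`, `n`, `n_events`, `k`.
#' @examples
#' ipd <- data.frame(time = c(1, 3, 2), event = c(1, 1, 0))
#' fit_aft(ipd, "exponential")$params$lambda # 2 events / 6 months = 1/3
#' @export
fit_aft <- function(ipd, family) {
  family <- match.arg(family, SURV_FAMILIES)
  ipd <- validate_ipd(ipd)
  n <- nrow(ipd)
  d <- sum(ipd$event)
  if (n < 2L) stop("need at least 2 records to fit")
  if (d < 1L) stop("degenerate data: no events observed")
  if (any(ipd$time <= 0 & ipd$event == 1L)) {
    stop("event times must be strictly positive")
  }

  if (family == "exponential") {
    exposure <- sum(ipd$time)
    lambda <- d / exposure
    loglik <- d * log(lambda) - lambda * exposure
    params <- surv_params("exponential", lambda)
    k <- 1L
  } else {
    fs <- flexsurv::flexsurvreg(
      survival::Surv(time, event) ~ 1,
      data = ipd, dist = flexsurv_dist(family)
    )
    est <- fs$res[, "est"]
    pg <- flexsurv_to_params(family, est)
    if (family == "gompertz" && pg[["gamma"]] <= 0) {
      stop("Gompertz fit returned a non-positive shape (improper survival); ",
           "this family is rejected for these data")
    }
    params <- surv_params(family, pg[["lambda"]], pg[["gamma"]])
    loglik <- fs$loglik
    k <- 2L
  }
  structure(
    list(params = params, loglik = loglik, aic = aic(loglik, k),
         n = n, n_events = d, k = k),
    class = "aft_fit"
  )
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("<aft_fit> %s: lambda = %.5g, gamma = %.5g | loglik = %.4f, AIC = %.4f (n = %d, events = %d)\n",
              x$params$family, x$params$lambda, x$params$gamma,
              x$loglik, x$aic, x$n, x$n_events))
  invisible(x)
}

#' Fit and rank all five survival families by AIC
#'
#' Fits each family in [SURV_FAMILIES] to the same data and returns a table
#' sorted ascending by AIC (ties broken by the canonical family order). A
#' family whose fit fails is kept in the table with `NA` estimates and the
#' error message, rather than aborting the comparison.
#'
#' @inheritParams fit_aft
#' @return A data.frame with columns `family, lambda, gamma, loglik, aic, n,
#'   n_events, error`, plus the fitted `aft_fit` objects in
#'   `attr(, "fits")`.
#' @export
compare_families <- function(ipd) {
  ipd <- validate_ipd(ipd)
  if (nrow(ipd) == 0L) stop("`ipd` is empty")
  fits <- lapply(SURV_FAMILIES, function(fam) {
    tryCatch(fit_aft(ipd, fam), error = function(e) conditionMessage(e))
  })
  names(fits) <- SURV_FAMILIES
  row1 <- function(fam, f) {
    if (is.character(f)) {
      data.frame(family = fam, lambda = NA_real_, gamma = NA_real_,
                 loglik = NA_real_, aic = NA_real_,
                 n = nrow(ipd), n_events = sum(ipd$event), error = f)
    } else {
      data.frame(family = fam, lambda = f$params$lambda, gamma = f$params$gamma,
                 loglik = f$loglik, aic = f$aic, n = f$n, n_events = f$n_events,
                 error = NA_character_)
    }
  }
  tab <- do.call(rbind, Map(row1, SURV_FAMILIES, fits))
  ord <- order(tab$aic, match(tab$family, SURV_FAMILIES), na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Read / write individual patient data CSV
#'
#' IPD files have the header `time_months,event` with `event` coded 0/1.
#'
#' @param path File path.
#' @return `read_ipd()` returns a data.frame with columns `time`, `event`.
#' @export
read_ipd <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_months", "event") %in% names(x))) {
    stop("IPD CSV must have columns `time_months,event`")
  }
  validate_ipd(data.frame(time = x$time_months, event = x$event))
}

#' @rdname read_ipd
#' @param ipd Data frame with columns `time`, `event`.
#' @export
write_ipd <- function(ipd, path) {
  ipd <- validate_ipd(ipd)
  utils::write.csv(
    data.frame(time_months = ipd$time, event = ipd$event),
    path, row.names = FALSE
  )
  invisible(path)
}
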