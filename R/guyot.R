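#' Digitized Kaplan-Meier curve with number-at-risk table
#'
#' Container for the inputs of the pseudo-IPD reconstruction: the digitized
#' survival coordinates of a published KM curve and the numbers at risk
#' printed beneath it. Coordinates must start at `(0, 1)`, be strictly
#' increasing in time and non-increasing in survival; the at-risk counts
#' must be non-increasing.
#'
#' @param points Data frame with columns `time` (months) and `survival`.
#' @param risk_table Data frame with columns `time` (months) and `n_at_risk`.
#' @param total_events Optional total number of events reported for the curve.
#' @return A `km_curve` object.
#' @export
km_curve <- function(points, risk_table, total_events = NULL) {
  if (!is.data.frame(points) || !all(c("time", "survival") %in% names(points))) {
    stop("`points` must have columns `time` and `survival`")
  }
  if (!is.data.frame(risk_table) || !all(c("time", "n_at_risk") %in% names(risk_table))) {
    stop("`risk_table` must have columns `time` and `n_at_risk`")
  }
  points <- data.frame(time = as.numeric(points$time),
                       survival = as.numeric(points$survival))
  risk_table <- data.frame(time = as.numeric(risk_table$time),
                           n_at_risk = as.integer(risk_table$n_at_risk))
  if (nrow(points) < 1 || points$time[1] != 0 || points$survival[1] != 1) {
    stop("`points` must start at (time = 0, survival = 1)")
  }
  if (any(diff(points$time) <= 0)) stop("`points$time` must be strictly increasing")
  if (any(points$survival < 0 | points$survival > 1)) {
    stop("survival values must lie in [0, 1]")
  }
  if (any(diff(points$survival) > 0)) {
    stop("monotonicity error: survival values increase along the curve")
  }
  if (any(diff(risk_table$time) <= 0)) {
    stop("`risk_table$time` must be strictly increasing")
  }
  if (risk_table$time[1] != 0) stop("`risk_table` must start at time 0")
  if (any(risk_table$n_at_risk < 0) || any(diff(risk_table$n_at_risk) > 0)) {
    stop("`n_at_risk` must be non-negative and non-increasing")
  }
  structure(
    list(points = points, risk_table = risk_table, total_events = total_events),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d coordinates over [0, %.3g] months, %d risk-table rows (n0 = %d)%s\n",
              nrow(x$points), max(x$points$time), nrow(x$risk_table),
              x$risk_table$n_at_risk[1],
              if (is.null(x$total_events)) "" else sprintf(", %d total events", x$total_events)))
  invisible(x)
}

# One deterministic pass over the coordinates of a risk-table interval:
# given the number entering, the running reconstructed KM value, and a
# proposed censoring count (spread uniformly over the interval), solve the
# per-coordinate event counts that track the digitized survival drops.
guyot_interval_pass <- function(tk, Sk, ks, n_enter, km_enter, ncen,
                                int_lo, int_hi) {
  cen_times <- if (ncen > 0) {
    int_lo + seq_len(ncen) * (int_hi - int_lo) / (ncen + 1)
  } else numeric(0)
  n <- n_enter; km <- km_enter
  d_out <- integer(length(ks)); c_out <- integer(length(ks))
  prev_t <- int_lo
  for (j in seq_along(ks)) {
    k <- ks[j]
    # censorings strictly before this drop leave the risk set first
    c_before <- sum(cen_times > prev_t & cen_times < tk[k])
    n <- n - c_before
    c_out[j] <- c_before
    d <- 0L
    if (n > 0 && km > 0) {
      d <- as.integer(round(n * (1 - Sk[k] / km)))
      d <- max(0L, min(d, n))
      if (d > 0) km <- km * (1 - d / n)
    }
    d_out[j] <- d
    n <- n - d
    prev_t <- tk[k]
  }
  c_tail <- sum(cen_times >= prev_t)
  n <- n - c_tail
  list(n_exit = n, km_exit = km, d = d_out, c = c_out, c_tail = c_tail,
       cen_times = cen_times)
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Implements the Guyot-style inversion of the Kaplan-Meier estimator: the
#' per-interval numbers of events and censorings are solved so that (a) the
#' reconstructed KM curve tracks the digitized survival drops and (b) the
#' number remaining at risk at each risk-table time matches the printed
#' count. Event times are placed at the digitized drop times; censoring
#' times are spread uniformly within each risk-table interval. When
#' `total_events` is supplied the censoring in the final interval is
#' calibrated so the reconstructed event count matches it; otherwise no
#' censoring is assumed after the last risk-table time and survivors are
#' administratively censored at the last coordinate.
#'
#' @param curve A [km_curve()] with at least two risk-table rows.
#' @return Data frame with columns `time` (months), `event` (0/1); one row
#'   per reconstructed patient, `nrow` equal to the initial number at risk.
#' @export
reconstruct_ipd <- function(curve) {
  if (!inherits(curve, "km_curve")) stop("`curve` must be a `km_curve`")
  if (nrow(curve$risk_table) < 2) stop("need at least 2 risk-table rows")
  tk <- curve$points$time; Sk <- curve$points$survival
  trisk <- curve$risk_table$time; nrisk <- curve$risk_table$n_at_risk
  I <- length(trisk); K <- length(tk)
  t_end <- max(tk[K], trisk[I])

  ev_t <- ev_e <- numeric(0)
  n <- nrisk[1]; km <- 1
  for (i in seq_len(I)) {
    lo <- trisk[i]
    hi <- if (i < I) trisk[i + 1] else t_end
    ks <- which(tk > lo & tk <= hi)
    run <- function(ncen) guyot_interval_pass(tk, Sk, ks, n, km, ncen, lo, hi)

    if (i < I) {
      target <- nrisk[i + 1]
      pass <- run(0L)
      if (pass$n_exit < target) {
        stop(sprintf(
          "infeasibility error: risk count %d at t = %g cannot be reached (only %d remain even with no censoring)",
          target, trisk[i + 1], pass$n_exit))
      }
      ncen <- pass$n_exit - target
      for (iter in 1:100) {
        pass <- run(ncen)
        gap <- pass$n_exit - target
        if (gap == 0L) break
        ncen <- ncen + gap
        if (ncen < 0L) {
          stop(sprintf(
            "infeasibility error: negative implied censorings in interval [%g, %g]",
            lo, hi))
        }
      }
      if (pass$n_exit != target) {
        stop(sprintf(
          "infeasibility error: could not match risk count %d at t = %g",
          target, trisk[i + 1]))
      }
    } else if (!is.null(curve$total_events)) {
      # calibrate final-interval censoring so total events match the report;
      # events are non-increasing in the censoring count, so bisect
      need <- curve$total_events - sum(ev_e)
      f <- function(ncen) sum(run(ncen)$d)
      lo_c <- 0L; hi_c <- n
      if (f(lo_c) <= need) {
        ncen <- lo_c
      } else if (f(hi_c) >= need) {
        ncen <- hi_c
      } else {
        while (hi_c - lo_c > 1L) {
          mid <- (lo_c + hi_c) %/% 2L
          if (f(mid) >= need) lo_c <- mid else hi_c <- mid
        }
        ncen <- if (abs(f(lo_c) - need) <= abs(f(hi_c) - need)) lo_c else hi_c
      }
      pass <- run(ncen)
    } else {
      pass <- run(0L)
    }

    if (length(ks)) {
      ev_t <- c(ev_t, rep(tk[ks], pass$d))
      ev_e <- c(ev_e, rep(1, sum(pass$d)))
    }
    if (length(pass$cen_times)) {
      ev_t <- c(ev_t, pass$cen_times)
      ev_e <- c(ev_e, rep(0, length(pass$cen_times)))
    }
    n <- pass$n_exit; km <- pass$km_exit
  }
  if (n > 0) {
    ev_t <- c(ev_t, rep(t_end, n))
    ev_e <- c(ev_e, rep(0, n))
  }
  out <- data.frame(time = ev_t, event = as.integer(ev_e))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a digitized KM curve from coordinate and risk-table CSV files
#'
#' @param points_path CSV with header `time_months,survival`.
#' @param risk_path CSV with header `time_months,n_at_risk`.
#' @param total_events Optional reported event count.
#' @return A [km_curve()].
#' @export
read_km_curve <- function(points_path, risk_path, total_events = NULL) {
  p <- utils::read.csv(points_path)
  r <- utils::read.csv(risk_path)
  if (!all(c("time_months", "survival") %in% names(p))) {
    stop("coordinates CSV must have columns `time_months,survival`")
  }
  if (!all(c("time_months", "n_at_risk") %in% names(r))) {
    stop("risk table CSV must have columns `time_months,n_at_risk`")
  }
  km_curve(points = data.frame(time = p$time_months, survival = p$survival),
           risk_table = data.frame(time = r$time_months, n_at_risk = r$n_at_risk),
           total_events = total_events)
}
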