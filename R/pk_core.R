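# Analytic one-compartment PK with first-order elimination for arbitrary
# sequences of zero-order intravenous infusions. Superposition over events
# gives closed-form concentrations; AUC comes from exact mass balance,
# so no ODE solver or numerical quadrature is involved.

#' Construct a regimen from explicit infusion events
#'
#' @param start Event start times (h since first dose).
#' @param amount Dose amounts (mg).
#' @param duration Infusion durations (h), strictly positive.
#' @param label Optional text label.
#' @return An object of class `regimen`: a data frame with columns
#'   `start`, `amount`, `duration`, `rate` (mg/h), sorted by start time.
#' @export
regimen <- function(start = numeric(), amount = numeric(), duration = numeric(),
                    label = "") {
  n <- length(start)
  if (length(amount) != n || length(duration) != n) {
    stop("`start`, `amount`, `duration` must have equal length", call. = FALSE)
  }
  if (n > 0) {
    if (any(start < 0)) stop("event start times must be >= 0", call. = FALSE)
    if (any(amount < 0)) stop("event amounts must be >= 0", call. = FALSE)
    if (any(duration <= 0)) stop("event durations must be > 0", call. = FALSE)
  }
  ord <- order(start)
  out <- data.frame(start = as.numeric(start)[ord],
                    amount = as.numeric(amount)[ord],
                    duration = as.numeric(duration)[ord])
  out$rate <- ifelse(out$duration > 0, out$amount / out$duration, 0)
  attr(out, "label") <- label
  class(out) <- c("regimen", "data.frame")
  out
}

#' Build a loading + maintenance (or continuous) dosing regimen
#'
#' Encodes the usual clinical grammar "LD x mg over d h, then MD y mg every
#' tau h over d2 h" within a simulation horizon. The first maintenance dose
#' starts `first_md_offset` hours after the loading-dose start (default: one
#' dosing interval). Continuous mode emits a single long infusion delivering
#' `continuous_daily` mg per 24 h, started after the loading dose ends (or at
#' time zero without one).
#'
#' @param loading_dose Loading dose (mg); 0 for none.
#' @param ld_duration Loading-infusion duration (h).
#' @param maintenance_dose Maintenance dose (mg); 0 for none.
#' @param interval Dosing interval (h), typically 6, 8, 12 or 24.
#' @param md_duration Maintenance-infusion duration (h).
#' @param horizon Simulation horizon (h); doses starting at or after it are
#'   not emitted.
#' @param continuous_daily Daily dose (mg/24 h) for continuous infusion mode;
#'   mutually exclusive with `maintenance_dose > 0`.
#' @param first_md_offset Start of the first maintenance dose relative to the
#'   loading-dose start (h); defaults to `interval`.
#' @param label Optional text label.
#' @return A `regimen`.
#' @examples
#' build_regimen(2000, 2, 1000, 8, 2, horizon = 60)
#' @export
build_regimen <- function(loading_dose = 0, ld_duration = 1,
                          maintenance_dose = 0, interval = 8, md_duration = 2,
                          horizon = 60, continuous_daily = NULL,
                          first_md_offset = NULL, label = NULL) {
  if (horizon <= 0) stop("`horizon` must be > 0", call. = FALSE)
  continuous <- !is.null(continuous_daily) && continuous_daily > 0
  if (continuous && maintenance_dose > 0) {
    stop("specify either intermittent maintenance dosing or a continuous daily dose, not both",
         call. = FALSE)
  }
  start <- amount <- duration <- numeric()
  if (loading_dose > 0) {
    start <- 0; amount <- loading_dose; duration <- ld_duration
  }
  if (continuous) {
    c0 <- if (loading_dose > 0) ld_duration else 0
    start <- c(start, c0)
    amount <- c(amount, continuous_daily * (horizon - c0) / 24)
    duration <- c(duration, horizon - c0)
  } else if (maintenance_dose > 0) {
    off <- if (is.null(first_md_offset)) interval else first_md_offset
    md_start <- seq(off, horizon, by = interval)
    md_start <- md_start[md_start < horizon]
    start <- c(start, md_start)
    amount <- c(amount, rep(maintenance_dose, length(md_start)))
    duration <- c(duration, rep(md_duration, length(md_start)))
  }
  if (is.null(label)) {
    label <- if (continuous) {
      sprintf("LD %g mg + continuous %g mg/day", loading_dose, continuous_daily)
    } else if (maintenance_dose > 0) {
      sprintf("LD %g mg + MD %g mg every %g", loading_dose, maintenance_dose, interval)
    } else sprintf("LD %g mg", loading_dose)
  }
  regimen(start, amount, duration, label = label)
}

# Concentration at scalar time t for vectors of (vd, cl): used by the Monte
# Carlo engine where thousands of parameter draws share one regimen.
.conc_many <- function(t, reg, vd, cl) {
  ke <- cl / vd
  out <- numeric(length(cl))
  for (i in seq_len(nrow(reg))) {
    el <- t - reg$start[i]
    if (el <= 0 || reg$amount[i] <= 0) next
    tau1 <- min(el, reg$duration[i])
    tau2 <- max(el - reg$duration[i], 0)
    out <- out + (reg$rate[i] / cl) * (1 - exp(-ke * tau1)) * exp(-ke * tau2)
  }
  out
}

#' Concentration-time profile under a regimen
#'
#' Superposition of the closed-form single-infusion solution: during an
#' event (elapsed time tau <= duration) the contribution is
#' \eqn{(R/CL)(1 - e^{-k_e \tau})}; afterwards the end-of-infusion
#' concentration decays mono-exponentially. `t` is vectorized.
#'
#' @param t Times (h), >= 0.
#' @param reg A `regimen`.
#' @param vd Volume of distribution (L).
#' @param cl Clearance (L/h).
#' @return Concentrations (mg/L).
#' @export
concentration <- function(t, reg, vd, cl) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (vd <= 0 || cl <= 0) stop("`vd` and `cl` must be > 0", call. = FALSE)
  ke <- cl / vd
  out <- numeric(length(t))
  for (i in seq_len(nrow(reg))) {
    el <- t - reg$start[i]
    act <- el > 0 & reg$amount[i] > 0
    if (!any(act)) next
    tau1 <- pmin(el[act], reg$duration[i])
    tau2 <- pmax(el[act] - reg$duration[i], 0)
    out[act] <- out[act] +
      (reg$rate[i] / cl) * (1 - exp(-ke * tau1)) * exp(-ke * tau2)
  }
  out
}

# Cumulative drug input (mg) delivered by time t (scalar in t).
.input_by <- function(t, reg) {
  if (nrow(reg) == 0) return(0)
  sum(reg$rate * pmin(pmax(t - reg$start, 0), reg$duration))
}

#' Exact AUC over a time window
#'
#' Mass balance for a linear one-compartment model gives
#' \eqn{AUC_{0..t} = (\mathrm{input}(t) - V_d C(t)) / CL} exactly, so the
#' window AUC is a difference of two closed-form terms; no numerical
#' integration is performed.
#'
#' @param t1,t2 Window bounds (h), `0 <= t1 < t2`.
#' @inheritParams concentration
#' @return AUC in mg*h/L.
#' @export
auc_window <- function(t1, t2, reg, vd, cl) {
  if (t1 < 0 || t2 <= t1) stop("need 0 <= t1 < t2", call. = FALSE)
  if (nrow(reg) == 0) return(0)
  auc0 <- function(t) (.input_by(t, reg) - vd * concentration(t, reg, vd, cl)) / cl
  auc0(t2) - auc0(t1)
}

# Vectorized-over-parameters AUC window (shared regimen), for Monte Carlo.
.auc_window_many <- function(t1, t2, reg, vd, cl) {
  if (nrow(reg) == 0) return(numeric(length(cl)))
  in1 <- .input_by(t1, reg); in2 <- .input_by(t2, reg)
  ((in2 - vd * .conc_many(t2, reg, vd, cl)) -
     (in1 - vd * .conc_many(t1, reg, vd, cl))) / cl
}

#' Elimination half-life
#'
#' @inheritParams concentration
#' @return Half-life in hours, `0.693 * vd / cl`.
#' @examples
#' half_life(75, 7)
#' @export
half_life <- function(vd, cl) {
  if (any(vd <= 0) || any(cl <= 0)) stop("`vd` and `cl` must be > 0", call. = FALSE)
  0.693 * vd / cl
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s: %d infusion event(s)\n",
              attr(x, "label"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Serialize a regimen to JSON
#' @param reg A `regimen`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
regimen_to_json <- function(reg, path = NULL) {
  obj <- list(label = attr(reg, "label"),
              events = as.data.frame(reg)[, c("start", "amount", "duration")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a regimen from JSON
#' @param path File path or JSON string.
#' @export
regimen_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ev <- obj$events
  regimen(ev$start, ev$amount, ev$duration,
          label = if (is.null(obj$label)) "" else obj$label)
}
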