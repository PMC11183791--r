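# The final covariate population model: Vd = Vd_pop (no covariates),
# CL = CL_pop * exp(beta_EGFR * eGFR) * exp(beta_LBM * LBM) (uncentered
# exponential covariate model), lognormal inter-individual variability on
# both parameters, additive (constant-SD) residual error.

#' Population parameter set
#'
#' Container for the fixed effects, covariate coefficients on clearance,
#' random-effect SDs and residual SD of the population model.
#'
#' @param vd_pop Typical volume of distribution (L).
#' @param cl_pop Typical clearance at covariate values of zero (L/h).
#' @param beta_cl Named numeric vector of exponential covariate coefficients
#'   on CL; names refer to covariate columns (e.g. `EGFR`, `LBM`). May be
#'   empty for the structural (covariate-free) model.
#' @param omega_vd,omega_cl SDs of the lognormal random effects (>= 0).
#' @param sigma_add Additive residual SD (mg/L, > 0).
#' @return An object of class `pop_params`.
#' @export
pop_params <- function(vd_pop, cl_pop, beta_cl = numeric(),
                       omega_vd, omega_cl, sigma_add) {
  if (vd_pop <= 0 || cl_pop <= 0) stop("typical values must be > 0", call. = FALSE)
  if (omega_vd < 0 || omega_cl < 0) stop("omegas must be >= 0", call. = FALSE)
  if (sigma_add <= 0) stop("sigma_add must be > 0", call. = FALSE)
  beta_cl <- unlist(beta_cl)
  if (length(beta_cl) && is.null(names(beta_cl))) {
    stop("`beta_cl` must be a named vector", call. = FALSE)
  }
  structure(list(vd_pop = vd_pop, cl_pop = cl_pop,
                 beta_cl = if (length(beta_cl)) beta_cl else stats::setNames(numeric(), character()),
                 omega_vd = omega_vd, omega_cl = omega_cl,
                 sigma_add = sigma_add),
            class = "pop_params")
}

#' Published final-model estimates
#'
#' The shipped parameter set of the final covariate model (Vd_pop 75.0 L,
#' CL_pop 1.32 L/h, beta_EGFR 0.61 per mL/s/1.73 m^2, beta_LBM 0.011 per kg,
#' Omega_Vd 0.31, Omega_CL 0.28, additive sigma 2.9 mg/L).
#'
#' @return A `pop_params` object.
#' @export
published_params <- function() {
  path <- system.file("extdata", "published_model.json", package = "vancopk", mustWork = TRUE)
  read_pop_params(path)
}

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params>\n")
  cat(sprintf("  Vd_pop %.4g L   CL_pop %.4g L/h\n", x$vd_pop, x$cl_pop))
  if (length(x$beta_cl)) {
    cat("  CL covariates:",
        paste(sprintf("%s=%.4g", names(x$beta_cl), x$beta_cl), collapse = ", "), "\n")
  } else cat("  CL covariates: none\n")
  cat(sprintf("  Omega_Vd %.3g  Omega_CL %.3g  sigma_add %.3g mg/L\n",
              x$omega_vd, x$omega_cl, x$sigma_add))
  invisible(x)
}

#' Typical clearance from the covariate model
#'
#' \eqn{CL = CL_{pop} e^{\beta_{eGFR} \cdot eGFR} e^{\beta_{LBM} \cdot LBM}}
#' for the final model; more generally the product over whatever covariates
#' `pop$beta_cl` names.
#'
#' @param egfr Creatinine-based eGFR (mL/s/1.73 m^2), >= 0. Vectorized.
#' @param lbm Lean body mass (kg), > 0. Vectorized.
#' @param pop A `pop_params` whose `beta_cl` names are a subset of
#'   `c("EGFR", "LBM")`.
#' @return Typical CL (L/h).
#' @examples
#' typical_cl(1.51, 68, published_params())
#' @export
typical_cl <- function(egfr, lbm, pop) {
  if (any(egfr < 0)) stop("`egfr` must be >= 0", call. = FALSE)
  if (any(lbm <= 0)) stop("`lbm` must be > 0", call. = FALSE)
  covs <- list(EGFR = egfr, LBM = lbm)
  .typical_cl_cov(covs, pop)
}

# General form: `covs` is a named list/data.frame of covariate vectors
# covering names(pop$beta_cl).
.typical_cl_cov <- function(covs, pop) {
  lin <- 0
  for (nm in names(pop$beta_cl)) {
    if (is.null(covs[[nm]])) stop("missing covariate `", nm, "`", call. = FALSE)
    lin <- lin + pop$beta_cl[[nm]] * covs[[nm]]
  }
  pop$cl_pop * exp(lin)
}

#' Typical volume of distribution
#'
#' No covariate predicts Vd in the final model, so the typical Vd is the
#' population value regardless of the covariate vector.
#'
#' @param pop A `pop_params`.
#' @param n Number of (identical) values to return.
#' @return Vd_pop (L), replicated `n` times.
#' @export
typical_vd <- function(pop, n = 1) {
  rep(pop$vd_pop, n)
}

#' Draw individual parameters from the population model
#'
#' Samples lognormal random effects `eta_vd ~ N(0, omega_vd^2)` and
#' `eta_cl ~ N(0, omega_cl^2)` and applies them to the typical values.
#' Uses the current R random stream; call `set.seed()` for reproducibility.
#'
#' @inheritParams typical_cl
#' @param n Number of individuals to draw per covariate vector element.
#' @return A data frame with columns `eta_vd`, `eta_cl`, `vd`, `cl`.
#' @export
sample_individual <- function(egfr, lbm, pop, n = 1) {
  tcl <- typical_cl(egfr, lbm, pop)
  m <- length(tcl) * n
  tcl <- rep(tcl, times = n)
  eta_vd <- stats::rnorm(m, 0, pop$omega_vd)
  eta_cl <- stats::rnorm(m, 0, pop$omega_cl)
  data.frame(eta_vd = eta_vd, eta_cl = eta_cl,
             vd = pop$vd_pop * exp(eta_vd), cl = tcl * exp(eta_cl))
}

#' Apply the residual-error model to true concentrations
#'
#' Constant (additive Gaussian) error: `y = c + e`, `e ~ N(0, sigma_add^2)`.
#' Values may fall below zero at low true concentrations; downstream
#' quantitation-limit filtering handles them.
#'
#' @param conc_true True model concentrations (mg/L), >= 0.
#' @param pop A `pop_params`.
#' @return Simulated observed concentrations (mg/L).
#' @export
observe <- function(conc_true, pop) {
  if (any(conc_true < 0)) stop("`conc_true` must be >= 0", call. = FALSE)
  conc_true + stats::rnorm(length(conc_true), 0, pop$sigma_add)
}

# Joint-posterior objective for one subject's random effects:
# 0.5 * sum((y - C)^2)/sigma^2 + 0.5 * eta_vd^2/omega_vd^2 + 0.5 * eta_cl^2/omega_cl^2
# (constants dropped). Gradient is analytic via the infusion solution.
.eta_objective <- function(eta, reg, times, dv, tvd, tcl, pop, grad = FALSE) {
  vd <- tvd * exp(eta[1]); cl <- tcl * exp(eta[2])
  ke <- cl / vd
  n <- length(times)
  C <- numeric(n); dec <- numeric(n); dev <- numeric(n)
  for (i in seq_len(nrow(reg))) {
    el <- times - reg$start[i]
    act <- el > 0 & reg$amount[i] > 0
    if (!any(act)) next
    tau1 <- pmin(el[act], reg$duration[i])
    tau2 <- pmax(el[act] - reg$duration[i], 0)
    A <- reg$rate[i] / cl
    E1 <- exp(-ke * tau1); D <- exp(-ke * tau2)
    Ce <- A * (1 - E1) * D
    C[act] <- C[act] + Ce
    if (grad) {
      # d/d eta_cl: -Ce + ke*(A*D*tau1*E1 - tau2*Ce); d/d eta_vd = -(that + Ce)... see below
      g <- ke * (A * D * tau1 * E1 - tau2 * Ce)
      dec[act] <- dec[act] + (-Ce + g)
      dev[act] <- dev[act] - g
    }
  }
  r <- dv - C
  f <- 0.5 * sum(r^2) / pop$sigma_add^2 +
    0.5 * eta[1]^2 / max(pop$omega_vd, 1e-12)^2 +
    0.5 * eta[2]^2 / max(pop$omega_cl, 1e-12)^2
  if (!grad) return(list(value = f, conc = C))
  gv <- -sum(r * dev) / pop$sigma_add^2 + eta[1] / max(pop$omega_vd, 1e-12)^2
  gc <- -sum(r * dec) / pop$sigma_add^2 + eta[2] / max(pop$omega_cl, 1e-12)^2
  list(value = f, gradient = c(gv, gc), conc = C)
}

#' Empirical-Bayes (MAP) individual estimate
#'
#' Conditional mode of the random effects given a subject's dosing history,
#' observations and covariates under the population model: minimizes the
#' penalized least-squares objective
#' \eqn{\sum_j (y_j - C(t_j;\eta))^2/\sigma^2 + \eta_{Vd}^2/\Omega_{Vd}^2 +
#' \eta_{CL}^2/\Omega_{CL}^2}. With no observations the prior mode (typical
#' values) is returned.
#'
#' @param reg The subject's `regimen`.
#' @param times Observation times (h).
#' @param dv Observed concentrations (mg/L), same length as `times`.
#' @param egfr,lbm Subject covariates.
#' @param pop A `pop_params`.
#' @return A list with `eta_vd`, `eta_cl`, `vd`, `cl`, `t_half`,
#'   `objective` (value at the mode), `objective_init` (value at eta = 0)
#'   and `converged`.
#' @export
map_estimate <- function(reg, times, dv, egfr, lbm, pop) {
  stopifnot(length(times) == length(dv))
  tvd <- pop$vd_pop
  tcl <- typical_cl(egfr, lbm, pop)
  f0 <- .eta_objective(c(0, 0), reg, times, dv, tvd, tcl, pop)$value
  if (length(dv) == 0 || (pop$omega_vd == 0 && pop$omega_cl == 0)) {
    return(list(eta_vd = 0, eta_cl = 0, vd = tvd, cl = tcl,
                t_half = half_life(tvd, tcl),
                objective = f0, objective_init = f0, converged = TRUE))
  }
  fit <- stats::nlminb(
    c(0, 0),
    function(e) .eta_objective(e, reg, times, dv, tvd, tcl, pop)$value,
    gradient = function(e) .eta_objective(e, reg, times, dv, tvd, tcl, pop, grad = TRUE)$gradient,
    control = list(rel.tol = 1e-12, abs.tol = 1e-12))
  eta <- fit$par
  list(eta_vd = eta[1], eta_cl = eta[2],
       vd = tvd * exp(eta[1]), cl = tcl * exp(eta[2]),
       t_half = half_life(tvd * exp(eta[1]), tcl * exp(eta[2])),
       objective = fit$objective, objective_init = f0,
       converged = fit$convergence == 0 || fit$objective <= f0 + 1e-10)
}

#' Write population parameters to JSON
#' @param pop A `pop_params`.
#' @param path Output file path.
#' @export
write_pop_params <- function(pop, path) {
  obj <- list(vd_pop = pop$vd_pop, cl_pop = pop$cl_pop,
              beta_cl = as.list(pop$beta_cl),
              omega_vd = pop$omega_vd, omega_cl = pop$omega_cl,
              sigma_add = pop$sigma_add)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read population parameters from JSON
#' @param path File path.
#' @return A `pop_params`.
#' @export
read_pop_params <- function(path) {
  obj <- jsonlite::fromJSON(path)
  pop_params(vd_pop = obj$vd_pop, cl_pop = obj$cl_pop,
             beta_cl = unlist(obj$beta_cl),
             omega_vd = obj$omega_vd, omega_cl = obj$omega_cl,
             sigma_add = obj$sigma_add)
}
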