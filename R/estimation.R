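# Approximate maximum-likelihood estimation of the population model from
# sparse TDM event records: Laplace (default) or 5x5 adaptive Gauss-Hermite
# marginal likelihood over the two random effects, computed in compiled code,
# with the population parameters optimized on the log scale. Covariate
# screening, forward/backward stepwise selection and a nonparametric
# patient-level bootstrap sit on top of the same fit machinery.

# Split an event-record table into flat per-patient arrays for the C++ kernel.
.prep_dataset <- function(dataset, covariates = character()) {
  need <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dataset <- .ensure_derived(dataset, covariates)
  ids <- unique(dataset$ID)
  n <- length(ids)
  ev_start <- ev_rate <- ev_dur <- numeric()
  obs_t <- obs_y <- numeric()
  ev_ptr <- obs_ptr <- integer(n + 1)
  X <- matrix(0, n, length(covariates), dimnames = list(NULL, covariates))
  for (i in seq_len(n)) {
    rows <- dataset[dataset$ID == ids[i], , drop = FALSE]
    d <- rows[rows$EVID == 1, , drop = FALSE]
    o <- rows[rows$EVID == 0 & !is.na(rows$DV), , drop = FALSE]
    if (nrow(d) == 0) stop("patient ", ids[i], " has no dose records", call. = FALSE)
    ev_start <- c(ev_start, d$TIME)
    ev_rate <- c(ev_rate, d$RATE)
    ev_dur <- c(ev_dur, d$AMT / d$RATE)
    obs_t <- c(obs_t, o$TIME)
    obs_y <- c(obs_y, o$DV)
    ev_ptr[i + 1] <- length(ev_start)
    obs_ptr[i + 1] <- length(obs_t)
    for (cv in covariates) X[i, cv] <- rows[[cv]][1]
  }
  list(ids = ids, n = n, ev_start = ev_start, ev_rate = ev_rate,
       ev_dur = ev_dur, ev_ptr = ev_ptr, obs_t = obs_t, obs_y = obs_y,
       obs_ptr = obs_ptr, X = X, n_obs = length(obs_t))
}

.ensure_derived <- function(dataset, covariates) {
  needed <- setdiff(covariates, names(dataset))
  if (length(needed)) {
    if (all(c("SEX", "AGE", "WT", "HT", "SCR") %in% names(dataset))) {
      dataset <- derive_covariates(dataset)
      needed <- setdiff(covariates, names(dataset))
    }
    if (length(needed)) {
      stop("covariate column(s) not in dataset: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
  }
  dataset
}

.typical_from_prep <- function(prep, pop) {
  tcl <- rep(pop$cl_pop, prep$n)
  for (nm in names(pop$beta_cl)) {
    if (!nm %in% colnames(prep$X)) stop("prep lacks covariate ", nm, call. = FALSE)
    tcl <- tcl * exp(pop$beta_cl[[nm]] * prep$X[, nm])
  }
  list(tvd = rep(pop$vd_pop, prep$n), tcl = tcl)
}

.neg2ll_prep <- function(pop, prep, method = "laplace", eta_start = NULL) {
  typ <- .typical_from_prep(prep, pop)
  if (is.null(eta_start)) eta_start <- matrix(0, prep$n, 2)
  res <- pop_neg2ll_cpp(prep$ev_start, prep$ev_rate, prep$ev_dur, prep$ev_ptr,
                        prep$obs_t, prep$obs_y, prep$obs_ptr,
                        typ$tvd, typ$tcl, pop$omega_vd, pop$omega_cl,
                        pop$sigma_add, match.arg(method, c("laplace", "agh")) == "agh",
                        eta_start)
  res
}

#' Marginal -2 log-likelihood (OFV) of a population model on a dataset
#'
#' Integrates the two random effects out of each patient's contribution by
#' Laplace approximation around the conditional mode (or 5-node-per-axis
#' adaptive Gauss-Hermite quadrature) and returns
#' \eqn{-2 \sum_i \log \int p(y_i|\eta) p(\eta) d\eta}.
#'
#' @param pop A `pop_params`.
#' @param dataset An event-record data frame (see [read_tdm()]); covariate
#'   columns named by `names(pop$beta_cl)` must be present or derivable.
#' @param method `"laplace"` (default) or `"agh"` (5x5 adaptive
#'   Gauss-Hermite).
#' @return The OFV (scalar), with per-patient contributions and conditional
#'   modes attached as attributes `ofv_i` and `eta`.
#' @export
neg2ll <- function(pop, dataset, method = c("laplace", "agh")) {
  method <- match.arg(method)
  prep <- .prep_dataset(dataset, names(pop$beta_cl))
  res <- .neg2ll_prep(pop, prep, method)
  structure(res$neg2ll, ofv_i = res$ofv_i, eta = res$eta, ids = prep$ids)
}

.theta_pack <- function(pop) {
  c(log(pop$vd_pop), log(pop$cl_pop), pop$beta_cl,
    log(pop$omega_vd), log(pop$omega_cl), log(pop$sigma_add))
}

.theta_unpack <- function(theta, covariates) {
  k <- length(covariates)
  beta <- if (k) stats::setNames(theta[2 + seq_len(k)], covariates) else numeric()
  pop_params(vd_pop = exp(theta[1]), cl_pop = exp(theta[2]), beta_cl = beta,
             omega_vd = exp(theta[3 + k]), omega_cl = exp(theta[4 + k]),
             sigma_add = exp(theta[5 + k]))
}


# Symmetric central-difference Hessian of scalar function f at x.
.hessian_central <- function(f, x, h = 0.01) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Fit the population model by approximate maximum likelihood
#'
#' Minimizes the adaptive Gauss-Hermite (or Laplace) OFV over the population
#' parameters, with typical values and variability parameters on the log
#' scale and covariate coefficients unconstrained. Conditional modes are
#' re-solved from the prior mode at every evaluation so the objective is a
#' deterministic function of the parameters. Relative standard errors come
#' from the inverse numerical Hessian of the OFV (delta method back to the
#' natural scale); if the Hessian is not positive definite the RSEs are
#' reported as `NA` rather than pseudo-inverted.
#'
#' @param dataset Event-record data frame.
#' @param covariates_cl Character vector of covariate columns entering CL
#'   exponentially (possibly empty for the structural model).
#' @param init A `pop_params` with starting values (its `beta_cl` is
#'   overridden by `covariates_cl`, new coefficients start at 0).
#' @param method Likelihood approximation, `"laplace"` or `"agh"`.
#' @param compute_rse Compute the numerical Hessian for RSEs (default TRUE;
#'   skipping it speeds up nested model comparisons).
#' @param control Passed to [stats::nlminb()]; defaults to
#'   `rel.tol = 1e-8`, `iter.max = 500`.
#' @return A `fit_result` list: `pop` (estimates), `rse_percent`, `ofv`,
#'   `aic`, `bic`, `converged`, `ebes` (per-patient conditional modes and
#'   individual parameters), `n_patients`, `n_obs`.
#' @export
fit_population <- function(dataset, covariates_cl = character(),
                           init = NULL, method = c("agh", "laplace"),
                           compute_rse = TRUE, control = list()) {
  method <- match.arg(method)
  prep <- .prep_dataset(dataset, covariates_cl)
  if (is.null(init)) {
    init <- pop_params(vd_pop = 70, cl_pop = 4, beta_cl = numeric(),
                       omega_vd = 0.3, omega_cl = 0.3, sigma_add = 3)
  }
  beta0 <- stats::setNames(rep(0, length(covariates_cl)), covariates_cl)
  keep <- intersect(names(init$beta_cl), covariates_cl)
  beta0[keep] <- init$beta_cl[keep]
  init <- pop_params(init$vd_pop, init$cl_pop, beta0,
                     init$omega_vd, init$omega_cl, init$sigma_add)

  # Optimize with covariates centered at their cohort mean: the uncentered
  # exponential model makes cl_pop and the coefficients nearly collinear.
  # The reported model is transformed back to the uncentered scale.
  k <- length(covariates_cl)
  xbar <- if (k) colMeans(prep$X) else numeric()
  prep_c <- prep
  if (k) prep_c$X <- sweep(prep$X, 2, xbar)
  init_c <- init
  if (k) init_c$cl_pop <- init$cl_pop * exp(sum(init$beta_cl * xbar))
  theta0 <- .theta_pack(init_c)

  # conditional modes are re-solved from the prior mode (eta = 0) at every
  # evaluation: the objective is then a deterministic function of theta
  # (warm starts can hop between basins of occasional multimodal
  # conditional posteriors and de-smooth the outer problem)
  eta0 <- matrix(0, prep$n, 2)
  obj <- function(theta) {
    pop <- try(.theta_unpack(theta, covariates_cl), silent = TRUE)
    if (inherits(pop, "try-error")) return(1e10)
    res <- try(.neg2ll_prep(pop, prep_c, method, eta0), silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$neg2ll)) return(1e10)
    res$neg2ll
  }
  gradient <- function(theta, h = 1e-5) {
    g <- numeric(length(theta))
    for (i in seq_along(theta)) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      g[i] <- (obj(tp) - obj(tm)) / (2 * h)
    }
    g
  }
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 500, eval.max = 2000),
                            control)
  opt <- stats::nlminb(theta0, obj, gradient = gradient, control = ctrl)
  # polish: PORT can stall in the stiff cl_pop/beta valley; restart from the
  # incumbent until the OFV is stable
  stable <- FALSE
  for (r in seq_len(3)) {
    prev <- opt$objective
    opt2 <- stats::nlminb(opt$par, obj, gradient = gradient, control = ctrl)
    if (opt2$objective <= prev) opt <- opt2
    if (abs(opt2$objective - prev) < 1e-3) {
      stable <- TRUE
      break
    }
  }
  pop_c <- .theta_unpack(opt$par, covariates_cl)
  pop <- pop_c
  if (k) pop$cl_pop <- pop_c$cl_pop * exp(-sum(pop_c$beta_cl * xbar))
  final <- .neg2ll_prep(pop, prep, method, eta0)

  rse <- rep(NA_real_, length(opt$par))
  names(rse) <- c("vd_pop", "cl_pop",
                  if (length(covariates_cl)) paste0("beta_cl_", covariates_cl),
                  "omega_vd", "omega_cl", "sigma_add")
  if (compute_rse) {
    # central-difference Hessian with a step wide enough (0.01 on the
    # optimization scale, i.e. ~1% for log-scale parameters) to average over
    # the tiny kinks that conditional-mode basin switches leave in the
    # objective; naive small-step differencing can misread those kinks as
    # huge curvature and collapse the standard errors
    H <- try(.hessian_central(obj, opt$par, h = 0.01), silent = TRUE)
    if (!inherits(H, "try-error")) {
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 0)) {
        covm <- 2 * solve(H)                 # H is the Hessian of -2LL
        np <- length(opt$par)
        se_theta <- sqrt(pmax(diag(covm), 0))
        # log cl_pop (uncentered) = log cl_pop (centered) - sum(beta * xbar)
        j_cl <- rep(0, np); j_cl[2] <- 1
        if (k) j_cl[2 + seq_len(k)] <- -xbar
        se_lcl_u <- sqrt(max(drop(t(j_cl) %*% covm %*% j_cl), 0))
        # log-scale parameters: RSE% ~= 100 * SE(log estimate)
        rse["vd_pop"] <- 100 * se_theta[1]
        rse["cl_pop"] <- 100 * se_lcl_u
        if (k) {
          rse[paste0("beta_cl_", covariates_cl)] <-
            100 * se_theta[2 + seq_len(k)] / abs(pop$beta_cl)
        }
        rse["omega_vd"] <- 100 * se_theta[3 + k]
        rse["omega_cl"] <- 100 * se_theta[4 + k]
        rse["sigma_add"] <- 100 * se_theta[5 + k]
      }
    }
  }
  typ <- .typical_from_prep(prep, pop)
  ebes <- data.frame(ID = prep$ids,
                     eta_vd = final$eta[, 1], eta_cl = final$eta[, 2],
                     vd = typ$tvd * exp(final$eta[, 1]),
                     cl = typ$tcl * exp(final$eta[, 2]))
  ebes$t_half <- half_life(ebes$vd, ebes$cl)
  p <- length(opt$par)
  structure(list(pop = pop, rse_percent = rse, ofv = final$neg2ll,
                 aic = final$neg2ll + 2 * p,
                 bic = final$neg2ll + p * log(prep$n_obs),
                 converged = (opt$convergence == 0 || stable) &&
                   is.finite(final$neg2ll),
                 message = opt$message, iterations = opt$iterations,
                 ebes = ebes, covariates = covariates_cl,
                 n_patients = prep$n, n_obs = prep$n_obs, method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, OFV %.3f, %s (%d patients, %d observations)\n",
              x$method, x$ofv, if (x$converged) "converged" else "NOT converged",
              x$n_patients, x$n_obs))
  est <- c(vd_pop = x$pop$vd_pop, cl_pop = x$pop$cl_pop,
           if (length(x$pop$beta_cl)) stats::setNames(x$pop$beta_cl,
             paste0("beta_cl_", names(x$pop$beta_cl))),
           omega_vd = x$pop$omega_vd, omega_cl = x$pop$omega_cl,
           sigma_add = x$pop$sigma_add)
  print(data.frame(estimate = signif(est, 4),
                   rse_percent = signif(x$rse_percent[names(est)], 3)))
  invisible(x)
}

#' Univariate covariate screening on empirical-Bayes estimates
#'
#' Pearson correlation of each log-scale individual parameter estimate
#' against each continuous covariate; pairs with p < `alpha` are flagged as
#' candidates for the covariate model. Zero-variance covariates are
#' reported with `NA` correlation and not flagged.
#'
#' @param fit A `fit_result` (typically of the structural model).
#' @param covariate_table Data frame with one row per patient (`ID` plus
#'   covariate columns).
#' @param covariates Covariate column names to screen.
#' @param parameters Which parameters to screen (default both).
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with columns `parameter`, `covariate`, `pearson_r`,
#'   `p_value`, `candidate`.
#' @export
covariate_screen <- function(fit, covariate_table,
                             covariates = c("EGFR", "LBM"),
                             parameters = c("cl", "vd"), alpha = 0.05) {
  ebes <- fit$ebes
  tab <- merge(ebes, covariate_table, by = "ID", sort = FALSE,
               suffixes = c("", ".cov"))
  if (nrow(tab) < 3) stop("need >= 3 patients for screening", call. = FALSE)
  out <- list()
  for (par in parameters) {
    lp <- log(tab[[par]])
    for (cv in covariates) {
      x <- tab[[cv]]
      if (is.null(x)) stop("covariate ", cv, " not found", call. = FALSE)
      ok <- stats::complete.cases(x, lp)
      if (sum(ok) < 3) {
        out[[length(out) + 1]] <- data.frame(parameter = par, covariate = cv,
                                             pearson_r = NA_real_, p_value = NA_real_,
                                             candidate = FALSE)
        next
      }
      x <- x[ok]; lpo <- lp[ok]
      if (stats::sd(x) == 0 || stats::sd(lpo) == 0) {
        out[[length(out) + 1]] <- data.frame(parameter = par, covariate = cv,
                                             pearson_r = NA_real_, p_value = NA_real_,
                                             candidate = FALSE)
        next
      }
      ct <- stats::cor.test(lpo, x, method = "pearson")
      out[[length(out) + 1]] <- data.frame(parameter = par, covariate = cv,
                                           pearson_r = unname(ct$estimate),
                                           p_value = ct$p.value,
                                           candidate = ct$p.value < alpha)
    }
  }
  do.call(rbind, out)
}

#' Forward-addition / backward-elimination covariate selection
#'
#' Forward step: among the remaining candidates, refit with each added to CL
#' and add the one with the largest OFV drop if it exceeds
#' `forward_dofv` (3.84, chi-square 1 df at p < 0.05). Backward step: from
#' the full forward model, remove any covariate whose removal raises the OFV
#' by at most `backward_dofv` (6.64, p < 0.01), least-supported first.
#' Candidates whose sub-fit fails to converge are skipped and logged in the
#' trace.
#'
#' @param dataset Event-record data frame.
#' @param candidates Character vector of candidate covariate columns for CL.
#' @param init Starting `pop_params` for every sub-fit.
#' @param forward_dofv,backward_dofv OFV-change thresholds.
#' @param method Likelihood approximation.
#' @param control Optimizer control for the sub-fits.
#' @return List with `selected` (character vector), `fit` (final refit with
#'   RSEs) and `trace` (data frame of every tested step).
#' @export
stepwise_selection <- function(dataset, candidates, init = NULL,
                               forward_dofv = 3.84, backward_dofv = 6.64,
                               method = "agh", control = list()) {
  subfit <- function(covs) {
    fit_population(dataset, covariates_cl = covs, init = init, method = method,
                   compute_rse = FALSE, control = control)
  }
  trace <- list()
  note <- function(phase, covs, ofv, dofv, action) {
    trace[[length(trace) + 1]] <<- data.frame(
      phase = phase, model = paste(covs, collapse = "+"),
      ofv = ofv, dofv = dofv, action = action)
  }
  base <- subfit(character())
  current <- character()
  cur_ofv <- base$ofv
  note("start", current, cur_ofv, NA, "structural model")
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    best <- NULL
    for (cv in remaining) {
      f <- try(subfit(c(current, cv)), silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) {
        note("forward", c(current, cv), NA, NA, "skipped (non-convergent)")
        next
      }
      dofv <- cur_ofv - f$ofv
      note("forward", c(current, cv), f$ofv, dofv, "tested")
      if (dofv > forward_dofv && (is.null(best) || dofv > best$dofv)) {
        best <- list(cov = cv, ofv = f$ofv, dofv = dofv)
      }
    }
    if (is.null(best)) break
    current <- c(current, best$cov)
    remaining <- setdiff(remaining, best$cov)
    cur_ofv <- best$ofv
    note("forward", current, cur_ofv, best$dofv, paste("added", best$cov))
  }
  # backward elimination on the forward-selected set
  repeat {
    if (!length(current)) break
    worst <- NULL
    for (cv in current) {
      f <- try(subfit(setdiff(current, cv)), silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) {
        note("backward", setdiff(current, cv), NA, NA, "skipped (non-convergent)")
        next
      }
      dofv <- f$ofv - cur_ofv   # OFV increase caused by removal
      note("backward", setdiff(current, cv), f$ofv, dofv, "tested")
      if (dofv <= backward_dofv && (is.null(worst) || dofv < worst$dofv)) {
        worst <- list(cov = cv, ofv = f$ofv, dofv = dofv)
      }
    }
    if (is.null(worst)) break
    current <- setdiff(current, worst$cov)
    cur_ofv <- worst$ofv
    note("backward", current, cur_ofv, worst$dofv, paste("removed", worst$cov))
  }
  final <- fit_population(dataset, covariates_cl = current, init = init,
                          method = method, control = control)
  list(selected = current, fit = final, trace = do.call(rbind, trace))
}

#' Nonparametric bootstrap of the fitted model
#'
#' Resamples patients with replacement to the original cohort size and
#' refits the fixed final covariate structure on each replicate. Reports the
#' per-parameter median and percentile 2.5/97.5% CI over converged
#' replicates; a warning status is set when more than 20% of replicates
#' fail.
#'
#' @param dataset Event-record data frame.
#' @param covariates_cl Covariate structure of the final model.
#' @param n_replicates Number of bootstrap replicates (250 by default).
#' @param seed Integer seed for the resampling stream.
#' @param init Starting values for each refit (typically the final
#'   estimates).
#' @param method,control As in [fit_population()].
#' @return A `bootstrap_result` list: `summary` (data frame with median and
#'   CI per parameter), `n_replicates`, `n_failed`, `warning`, `replicates`
#'   (matrix of natural-scale estimates).
#' @export
bootstrap_population <- function(dataset, covariates_cl, n_replicates = 250,
                                 seed = 1L, init = NULL, method = "agh",
                                 control = list()) {
  ids <- unique(dataset$ID)
  n <- length(ids)
  rows_of <- split(seq_len(nrow(dataset)), dataset$ID)
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_replicates, replace = TRUE),
                  nrow = n_replicates)
  est <- list()
  n_failed <- 0
  for (r in seq_len(n_replicates)) {
    take <- draws[r, ]
    parts <- lapply(seq_along(take), function(j) {
      d <- dataset[rows_of[[as.character(ids[take[j]])]], , drop = FALSE]
      d$ID <- sprintf("B%04d", j)
      d
    })
    rep_data <- do.call(rbind, parts)
    f <- try(fit_population(rep_data, covariates_cl = covariates_cl,
                            init = init, method = method,
                            compute_rse = FALSE, control = control),
             silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) {
      n_failed <- n_failed + 1
      next
    }
    est[[length(est) + 1]] <- c(vd_pop = f$pop$vd_pop, cl_pop = f$pop$cl_pop,
                                f$pop$beta_cl[covariates_cl],
                                omega_vd = f$pop$omega_vd,
                                omega_cl = f$pop$omega_cl,
                                sigma_add = f$pop$sigma_add)
  }
  reps <- do.call(rbind, est)
  summ <- data.frame(
    parameter = colnames(reps),
    median = apply(reps, 2, stats::median),
    ci_lower = apply(reps, 2, stats::quantile, probs = 0.025),
    ci_upper = apply(reps, 2, stats::quantile, probs = 0.975),
    row.names = NULL)
  structure(list(summary = summ, n_replicates = n_replicates,
                 n_failed = n_failed,
                 warning = n_failed > 0.2 * n_replicates,
                 resample_indices = draws, replicates = reps),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates (%d failed%s)\n",
              x$n_replicates, x$n_failed,
              if (x$warning) ", WARNING: >20% failures" else ""))
  print(transform(x$summary, median = signif(median, 4),
                  ci_lower = signif(ci_lower, 4), ci_upper = signif(ci_upper, 4)))
  invisible(x)
}
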