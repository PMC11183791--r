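# Simulation-based goodness-of-fit: population/individual predictions,
# population-weighted residuals (PWRES), normalized prediction distribution
# errors (NPDE) and VPC-style percentile bands. All diagnostics are
# deterministic given (dataset, pop, n_sim, seed), and PWRES/NPDE share one
# simulation stream when computed together through gof_table().

.patient_structures <- function(dataset, pop) {
  prep <- .prep_dataset(dataset, names(pop$beta_cl))
  typ <- .typical_from_prep(prep, pop)
  pats <- lapply(seq_len(prep$n), function(i) {
    ei <- (prep$ev_ptr[i] + 1):prep$ev_ptr[i + 1]
    oi <- if (prep$obs_ptr[i + 1] > prep$obs_ptr[i])
      (prep$obs_ptr[i] + 1):prep$obs_ptr[i + 1] else integer()
    reg <- regimen(prep$ev_start[ei], prep$ev_rate[ei] * prep$ev_dur[ei],
                   prep$ev_dur[ei])
    list(id = prep$ids[i], reg = reg, times = prep$obs_t[oi],
         dv = prep$obs_y[oi], tvd = typ$tvd[i], tcl = typ$tcl[i])
  })
  pats
}

# Simulate n_sim replicates of every observation under the full model
# (new random effects per patient per replicate + residual error).
# Returns a list: `sim` (n_obs x n_sim matrix, rows in dataset observation
# order) and `obs` (observed values).
.simulate_observations <- function(pats, pop, n_sim) {
  blocks <- lapply(pats, function(p) {
    m <- length(p$times)
    if (m == 0) return(NULL)
    eta_vd <- stats::rnorm(n_sim, 0, pop$omega_vd)
    eta_cl <- stats::rnorm(n_sim, 0, pop$omega_cl)
    vd <- p$tvd * exp(eta_vd)
    cl <- p$tcl * exp(eta_cl)
    sim <- matrix(0, m, n_sim)
    for (j in seq_len(m)) {
      sim[j, ] <- .conc_many(p$times[j], p$reg, vd, cl)
    }
    sim + matrix(stats::rnorm(m * n_sim, 0, pop$sigma_add), m, n_sim)
  })
  list(sim = do.call(rbind, blocks),
       obs = unlist(lapply(pats, `[[`, "dv")),
       rows_per_patient = vapply(pats, function(p) length(p$times), 0L))
}

#' Population predictions
#'
#' Model prediction at zero random effects given each patient's regimen and
#' covariates, one value per observation row (dataset order).
#'
#' @param dataset Event-record data frame.
#' @param pop A `pop_params`.
#' @return Numeric vector of predicted concentrations (mg/L).
#' @export
population_predictions <- function(dataset, pop) {
  pats <- .patient_structures(dataset, pop)
  unlist(lapply(pats, function(p) {
    if (!length(p$times)) return(numeric())
    concentration(p$times, p$reg, p$tvd, p$tcl)
  }))
}

#' Population-weighted residuals
#'
#' `(y - mean(y_sim)) / sd(y_sim)` per observation, with the simulation
#' distribution generated under the full model (inter-individual +
#' residual variability).
#'
#' @inheritParams population_predictions
#' @param n_sim Number of simulation replicates (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of PWRES, one per observation.
#' @export
pwres <- function(dataset, pop, n_sim = 1000, seed = 1L) {
  pats <- .patient_structures(dataset, pop)
  set.seed(seed)
  sims <- .simulate_observations(pats, pop, n_sim)
  .pwres_from_sims(sims)
}

.pwres_from_sims <- function(sims) {
  mu <- rowMeans(sims$sim)
  sd_ <- apply(sims$sim, 1, stats::sd)
  if (any(sd_ == 0)) stop("degenerate simulated SD; model has no variability",
                          call. = FALSE)
  (sims$obs - mu) / sd_
}

#' Normalized prediction distribution errors
#'
#' Standard decorrelated-rank procedure: each patient's observed vector and
#' its simulated replicates are decorrelated with the simulated mean and
#' Cholesky factor of the simulated covariance; the NPDE is the standard
#' normal quantile of the decorrelated observation's mid-rank among its
#' decorrelated simulations (ranks clipped inside the open unit interval).
#' For one observation per patient this reduces to the quantile of the
#' marginal rank. A singular simulated covariance falls back to the
#' marginal (non-decorrelated) prediction-distribution rank with a warning.
#'
#' @inheritParams pwres
#' @return Numeric vector of NPDE, one per observation (dataset order).
#' @export
npde <- function(dataset, pop, n_sim = 1000, seed = 1L) {
  if (n_sim < 100) stop("`n_sim` must be >= 100", call. = FALSE)
  pats <- .patient_structures(dataset, pop)
  set.seed(seed)
  sims <- .simulate_observations(pats, pop, n_sim)
  .npde_from_sims(sims)
}

.npde_from_sims <- function(sims) {
  n_sim <- ncol(sims$sim)
  out <- numeric(0)
  offset <- 0
  for (m in sims$rows_per_patient) {
    if (m == 0) next
    rows <- offset + seq_len(m)
    offset <- offset + m
    Y <- sims$sim[rows, , drop = FALSE]
    y <- sims$obs[rows]
    mu <- rowMeans(Y)
    if (m > 1) {
      S <- stats::cov(t(Y))
      L <- try(chol(S), silent = TRUE)
      if (inherits(L, "try-error")) {
        warning("singular simulated covariance; falling back to marginal pd")
        ystar <- y
        Ystar <- Y
      } else {
        ystar <- backsolve(L, y - mu, transpose = TRUE)
        Ystar <- backsolve(L, Y - mu, transpose = TRUE)
      }
    } else {
      ystar <- y
      Ystar <- Y
    }
    for (j in seq_len(m)) {
      below <- sum(Ystar[j, ] < ystar[j])
      ties <- sum(Ystar[j, ] == ystar[j])
      pd <- (below + 0.5 * ties) / n_sim
      pd <- min(max(pd, 0.5 / n_sim), 1 - 0.5 / n_sim)
      out <- c(out, stats::qnorm(pd))
    }
  }
  out
}

#' Full diagnostic table
#'
#' One row per observation with population and individual (empirical-Bayes)
#' predictions, PWRES and NPDE. PWRES and NPDE are computed from the same
#' simulation stream.
#'
#' @inheritParams pwres
#' @return Data frame with columns `ID`, `TIME`, `DV`, `PRED`, `IPRED`,
#'   `PWRES`, `NPDE`.
#' @export
gof_table <- function(dataset, pop, n_sim = 1000, seed = 1L) {
  pats <- .patient_structures(dataset, pop)
  set.seed(seed)
  sims <- .simulate_observations(pats, pop, n_sim)
  ipred <- unlist(lapply(pats, function(p) {
    if (!length(p$times)) return(numeric())
    # typical values enter through a covariate-free pop with cl_pop = tcl
    mp <- map_estimate(p$reg, p$times, p$dv,
                       egfr = 0, lbm = 1,
                       pop = pop_params(p$tvd, p$tcl, numeric(),
                                        pop$omega_vd, pop$omega_cl,
                                        pop$sigma_add))
    concentration(p$times, p$reg, mp$vd, mp$cl)
  }))
  data.frame(
    ID = rep(vapply(pats, function(p) as.character(p$id), ""),
             times = sims$rows_per_patient),
    TIME = unlist(lapply(pats, `[[`, "times")),
    DV = sims$obs,
    PRED = population_predictions(dataset, pop),
    IPRED = ipred,
    PWRES = .pwres_from_sims(sims),
    NPDE = .npde_from_sims(sims))
}

#' VPC percentile bands
#'
#' Observed percentiles of the concentrations per time bin together with
#' the simulated 95% confidence band of each percentile. Bins are
#' quantile-based on observation times with at least `min_bin` observations
#' per bin; empty bins are dropped with a warning.
#'
#' @inheritParams pwres
#' @param percentiles Percentiles to band (default 10/50/90).
#' @param n_bins Number of time bins (quantile-based).
#' @param min_bin Minimum observations per bin.
#' @return Data frame with one row per bin x percentile: bin midpoint,
#'   observed percentile, simulated 2.5/97.5% band.
#' @export
vpc_percentiles <- function(dataset, pop, n_sim = 500,
                            percentiles = c(10, 50, 90), n_bins = 4,
                            min_bin = 10, seed = 1L) {
  pats <- .patient_structures(dataset, pop)
  set.seed(seed)
  sims <- .simulate_observations(pats, pop, n_sim)
  times <- unlist(lapply(pats, `[[`, "times"))
  n_bins <- max(1, min(n_bins, floor(length(times) / min_bin)))
  brk <- unique(stats::quantile(times, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(times, breaks = brk, include.lowest = TRUE)
  probs <- percentiles / 100
  out <- list()
  for (b in levels(bin)) {
    idx <- which(bin == b)
    if (!length(idx)) {
      warning("empty VPC bin dropped: ", b)
      next
    }
    obs_q <- stats::quantile(sims$obs[idx], probs = probs, names = FALSE)
    sim_q <- apply(sims$sim[idx, , drop = FALSE], 2, stats::quantile,
                   probs = probs, names = FALSE)
    sim_q <- matrix(sim_q, nrow = length(probs))
    lo <- apply(sim_q, 1, stats::quantile, probs = 0.025)
    hi <- apply(sim_q, 1, stats::quantile, probs = 0.975)
    out[[length(out) + 1]] <- data.frame(
      bin = b, time_mid = stats::median(times[idx]), n = length(idx),
      percentile = percentiles, observed = obs_q,
      sim_lower = lo, sim_upper = hi)
  }
  do.call(rbind, out)
}
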