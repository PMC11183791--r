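# Monte Carlo probability-of-target-attainment (PTA) engine: simulate
# individual 24-h AUCs under the population model for a covariate sample and
# a dosing regimen, score the fraction inside the AUC24 400-600 mg*h/L
# target (MIC 1 mg/L, so AUC/MIC reduces to AUC), and search a regimen grid
# for the stratum-optimal dosage.

.egfr_breaks <- c(0, 0.5, 1, 1.5, 2.13, Inf)
.lbm_breaks <- c(0, 70, Inf)

#' Stratum labels of the dosing grid
#'
#' Assigns each (eGFR, LBM) pair to the covariate stratum of the dosing
#' table: eGFR in {<0.5, 0.5-1, 1-1.5, 1.5-2.13, >2.13} mL/s/1.73 m^2 and
#' LBM split at 70 kg. Interval edges are half-open `[lower, upper)`, so
#' eGFR 1.5 falls in the 1.5-2.13 stratum and LBM 70 in the upper LBM
#' stratum.
#'
#' @param egfr eGFR values (mL/s/1.73 m^2), >= 0.
#' @param lbm LBM values (kg), > 0.
#' @return Character vector of stratum labels, e.g. `"0.5-1/<70"`.
#' @export
stratum_of <- function(egfr, lbm) {
  if (any(egfr < 0) || any(lbm <= 0)) stop("invalid covariates", call. = FALSE)
  ei <- findInterval(egfr, .egfr_breaks, rightmost.closed = FALSE)
  li <- findInterval(lbm, .lbm_breaks, rightmost.closed = FALSE)
  elab <- c("<0.5", "0.5-1", "1-1.5", "1.5-2.13", ">2.13")[ei]
  llab <- c("<70", ">70")[li]
  paste0(elab, "/", llab)
}

#' Published stratum-to-regimen dosing map
#'
#' The proposed dosing-individualization grid: per eGFR/LBM stratum a
#' loading dose, maintenance dose and interval.
#'
#' @return Data frame with columns `stratum`, `egfr_lo`, `egfr_hi`,
#'   `lbm_lo`, `lbm_hi`, `ld`, `md`, `interval`, `published_pta`.
#' @export
published_regimen_map <- function() {
  path <- system.file("extdata", "published_dosing_table.json", package = "vancopk",
                      mustWork = TRUE)
  obj <- jsonlite::fromJSON(path)
  rows <- obj$rows
  rows$egfr_hi[is.na(rows$egfr_hi)] <- Inf
  rows$lbm_hi[is.na(rows$lbm_hi)] <- Inf
  rows$stratum <- stratum_of(rows$egfr_lo, pmax(rows$lbm_lo, 1))
  rows
}

#' Recommended initial regimen for a patient
#'
#' Grid lookup in the published dosing table by eGFR/LBM stratum
#' (half-open `[lower, upper)` edges).
#'
#' @param egfr Creatinine-based eGFR (mL/s/1.73 m^2).
#' @param lbm Boer lean body mass (kg).
#' @param ld_duration,md_duration Infusion durations (h) used when the
#'   regimen is materialized.
#' @param horizon Simulation horizon (h).
#' @return A `regimen` with attributes `ld`, `md`, `interval`.
#' @examples
#' recommend_dose(0.8, 60)
#' @export
recommend_dose <- function(egfr, lbm, ld_duration = 2, md_duration = 2,
                           horizon = 60) {
  stopifnot(length(egfr) == 1, length(lbm) == 1)
  map <- published_regimen_map()
  row <- map[map$stratum == stratum_of(egfr, lbm), , drop = FALSE]
  reg <- build_regimen(row$ld, ld_duration, row$md, row$interval, md_duration,
                       horizon = horizon)
  attr(reg, "ld") <- row$ld
  attr(reg, "md") <- row$md
  attr(reg, "interval") <- row$interval
  reg
}

#' Simulate a 24-h AUC sample under the population model
#'
#' For each replicate x patient, draws random effects, forms the individual
#' PK parameters from the covariate-model typical values, evaluates the
#' analytic AUC over the scoring window of the simulated horizon, and
#' normalizes it to a per-24-h exposure (`AUC * 24 / (t2 - t1)`). The
#' default window is the full 60-h initial-treatment horizon; for a 24-h
#' window the normalization is the identity.
#'
#' @param pop A `pop_params`.
#' @param covariate_sample Data frame with columns `EGFR` and `LBM` (one row
#'   per patient).
#' @param reg A `regimen` shared by the sample.
#' @param window Length-2 scoring window (h), default `c(0, 60)`.
#' @param n_replicates Random-effect replicates per patient (default 250).
#' @param seed Integer seed (`NULL` to use the current stream).
#' @return Numeric vector of AUC24 draws (mg*h/L per 24 h), length
#'   `nrow(covariate_sample) * n_replicates`.
#' @export
simulate_auc <- function(pop, covariate_sample, reg, window = c(0, 60),
                         n_replicates = 250, seed = NULL) {
  if (!nrow(covariate_sample)) stop("empty covariate sample", call. = FALSE)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("`window` must be (t1, t2) with t1 < t2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  tcl <- typical_cl(covariate_sample$EGFR, covariate_sample$LBM, pop)
  m <- length(tcl) * n_replicates
  tcl <- rep(tcl, times = n_replicates)
  vd <- pop$vd_pop * exp(stats::rnorm(m, 0, pop$omega_vd))
  cl <- tcl * exp(stats::rnorm(m, 0, pop$omega_cl))
  .auc_window_many(window[1], window[2], reg, vd, cl) * 24 / (window[2] - window[1])
}

#' Probability of target attainment
#'
#' Fraction (in percent) of AUC draws inside the closed target interval.
#'
#' @param auc_sample Numeric vector of AUC draws (mg*h/L).
#' @param target Closed target interval, default `c(400, 600)`.
#' @return PTA in percent.
#' @export
pta <- function(auc_sample, target = c(400, 600)) {
  if (!length(auc_sample)) stop("empty AUC sample", call. = FALSE)
  100 * mean(auc_sample >= target[1] & auc_sample <= target[2])
}

#' Stratified PTA table under a dosing map
#'
#' Scores the per-stratum and pooled PTA when every patient of a covariate
#' population receives the regimen of their eGFR/LBM stratum. Strata with
#' fewer than `min_profiles` simulated profiles are flagged low-precision;
#' the overall row pools all patients under their stratum regimens (and
#' equals the patient-count-weighted mean of the stratum PTAs by
#' construction).
#'
#' @param pop A `pop_params`.
#' @param population Data frame with `EGFR` and `LBM` columns.
#' @param regimen_map Data frame as returned by [published_regimen_map()], or a
#'   single `regimen` applied uniformly to all patients.
#' @param window Scoring window (h).
#' @param n_replicates Replicates per patient.
#' @param seed Integer seed.
#' @param target AUC target interval.
#' @param min_profiles Low-precision threshold on simulated profiles per
#'   stratum.
#' @return A `data.frame` with one row per populated stratum plus an
#'   `"overall"` row: `stratum`, `label`, `n_patients`, `n_simulated`,
#'   `pta_percent`, `auc_median`, `auc_q25`, `auc_q75`, `low_precision`.
#' @export
pta_table <- function(pop, population, regimen_map = published_regimen_map(),
                      window = c(0, 60), n_replicates = 250, seed = 1L,
                      target = c(400, 600), min_profiles = 50) {
  set.seed(seed)
  strata <- stratum_of(population$EGFR, population$LBM)
  uniform <- inherits(regimen_map, "regimen")
  out <- list()
  pooled_in <- 0
  pooled_n <- 0
  for (s in unique(strata)) {
    subpop <- population[strata == s, , drop = FALSE]
    if (uniform) {
      reg <- regimen_map
    } else {
      row <- regimen_map[regimen_map$stratum == s, , drop = FALSE]
      if (!nrow(row)) stop("regimen map lacks stratum ", s, call. = FALSE)
      reg <- build_regimen(row$ld, 2, row$md, row$interval, 2,
                           horizon = max(window) + 12)
    }
    auc <- simulate_auc(pop, subpop, reg, window, n_replicates, seed = NULL)
    qs <- stats::quantile(auc, c(0.25, 0.5, 0.75), names = FALSE)
    hit <- sum(auc >= target[1] & auc <= target[2])
    pooled_in <- pooled_in + hit
    pooled_n <- pooled_n + length(auc)
    out[[length(out) + 1]] <- data.frame(
      stratum = s, label = attr(reg, "label"),
      n_patients = nrow(subpop), n_simulated = length(auc),
      pta_percent = 100 * hit / length(auc),
      auc_median = qs[2], auc_q25 = qs[1], auc_q75 = qs[3],
      low_precision = length(auc) < min_profiles)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$stratum), , drop = FALSE]
  overall <- data.frame(
    stratum = "overall", label = if (uniform) attr(regimen_map, "label") else "stratum map",
    n_patients = nrow(population), n_simulated = pooled_n,
    pta_percent = 100 * pooled_in / pooled_n,
    auc_median = NA_real_, auc_q25 = NA_real_, auc_q75 = NA_real_,
    low_precision = FALSE)
  rownames(tab) <- NULL
  rbind(tab, overall)
}

#' Overall PTA of a dosing policy
#'
#' Convenience wrapper: the pooled `"overall"` PTA row of [pta_table()].
#'
#' @inheritParams pta_table
#' @return Overall PTA in percent.
#' @export
overall_pta <- function(pop, population, regimen_map = published_regimen_map(),
                        window = c(0, 60), n_replicates = 250, seed = 1L,
                        target = c(400, 600)) {
  tab <- pta_table(pop, population, regimen_map, window, n_replicates, seed,
                   target)
  tab$pta_percent[tab$stratum == "overall"]
}

#' Default candidate regimen grid for dose optimization
#'
#' Loading doses 1500-3000 mg by 250, maintenance doses 500-1500 mg by 250,
#' intervals 6/8/12/24 h.
#'
#' @return Data frame with columns `ld`, `md`, `interval`.
#' @export
default_regimen_grid <- function() {
  expand.grid(ld = seq(1500, 3000, by = 250), md = seq(500, 1500, by = 250),
              interval = c(6, 8, 12, 24))
}

#' Stratum-optimal regimen search
#'
#' Evaluates the PTA of every candidate regimen on a stratum population
#' (common random numbers across candidates) and returns the maximizer.
#' Ties are broken by the lower total daily dose, then by the lower loading
#' dose.
#'
#' @param pop A `pop_params`.
#' @param stratum_population Data frame with `EGFR`, `LBM` for the stratum.
#' @param grid Candidate grid (data frame with `ld`, `md`, `interval`).
#' @param window Scoring window.
#' @param n_replicates Replicates per patient per candidate.
#' @param seed Integer seed (same draws reused for every candidate).
#' @return List with `best` (one-row data frame: ld, md, interval,
#'   pta_percent, daily_dose) and `grid` (all candidates with their PTA).
#' @export
optimize_regimen <- function(pop, stratum_population,
                             grid = default_regimen_grid(),
                             window = c(0, 60), n_replicates = 250,
                             seed = 1L) {
  if (!nrow(grid)) stop("empty candidate grid", call. = FALSE)
  tcl <- typical_cl(stratum_population$EGFR, stratum_population$LBM, pop)
  m <- length(tcl) * n_replicates
  set.seed(seed)
  zv <- stats::rnorm(m); zc <- stats::rnorm(m)
  vd <- pop$vd_pop * exp(pop$omega_vd * zv)
  cl <- rep(tcl, times = n_replicates) * exp(pop$omega_cl * zc)
  grid$pta_percent <- NA_real_
  grid$daily_dose <- grid$md * 24 / grid$interval
  for (g in seq_len(nrow(grid))) {
    reg <- build_regimen(grid$ld[g], 2, grid$md[g], grid$interval[g], 2,
                         horizon = max(window) + 12)
    auc <- .auc_window_many(window[1], window[2], reg, vd, cl) *
      24 / (window[2] - window[1])
    grid$pta_percent[g] <- 100 * mean(auc >= 400 & auc <= 600)
  }
  ord <- order(-grid$pta_percent, grid$daily_dose, grid$ld)
  list(best = grid[ord[1], , drop = FALSE], grid = grid)
}
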