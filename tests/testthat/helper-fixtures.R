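# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

pub_model <- published_params()

# A small synthetic TDM cohort reused across test files.
fix_cohort <- make_tdm_cohort(n = 40, pop = pub_model, seed = 101)

# Brute-force marginal -2 log-likelihood for a single patient by dense 2-D
# trapezoid quadrature over standardized random effects. Independent of the
# package's Laplace/AGH path: concentrations are recomputed from the
# closed-form infusion solution written out locally.
brute_neg2ll_patient <- function(reg, times, dv, tvd, tcl, pop,
                                 half_width = 6, n_grid = 401) {
  single_conc <- function(t, vd, cl) {
    ke <- cl / vd
    tot <- 0
    for (i in seq_len(nrow(reg))) {
      el <- t - reg$start[i]
      if (el <= 0) next
      tau1 <- min(el, reg$duration[i])
      tau2 <- max(el - reg$duration[i], 0)
      tot <- tot + (reg$rate[i] / cl) * (1 - exp(-ke * tau1)) * exp(-ke * tau2)
    }
    tot
  }
  z <- seq(-half_width, half_width, length.out = n_grid)
  h <- z[2] - z[1]
  logf <- matrix(0, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    vd <- tvd * exp(z[i] * pop$omega_vd)
    for (j in seq_len(n_grid)) {
      cl <- tcl * exp(z[j] * pop$omega_cl)
      cc <- vapply(times, single_conc, 0, vd = vd, cl = cl)
      logf[i, j] <- sum(stats::dnorm(dv, cc, pop$sigma_add, log = TRUE)) +
        stats::dnorm(z[i], log = TRUE) + stats::dnorm(z[j], log = TRUE)
    }
  }
  m <- max(logf)
  -2 * (m + log(sum(exp(logf - m))) + 2 * log(h))
}

# Extract one patient's regimen/observations from an event-record dataset.
patient_pieces <- function(dataset, id) {
  rows <- dataset[dataset$ID == id, ]
  d <- rows[rows$EVID == 1, ]
  o <- rows[rows$EVID == 0, ]
  list(reg = regimen(d$TIME, d$AMT, d$AMT / d$RATE),
       times = o$TIME, dv = o$DV,
       egfr = rows$EGFR[1], lbm = rows$LBM[1])
}

# Build an event-record data frame from explicit pieces (doses + observations
# + covariates), for hand-constructed test patients.
make_patient_data <- function(id, reg, times, dv, egfr = 1.5, lbm = 68,
                              sex = "male", age = 60, wt = 104, ht = 1.74,
                              scr = 72.3) {
  cov_cols <- data.frame(SEX = sex, AGE = age, WT = wt, HT = ht, SCR = scr,
                         CYSC = NA_real_, EGFR = egfr, LBM = lbm)
  dose <- data.frame(ID = id, TIME = reg$start, AMT = reg$amount,
                     RATE = reg$rate, EVID = 1L, DV = NA_real_, MDV = 1L,
                     cov_cols)
  if (length(times)) {
    obs <- data.frame(ID = id, TIME = times, AMT = 0, RATE = 0, EVID = 0L,
                      DV = dv, MDV = 0L, cov_cols)
    rbind(dose, obs)
  } else dose
}
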