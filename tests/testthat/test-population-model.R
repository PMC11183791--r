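test_that("typical clearance follows the exponential covariate model", {
  # worked example at the cohort medians: 1.32 * e^(0.61*1.51) * e^(0.011*68)
  expect_equal(typical_cl(1.51, 68, pub_model), 7.006, tolerance = 1e-3)
  # covariates at zero recover CL_pop
  expect_equal(typical_cl(0, 1e-9, pub_model), pub_model$cl_pop, tolerance = 1e-6)
  expect_equal(typical_cl(1.0, 70, pub_model), 1.32 * exp(0.61) * exp(0.77),
               tolerance = 1e-12)
  # strictly increasing in both covariates
  expect_true(all(diff(typical_cl(seq(0.2, 2.4, by = 0.2), 68, pub_model)) > 0))
  expect_true(all(diff(typical_cl(1.5, seq(45, 100, by = 5), pub_model)) > 0))
  expect_error(typical_cl(-0.1, 68, pub_model), ">= 0")
})

test_that("typical volume is covariate-independent", {
  expect_equal(typical_vd(pub_model), 75.0)
  expect_equal(typical_vd(pub_model, 5), rep(75, 5))
  # the median-covariate chain: CL 7 -> t1/2 7.4 h
  cl_med <- typical_cl(1.51, 68, pub_model)
  expect_equal(round(half_life(typical_vd(pub_model), cl_med), 1), 7.4)
})

test_that("individual sampling has the stated lognormal structure", {
  # zero variability collapses to the typical values
  p0 <- pop_params(75, 1.32, c(EGFR = 0.61, LBM = 0.011), 0, 0, 2.9)
  ind <- sample_individual(1.51, 68, p0, n = 10)
  expect_equal(ind$vd, rep(75, 10))
  expect_equal(ind$cl, rep(typical_cl(1.51, 68, p0), 10), tolerance = 1e-12)
  # over many draws the log deviations are centred and the median matches
  set.seed(42)
  big <- sample_individual(1.51, 68, pub_model, n = 1e5)
  tcl <- typical_cl(1.51, 68, pub_model)
  se <- pub_model$omega_cl / sqrt(1e5)
  expect_lt(abs(mean(log(big$cl) - log(tcl))), 3 * se)
  expect_lt(abs(stats::median(big$cl) / tcl - 1), 0.02)
})

test_that("the residual error model is additive with the stated SD", {
  p0 <- pop_params(75, 1.32, numeric(), 0.31, 0.28, 1e-12)
  x <- c(0, 5, 20)
  expect_equal(observe(x, p0), x, tolerance = 1e-9)
  set.seed(7)
  y <- observe(rep(10, 1e5), pub_model)
  expect_lt(abs(stats::sd(y - 10) - 2.9), 0.05)
  # Gaussian support allows negative observations at low true values
  set.seed(8)
  expect_true(any(observe(rep(0.5, 1000), pub_model) < 0))
})

test_that("MAP estimation returns the prior mode without data and recovers
           known effects from rich noise-free profiles", {
  reg <- build_regimen(2000, 2, 1000, 8, 2, horizon = 72)
  # no observations -> typical values
  m0 <- map_estimate(reg, numeric(), numeric(), 1.51, 68, pub_model)
  expect_equal(m0$eta_vd, 0)
  expect_equal(m0$eta_cl, 0)
  expect_equal(m0$vd, 75)
  # rich noise-free profile: 12 samples simulated from known eta, tiny sigma
  truth <- c(eta_vd = 0.25, eta_cl = -0.30)
  vd_i <- 75 * exp(truth["eta_vd"])
  cl_i <- typical_cl(1.51, 68, pub_model) * exp(truth["eta_cl"])
  times <- seq(2, 70, length.out = 12)
  dv <- concentration(times, reg, vd_i, cl_i)
  sharp <- pop_params(75, 1.32, c(EGFR = 0.61, LBM = 0.011),
                      pub_model$omega_vd, pub_model$omega_cl, 1e-6)
  m <- map_estimate(reg, times, dv, 1.51, 68, sharp)
  expect_lt(abs(m$eta_vd - truth["eta_vd"]), 0.01)
  expect_lt(abs(m$eta_cl - truth["eta_cl"]), 0.01)
  expect_true(m$converged)
  # the optimizer never ends above its starting objective
  expect_lte(m$objective, m$objective_init)
})

test_that("a single trough shrinks the estimate toward the population prior", {
  reg <- build_regimen(2000, 2, 1000, 8, 2, horizon = 72)
  tcl <- typical_cl(1.51, 68, pub_model)
  # simulate a patient whose clearance is well above typical
  cl_i <- tcl * exp(0.5)
  dv <- concentration(31.8, reg, 75, cl_i)
  m <- map_estimate(reg, 31.8, dv, 1.51, 68, pub_model)
  # EBE deviation from typical is smaller than the data-only deviation
  expect_lt(abs(log(m$cl) - log(tcl)), 0.5)
  expect_gt(log(m$cl) - log(tcl), 0)   # still pulled in the right direction
})

test_that("population parameters serialize to JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  write_pop_params(pub_model, path)
  back <- read_pop_params(path)
  expect_equal(back$vd_pop, pub_model$vd_pop)
  expect_equal(back$beta_cl, pub_model$beta_cl)
  expect_equal(back$sigma_add, pub_model$sigma_add)
  # shipped published estimates
  expect_equal(pub_model$vd_pop, 75.0)
  expect_equal(pub_model$cl_pop, 1.32)
  expect_equal(unname(pub_model$beta_cl["EGFR"]), 0.61)
  expect_equal(unname(pub_model$beta_cl["LBM"]), 0.011)
  expect_equal(pub_model$omega_vd, 0.31)
  expect_equal(pub_model$omega_cl, 0.28)
  expect_equal(pub_model$sigma_add, 2.9)
})
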