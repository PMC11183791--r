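test_that("population predictions equal the closed-form profile at eta = 0", {
  reg <- build_regimen(2000, 2, 1000, 8, 2, horizon = 72)
  times <- c(7.5, 31.8)
  d <- make_patient_data("X1", reg, times, dv = c(15, 12), egfr = 1.51, lbm = 68)
  pred <- population_predictions(d, pub_model)
  tcl <- typical_cl(1.51, 68, pub_model)
  expect_equal(pred, concentration(times, reg, 75, tcl), tolerance = 1e-12)
})

test_that("predictions are invariant to patient ordering", {
  d <- fix_cohort$dataset
  ids <- unique(d$ID)
  perm <- do.call(rbind, lapply(rev(ids), function(i) d[d$ID == i, ]))
  p1 <- population_predictions(d, pub_model)
  p2 <- population_predictions(perm, pub_model)
  obs1 <- d$DV[d$EVID == 0]
  obs2 <- perm$DV[perm$EVID == 0]
  expect_equal(p1[order(obs1)], p2[order(obs2)], tolerance = 1e-12)
})

test_that("PWRES is calibrated under the generating model and shrinks when
           the evaluating residual SD grows", {
  d <- fix_cohort$dataset
  w <- pwres(d, pub_model, n_sim = 1000, seed = 31)
  n <- length(w)
  expect_lt(abs(mean(w)), 3 / sqrt(n) * stats::sd(w) + 0.15)
  wide <- pop_params(pub_model$vd_pop, pub_model$cl_pop, pub_model$beta_cl,
                     pub_model$omega_vd, pub_model$omega_cl, 2 * pub_model$sigma_add)
  w2 <- pwres(d, wide, n_sim = 1000, seed = 31)
  expect_lt(mean(abs(w2)), mean(abs(w)))
})

test_that("NPDE reduces to the marginal rank for one observation per patient
           and is reproducible under a seed", {
  d <- fix_cohort$dataset
  x1 <- npde(d, pub_model, n_sim = 500, seed = 13)
  x2 <- npde(d, pub_model, n_sim = 500, seed = 13)
  expect_identical(x1, x2)
  # single-observation patients: marginal rank computed from the same stream
  pats <- vancopk:::.patient_structures(d, pub_model)
  set.seed(13)
  sims <- vancopk:::.simulate_observations(pats, pub_model, 500)
  one_obs <- which(sims$rows_per_patient == 1)
  row_of <- cumsum(sims$rows_per_patient)
  for (i in one_obs[1:5]) {
    r <- row_of[i]
    pd <- (sum(sims$sim[r, ] < sims$obs[r]) +
             0.5 * sum(sims$sim[r, ] == sims$obs[r])) / 500
    pd <- min(max(pd, 0.5 / 500), 1 - 0.5 / 500)
    expect_equal(x1[r], stats::qnorm(pd), tolerance = 1e-12)
  }
})

test_that("NPDE detects a halved-clearance misspecification with the
           expected sign", {
  d <- fix_cohort$dataset
  half_cl <- pop_params(pub_model$vd_pop, pub_model$cl_pop / 2, pub_model$beta_cl,
                        pub_model$omega_vd, pub_model$omega_cl, pub_model$sigma_add)
  x <- npde(d, half_cl, n_sim = 500, seed = 17)
  # halving CL makes the evaluating model predict higher concentrations, so
  # observations sit in the lower tail of the simulated distribution
  expect_lt(mean(x), -0.5)
  expect_lt(stats::t.test(x)$p.value, 1e-6)
})

test_that("gof_table assembles all diagnostics row-aligned", {
  d <- fix_cohort$dataset
  g <- gof_table(d, pub_model, n_sim = 300, seed = 19)
  expect_equal(nrow(g), sum(d$EVID == 0))
  expect_true(all(is.finite(g$NPDE)))
  expect_true(all(is.finite(g$PWRES)))
  expect_true(all(g$PRED >= 0))
  expect_true(all(g$IPRED >= 0))
  # individual predictions track the data more closely than population ones
  expect_lt(mean(abs(g$DV - g$IPRED)), mean(abs(g$DV - g$PRED)))
})

test_that("VPC percentile bands are ordered and collapse without variability", {
  d <- fix_cohort$dataset
  v <- vpc_percentiles(d, pub_model, n_sim = 300, seed = 23)
  for (b in unique(v$bin)) {
    sub <- v[v$bin == b, ]
    expect_true(all(diff(sub$observed) >= 0))     # p10 <= p50 <= p90
    expect_true(all(sub$sim_lower <= sub$sim_upper))
  }
  # degenerate model: bands collapse onto the deterministic profile
  p0 <- pop_params(pub_model$vd_pop, pub_model$cl_pop, pub_model$beta_cl,
                   1e-9, 1e-9, 1e-9)
  v0 <- vpc_percentiles(d, p0, n_sim = 100, seed = 29)
  expect_lt(max(v0$sim_upper - v0$sim_lower), 1e-6)
})

test_that("VPC observed percentiles fall inside the simulated bands most of
           the time under the generating model", {
  hits <- 0; total <- 0
  for (s in 1:4) {
    ck <- make_tdm_cohort(n = 40, pop = pub_model, seed = 400 + s)
    v <- vpc_percentiles(ck$dataset, pub_model, n_sim = 300, seed = s)
    hits <- hits + sum(v$observed >= v$sim_lower & v$observed <= v$sim_upper)
    total <- total + nrow(v)
  }
  expect_gt(hits / total, 0.80)
})
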