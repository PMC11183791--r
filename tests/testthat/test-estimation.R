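test_that("marginal likelihood reduces to the fixed-effects form as omega -> 0", {
  pp <- patient_pieces(fix_cohort$dataset, fix_cohort$population$ID[1])
  d1 <- fix_cohort$dataset[fix_cohort$dataset$ID == fix_cohort$population$ID[1], ]
  tiny <- pop_params(pub_model$vd_pop, pub_model$cl_pop, pub_model$beta_cl,
                     1e-6, 1e-6, pub_model$sigma_add)
  got <- as.numeric(neg2ll(tiny, d1, "laplace"))
  # closed-form Gaussian -2LL at the typical parameters
  tcl <- typical_cl(pp$egfr, pp$lbm, pub_model)
  mu <- concentration(pp$times, pp$reg, pub_model$vd_pop, tcl)
  ref <- -2 * sum(stats::dnorm(pp$dv, mu, pub_model$sigma_add, log = TRUE))
  expect_lt(abs(got - ref) / abs(ref), 1e-6)
})

test_that("Laplace and adaptive Gauss-Hermite agree with a dense quadrature
           oracle on single-patient data", {
  for (k in 1:3) {
    id <- fix_cohort$population$ID[k]
    d1 <- fix_cohort$dataset[fix_cohort$dataset$ID == id, ]
    pp <- patient_pieces(fix_cohort$dataset, id)
    tcl <- typical_cl(pp$egfr, pp$lbm, pub_model)
    oracle <- brute_neg2ll_patient(pp$reg, pp$times, pp$dv,
                                   pub_model$vd_pop, tcl, pub_model)
    expect_lt(abs(as.numeric(neg2ll(pub_model, d1, "laplace")) - oracle), 0.1)
    expect_lt(abs(as.numeric(neg2ll(pub_model, d1, "agh")) - oracle), 0.05)
  }
})

test_that("per-patient Laplace and AGH contributions stay close on a cohort", {
  # Laplace carries a small per-patient approximation error on sparse
  # additive-error data; AGH is the quadrature-verified reference
  ofv_l <- neg2ll(pub_model, fix_cohort$dataset, "laplace")
  ofv_a <- neg2ll(pub_model, fix_cohort$dataset, "agh")
  diffs <- abs(attr(ofv_l, "ofv_i") - attr(ofv_a, "ofv_i"))
  expect_lt(max(diffs), 0.3)
  expect_lt(mean(diffs), 0.05)
})

test_that("the likelihood is additive over independent patients", {
  d1 <- fix_cohort$dataset[fix_cohort$dataset$ID %in% fix_cohort$population$ID[1:5], ]
  d2 <- d1
  d2$ID <- paste0(d2$ID, "_copy")
  doubled <- rbind(d1, d2)
  expect_equal(as.numeric(neg2ll(pub_model, doubled)),
               2 * as.numeric(neg2ll(pub_model, d1)), tolerance = 1e-10)
})

test_that("fitting from the truth on informative data cannot worsen the OFV", {
  d <- fix_cohort$dataset
  ofv_init <- as.numeric(neg2ll(pub_model, d, "agh"))
  f <- fit_population(d, c("EGFR", "LBM"), init = pub_model, compute_rse = FALSE)
  expect_lte(f$ofv, ofv_init + 1e-6)
  expect_true(f$converged)
})

test_that("rich-design fits are consistent for every parameter group", {
  # 8 samples per patient, n = 120: the CL surface and variability
  # parameters should be recovered tightly, the collinear (cl_pop, beta)
  # decomposition within its sampling error
  set.seed(314)
  popn <- generate_population(120, seed = 314)
  regs <- generate_regimens(popn, seed = 315)
  rows <- lapply(seq_len(nrow(popn)), function(i) {
    pat <- popn[i, ]
    reg <- regs[[pat$ID]]
    ind <- sample_individual(pat$EGFR, pat$LBM, pub_model, 1)
    tms <- sort(stats::runif(8, 1, 70))
    dv <- observe(concentration(tms, reg, ind$vd, ind$cl), pub_model)
    make_patient_data(pat$ID, reg, tms, dv, pat$EGFR, pat$LBM)
  })
  d <- do.call(rbind, rows)
  f <- fit_population(d, c("EGFR", "LBM"), compute_rse = FALSE)
  expect_true(f$converged)
  expect_lt(abs(f$pop$vd_pop / 75 - 1), 0.10)
  expect_lt(abs(f$pop$omega_vd / 0.31 - 1), 0.25)
  expect_lt(abs(f$pop$omega_cl / 0.28 - 1), 0.25)
  expect_lt(abs(f$pop$sigma_add / 2.9 - 1), 0.10)
  expect_lt(abs(typical_cl(1.51, 68, f$pop) / typical_cl(1.51, 68, pub_model) - 1),
            0.05)
  expect_lt(abs(f$pop$beta_cl[["EGFR"]] / 0.61 - 1), 0.25)
  expect_lt(abs(f$pop$beta_cl[["LBM"]] / 0.011 - 1), 0.40)
})

test_that("covariate screening flags real predictors and respects edge cases", {
  f <- fit_population(fix_cohort$dataset, character(), compute_rse = FALSE)
  cov_tab <- fix_cohort$population
  scr <- covariate_screen(f, cov_tab, covariates = c("EGFR", "LBM", "AGE"))
  row <- scr[scr$parameter == "cl" & scr$covariate == "EGFR", ]
  expect_gt(row$pearson_r, 0)
  expect_lt(row$p_value, 0.05)
  expect_true(row$candidate)
  # a covariate exactly equal to the log-EBE correlates perfectly
  cov_tab$SELF <- log(f$ebes$cl[match(cov_tab$ID, f$ebes$ID)])
  scr2 <- covariate_screen(f, cov_tab, covariates = "SELF", parameters = "cl")
  expect_equal(scr2$pearson_r, 1, tolerance = 1e-9)
  expect_lt(scr2$p_value, 1e-20)
  # zero-variance covariate is reported but never a candidate
  cov_tab$CONST <- 5
  scr3 <- covariate_screen(f, cov_tab, covariates = "CONST")
  expect_true(all(is.na(scr3$pearson_r)))
  expect_false(any(scr3$candidate))
  # permuted covariate is null
  set.seed(11)
  cov_tab$PERM <- sample(cov_tab$EGFR)
  scr4 <- covariate_screen(f, cov_tab, covariates = "PERM", parameters = "cl")
  expect_lt(abs(scr4$pearson_r), 0.5)
})

test_that("stepwise selection returns the structural model for empty
           candidate sets and recovers the generating covariates", {
  d <- fix_cohort$dataset
  sel0 <- stepwise_selection(d, character())
  expect_identical(sel0$selected, character())
  expect_identical(sel0$fit$covariates, character())
  # on generated data the eGFR effect is strong enough at n = 40 to enter
  sel <- stepwise_selection(d, c("EGFR", "AGE"))
  expect_true("EGFR" %in% sel$selected)
  expect_false("AGE" %in% sel$selected)
  expect_true(all(c("phase", "model", "ofv", "dofv", "action") %in%
                    names(sel$trace)))
})

test_that("the bootstrap is deterministic under a seed and summarizes
           replicates sanely", {
  d <- fix_cohort$dataset
  f <- fit_population(d, "EGFR", compute_rse = FALSE)
  b1 <- bootstrap_population(d, "EGFR", n_replicates = 6, seed = 5, init = f$pop)
  b2 <- bootstrap_population(d, "EGFR", n_replicates = 6, seed = 5, init = f$pop)
  expect_identical(b1$resample_indices, b2$resample_indices)
  expect_equal(b1$replicates, b2$replicates)
  expect_true(all(b1$summary$ci_lower <= b1$summary$median + 1e-9))
  expect_true(all(b1$summary$median <= b1$summary$ci_upper + 1e-9))
  expect_lte(b1$n_failed, 6)
  # bootstrap medians stay in the neighbourhood of the point estimate
  vd_row <- b1$summary[b1$summary$parameter == "vd_pop", ]
  expect_lt(abs(vd_row$median / f$pop$vd_pop - 1), 0.25)
})
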