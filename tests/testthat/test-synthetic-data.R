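test_that("generated cohorts satisfy obesity eligibility and reproduce the
           published covariate marginals", {
  popn <- generate_population(500, seed = 211)
  expect_true(all(popn$BMI >= 30))
  # medians inside the published IQRs
  expect_true(stats::median(popn$WT) > 95 && stats::median(popn$WT) < 120)
  expect_true(stats::median(popn$HT) > 1.65 && stats::median(popn$HT) < 1.80)
  expect_true(stats::median(popn$LBM) > 55 && stats::median(popn$LBM) < 76)
  expect_true(stats::median(popn$BSA) > 2.02 && stats::median(popn$BSA) < 2.35)
  expect_true(stats::median(popn$EGFR) > 1.12 && stats::median(popn$EGFR) < 1.72)
  expect_true(stats::median(popn$SCR) > 55.8 && stats::median(popn$SCR) < 98.1)
  # headline marginals near the published medians at cohort size
  meds <- replicate(4, {
    pp <- generate_population(138, seed = sample.int(1e6, 1))
    c(wt = stats::median(pp$WT), egfr = stats::median(pp$EGFR))
  })
  expect_lt(max(abs(meds["wt", ] - 104)), 8)
  expect_lt(max(abs(meds["egfr", ] - 1.51)), 0.15)
  # sex ratio near 82/138
  expect_lt(abs(mean(popn$SEX == "male") - 82 / 138), 0.07)
})

test_that("cohort generation is reproducible under a fixed seed", {
  a <- generate_population(50, seed = 221)
  b <- generate_population(50, seed = 221)
  expect_identical(a, b)
  r1 <- generate_regimens(a, seed = 222)
  r2 <- generate_regimens(a, seed = 222)
  expect_identical(r1, r2)
  d1 <- generate_tdm_dataset(a, r1, pub_model, seed = 223)
  d2 <- generate_tdm_dataset(a, r1, pub_model, seed = 223)
  expect_identical(d1, d2)
})

test_that("regimens respect the reported dose grammar", {
  popn <- generate_population(400, seed = 231)
  regs <- generate_regimens(popn, seed = 232)
  lds <- mds <- ivs <- numeric()
  n_cont <- 0
  for (r in regs) {
    if (nrow(r) == 0) next
    if (any(r$duration > 36)) {           # continuous maintenance
      n_cont <- n_cont + 1
      next
    }
    if (r$start[1] == 0 && nrow(r) > 1 && r$amount[1] >= 1000) {
      lds <- c(lds, r$amount[1])
      md_ev <- r[-1, ]
    } else md_ev <- r
    if (nrow(md_ev) >= 2) {
      mds <- c(mds, md_ev$amount[1])
      ivs <- c(ivs, diff(md_ev$start)[1])
    }
  }
  expect_true(all(lds >= 1000 & lds <= 4000))
  expect_true(all(mds >= 500 & mds <= 1500))
  expect_true(all(ivs %in% c(6, 8, 12, 24)))
  expect_equal(stats::median(lds), 2500)
  expect_lt(abs(n_cont / length(regs) - 9 / 138), 0.05)
})

test_that("TDM datasets match the reported sampling design", {
  drawn <- 0; kept <- 0; types <- c(trough = 0, peak = 0, mid = 0)
  for (s in 1:4) {
    ck <- make_tdm_cohort(n = 138, pop = pub_model, seed = 240 + s)
    d <- ck$dataset
    obs <- d[d$EVID == 0, ]
    kept <- kept + nrow(obs)
    drawn <- drawn + nrow(obs) + attr(d, "n_bloq") + attr(d, "n_uloq")
    tt <- table(obs$TYPE)
    for (nm in names(tt)) types[nm] <- types[nm] + tt[nm]
    # all retained concentrations inside the assay range
    expect_true(all(obs$DV >= 4.0 & obs$DV <= 80.0))
    # all times inside the 72-h study window
    expect_true(all(obs$TIME >= 0 & obs$TIME <= 72))
  }
  # 1-2 samples per patient averaging ~147 drawn per 138 patients
  expect_lt(abs(drawn / 4 - 147), 12)
  # sampling-type mix within 5 points of 84.4 / 7.5 / 8.2
  frac <- 100 * types / sum(types)
  expect_lt(abs(frac["trough"] - 84.4), 5)
  expect_lt(abs(frac["peak"] - 7.5), 5)
  expect_lt(abs(frac["mid"] - 8.2), 5)
})

test_that("trough samples precede an upcoming dose by at most one hour", {
  ck <- make_tdm_cohort(n = 80, pop = pub_model, seed = 251)
  d <- ck$dataset
  obs <- d[d$EVID == 0 & d$TYPE == "trough", ]
  for (r in seq_len(nrow(obs))) {
    reg <- ck$regimens[[obs$ID[r]]]
    if (nrow(reg) == 1 && reg$duration[1] > 36) next   # continuous infusion
    gap <- reg$start - obs$TIME[r]
    gap <- gap[gap >= -1e-9]
    expect_true(length(gap) > 0 && min(gap) <= 1 + 1e-9)
  }
})

test_that("patients whose samples all fall outside the assay range keep
           their dose records and are flagged", {
  # force universal dropping with an absurd quantitation window
  sp <- sampling_spec(lloq = 1e6, uloq = 2e6)
  popn <- generate_population(10, seed = 261)
  regs <- generate_regimens(popn, seed = 262)
  d <- generate_tdm_dataset(popn, regs, pub_model, sampling = sp, seed = 263)
  expect_equal(sum(d$EVID == 0), 0)
  expect_true(all(popn$ID %in% d$ID))
  expect_setequal(attr(d, "flagged_ids"), popn$ID)
})
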