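# Adjustment models: OLS engine, Tukey-fence outliers, two-pass fits,
# residual computation.

test_that("least squares matches the normal-equations oracle", {
  for (s in 1:3) {
    dat <- tivadj:::with_seed(s, {
      design <- cbind(x1 = rnorm(50), x2 = runif(50, 10, 20), x3 = rnorm(50))
      list(design = design,
           response = rnorm(50, 5 + design %*% c(1, -2, 0.5), 1))
    })
    fit <- least_squares_fit(dat$design, dat$response)
    oracle <- normal_equations_fit(dat$design, dat$response)
    expect_equal(unname(fit$coefficients[rownames(oracle)]),
                 unname(oracle[, 1]), tolerance = 1e-8)
  }
})

test_that("exact polynomial responses are recovered exactly", {
  dat <- tivadj:::with_seed(11, {
    tiv <- runif(80, 1200, 1600); age <- runif(80, 20, 90)
    list(tiv = tiv, age = age)
  })
  truth <- c(a = 1e-5, b = -0.002, c = -1e-4, d = 0.7, e = -1.5, f = 250)
  y <- truth["a"] * dat$tiv^2 + truth["b"] * dat$age^2 +
    truth["c"] * dat$tiv * dat$age + truth["d"] * dat$tiv +
    truth["e"] * dat$age + truth["f"]
  design <- tivadj:::residual_design(dat$tiv, dat$age)
  fit <- least_squares_fit(design, y)
  co <- fit$coefficients[c(colnames(design), "(Intercept)")]
  expect_equal(unname(co), unname(truth), tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("constant response yields zero slopes and the constant intercept", {
  design <- cbind(x1 = 1:30, x2 = (1:30)^2)
  fit <- least_squares_fit(design, rep(7, 30))
  expect_equal(unname(fit$coefficients["(Intercept)"]), 7, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[c("x1", "x2")]), c(0, 0),
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  design <- cbind(x1 = 1:40, x_dup = 2 * (1:40))
  expect_error(least_squares_fit(design, rnorm(40)), "singular.*x_dup")
})

test_that("Tukey fences flag the hand-computed outlier set", {
  # type-7 quartiles of {-1,-0.5,0,0.5,1,10}: Q1 = -0.375, Q3 = 0.875,
  # fences at -2.25 and 2.75, so only the 10 is outside
  expect_equal(flag_outliers(c(-1, -0.5, 0, 0.5, 1, 10)), 6L)
  ids <- letters[1:6]
  expect_equal(flag_outliers(c(-1, -0.5, 0, 0.5, 1, 10), ids = ids), "f")
  # well-behaved symmetric sample: nothing flagged
  x <- tivadj:::with_seed(3, qnorm(ppoints(100)))
  expect_length(flag_outliers(x), 0)
  # degenerate spread: fences collapse onto the common value, still inside
  expect_length(flag_outliers(rep(2.5, 10)), 0)
  # a value exactly on the fence is inside it
  expect_length(flag_outliers(c(-1, -0.5, 0, 0.5, 1, 2.75)), 0)
})

test_that("two-pass residual fit keeps its bookkeeping identity", {
  db <- generate_normal_database(calibrated_params, 2000, seed = FIXED_SEED)
  for (roi in roi_labels()) {
    fr <- fit_residual_model(db, roi)
    expect_equal(fr$n_fit, nrow(db) - length(fr$outlier_ids))
    expect_setequal(c(fr$fit_ids, fr$outlier_ids), db$subject_id)
    expect_gt(fr$residual_sd, 0)
    expect_named(fr$coefficients, c("a", "b", "c", "d", "e", "f"))
  }
})

test_that("final-fit residuals are orthogonal to every model regressor", {
  db <- generate_normal_database(calibrated_params, 2000, seed = FIXED_SEED)
  for (roi in roi_labels()) {
    fr <- fit_residual_model(db, roi)
    fp <- fit_proportion_model(db, roi)
    adj <- compute_adjusted(fr, fp, db)
    kr <- db$subject_id %in% fr$fit_ids
    res <- adj$res_roiv_ml[kr]
    expect_lt(abs(mean(res)), 1e-8)
    for (reg in list(db$tiv_ml[kr], db$age[kr], db$tiv_ml[kr]^2,
                     db$age[kr]^2, db$tiv_ml[kr] * db$age[kr]))
      expect_lt(abs(cor(res, reg)), 1e-8)
    kp <- db$subject_id %in% fp$fit_ids
    resf <- adj$res_roif[kp]
    expect_lt(abs(cor(resf, db$age[kp])), 1e-8)
    expect_lt(abs(cor(resf, db$age[kp]^2)), 1e-8)
  }
})

test_that("a grossly inflated volume is flagged and barely moves the fit", {
  db <- generate_normal_database(calibrated_params, 1500, seed = FIXED_SEED)
  clean <- fit_residual_model(db, "THAL")
  spiked <- db
  spiked$thal_ml[10] <- spiked$thal_ml[10] * 3
  spiked$thal_ml[10] <- min(spiked$thal_ml[10], spiked$tiv_ml[10] * 0.99)
  fr <- fit_residual_model(spiked, "THAL")
  expect_true(db$subject_id[10] %in% fr$outlier_ids)
  expect_equal(unname(fr$coefficients), unname(clean$coefficients),
               tolerance = 0.05)
})

test_that("noise-free databases are fitted exactly with no outliers", {
  p <- manual_params(list(THAL = roi_spec(beta0 = 9, beta1 = 0.006,
                                          beta2 = -0.05, beta3 = -2e-5,
                                          beta4 = -1.5e-6)))
  db <- generate_normal_database(p, 400, seed = FIXED_SEED)
  fr <- fit_residual_model(db, "THAL")
  expect_length(fr$outlier_ids, 0)
  truth <- c(a = 0, b = -2e-5, c = -1.5e-6, d = 0.006, e = -0.05, f = 9)
  expect_equal(unname(fr$coefficients), unname(truth), tolerance = 1e-6)
  adj <- compute_adjusted(fr, fit_proportion_model(db, "THAL"), db)
  expect_lt(max(abs(adj$res_roiv_ml)), 1e-6)
})

test_that("pass two is a fixed point when it flags no new outliers", {
  # noise-free surface plus one gross outlier: pass 1 flags it, pass 2 is
  # exact, so re-flagging on pass-2 residuals finds only the same point
  # and a hypothetical third pass would change nothing
  p <- manual_params(list(BP = roi_spec(beta0 = 300, beta1 = 0.6,
                                        beta2 = -1)))
  db <- generate_normal_database(p, 200, seed = FIXED_SEED)
  db$bp_ml[5] <- db$bp_ml[5] * 0.5
  fr <- fit_residual_model(db, "BP")
  expect_equal(fr$outlier_ids, db$subject_id[5])
  adj <- compute_adjusted(fr, fit_proportion_model(db, "BP"), db)
  keep <- db$subject_id %in% fr$fit_ids
  reflagged <- flag_outliers(adj$res_roiv_ml[keep], ids = db$subject_id[keep],
                             tol = 1e-8 * sd(db$bp_ml[keep]))
  expect_length(reflagged, 0)
  refit <- fit_residual_model(db[keep, ], "BP")
  expect_equal(refit$coefficients, fr$coefficients, tolerance = 1e-8)
})

test_that("proportion residuals flip the TIV association when the intercept is positive", {
  # pure proportionality (zero intercept): fraction residuals carry no
  # TIV association beyond noise
  p0 <- manual_params(list(BP = roi_spec(beta0 = 0, beta1 = 0.8,
                                         sigma_eps = 20)))
  db0 <- generate_normal_database(p0, 5000, seed = FIXED_SEED)
  fp0 <- fit_proportion_model(db0, "BP")
  adj0 <- compute_adjusted(fit_residual_model(db0, "BP"), fp0, db0)
  k0 <- db0$subject_id %in% fp0$fit_ids
  expect_lt(abs(cor(adj0$res_roif[k0], db0$tiv_ml[k0])), 0.05)

  # positive intercept, no age terms, no noise: ROIF = slope + b0/TIV,
  # so the fraction residual is strictly negatively associated with TIV
  p1 <- manual_params(list(BP = roi_spec(beta0 = 400, beta1 = 0.5)))
  db1 <- generate_normal_database(p1, 500, seed = FIXED_SEED)
  fp1 <- fit_proportion_model(db1, "BP")
  adj1 <- compute_adjusted(fit_residual_model(db1, "BP"), fp1, db1)
  k1 <- db1$subject_id %in% fp1$fit_ids
  expect_lt(cor(adj1$res_roif[k1], db1$tiv_ml[k1]), -0.9)
})

test_that("calibrated fractions have the expected scale", {
  db <- generate_normal_database(calibrated_params, 5000, seed = FIXED_SEED)
  expect_equal(mean(db$bp_ml / db$tiv_ml), 0.813, tolerance = 0.005)
})

test_that("adjusted values follow the written-out residual arithmetic", {
  fit_res <- manual_model("residual", "BP",
                          c(a = 0, b = 0, c = 0, d = 0.8, e = -1, f = 100))
  fit_prop <- manual_model("proportion", "BP",
                           c(r = 0, s = 0, t = 0.8))
  subj <- data.frame(subject_id = "X1", age = 50, tiv_ml = 1400,
                     bp_ml = 1200)
  adj <- compute_adjusted(fit_res, fit_prop, subj)
  expect_equal(adj$res_roiv_ml, 1200 - (0.8 * 1400 - 1 * 50 + 100))  # 30 ml
  expect_equal(adj$res_roif, 1200 / 1400 - 0.8)
  expect_false(adj$extrapolation)
})

test_that("database subjects reproduce their own fit residuals; outsiders flag and fail softly", {
  db <- generate_normal_database(calibrated_params, 500, seed = FIXED_SEED)
  fr <- fit_residual_model(db, "BP")
  fp <- fit_proportion_model(db, "BP")
  adj <- compute_adjusted(fr, fp, db)
  keep <- db$subject_id %in% fr$fit_ids
  # non-outlier residuals have mean zero only as a refit property
  expect_lt(abs(mean(adj$res_roiv_ml[keep])), 1e-8)

  subj <- data.frame(
    subject_id = c("young", "nomeas"),
    age = c(15, 60), tiv_ml = c(1400, NA), bp_ml = c(1150, 1100)
  )
  adj2 <- compute_adjusted(fr, fp, subj)
  expect_true(adj2$extrapolation[1])
  expect_true(is.na(adj2$res_roiv_ml[2]))
  expect_match(adj2$note[2], "missing TIV")
})

test_that("fits refuse databases below the configurable floor", {
  db <- generate_normal_database(calibrated_params, 20, seed = 1)
  expect_error(fit_residual_model(db, "BP"), "at least 30")
  expect_s3_class(fit_residual_model(db, "BP", min_n = 15), "tivadj_model")
  expect_error(fit_residual_model(db[, c("subject_id", "age", "tiv_ml")],
                                  "BP", min_n = 15), "bp_ml")
})
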