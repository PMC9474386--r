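# Shared fixtures. All simulation tests use fixed seeds so the suite is
# deterministic; FIXED_SEED is the suite-wide default.

FIXED_SEED <- 424242

# Built-in calibration, computed once (closed form, cheap).
calibrated_params <- calibrate_generator()

# Hand-built generator parameters, bypassing calibration, for limit cases
# (noise-free, proportional, intercept-only, ...).
manual_params <- function(rois, tiv = list(mean = 1400, sd = 120),
                          age = list(mean = 50, sd = 15, min = 20, max = 90),
                          female_fraction = 0.5) {
  structure(list(rois = rois, tiv = tiv, age = age,
                 female_fraction = female_fraction),
            class = "tivadj_generator_params")
}

roi_spec <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0,
                     sigma_eps = 0) {
  list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
       beta4 = beta4, sigma_eps = sigma_eps)
}

# Hand-built fitted model object for arithmetic checks.
manual_model <- function(method, roi, coefficients, residual_sd = 1,
                         age_range = c(20, 90)) {
  structure(
    list(method = method, roi = roi, coefficients = coefficients,
         se = coefficients * NA, p_value = coefficients * NA,
         significant = rep(NA, length(coefficients)),
         outlier_ids = character(0), n_fit = NA_integer_,
         residual_sd = residual_sd, fit_ids = character(0),
         age_range = age_range, fence_k = 1.5, min_n = 30),
    class = "tivadj_model"
  )
}

# Brute-force normal-equations OLS: the independent oracle for lm-based
# fits. Columns are equilibrated by their norms before the explicit
# inversion so the oracle stays accurate on raw polynomial designs.
normal_equations_fit <- function(design, response) {
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  s <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, s, "/")
  beta <- solve(t(Xs) %*% Xs) %*% (t(Xs) %*% response) / s
  rownames(beta) <- colnames(X)
  beta
}

# Brute-force AUC: fraction of (patient, control) pairs correctly ordered
# on the higher-is-more-diseased orientation, ties counted one half.
pairwise_auc <- function(sp, sc) {
  total <- 0
  for (p in sp) for (c in sc)
    total <- total + (p > c) + 0.5 * (p == c)
  total / (length(sp) * length(sc))
}

# Trapezoidal integral of an ROC curve (sorted by fpr).
trapezoid_auc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  f <- curve$fpr[o]; t <- curve$tpr[o]
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}
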