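# Normative adjustment models.
#
# Residual method: regress ROIV on TIV^2, age^2, TIV*age, TIV, age in the
# normative database,
#   ROIV = a*TIV^2 + b*age^2 + c*TIV*age + d*TIV + e*age + f,
# and adjust any subject by the residual
#   resROIV = ROIV - model prediction.
#
# Proportion method: form the fraction ROIF = ROIV/TIV, regress it on a
# quadratic in age,
#   ROIF = r*age^2 + s*age + t,
# and adjust by resROIF = ROIF - model prediction.
#
# Both fits use a two-pass scheme: fit once, drop Tukey-fence outliers of
# the residual, refit once on the remainder (exactly two passes).

#' Ordinary least-squares fit with per-coefficient inference
#'
#' Thin wrapper around [stats::lm()] taking an explicit regressor matrix;
#' returns coefficients (intercept first), residuals over all input rows,
#' and standard t-based inference per coefficient. Rank-deficient designs
#' are an error naming the offending columns.
#'
#' @param design Numeric matrix or data frame of regressors (no intercept
#'   column; one is added).
#' @param response Numeric response vector, `nrow(design)` long.
#' @return List with `coefficients`, `residuals`, `fitted`, `se`,
#'   `t_value`, `p_value`, `sigma` (residual standard error), `df_residual`.
#' @export
least_squares_fit <- function(design, response) {
  design <- as.matrix(design)
  stopifnot(is.numeric(design), is.numeric(response),
            nrow(design) == length(response))
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (nrow(design) < ncol(design) + 3)
    stop("need at least two more subjects than coefficients")
  dat <- as.data.frame(design)
  dat$.response <- response
  fit <- stats::lm(.response ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular fit: collinear column(s) ", paste(bad, collapse = ", "))
  }
  # a noise-free response fits exactly; summary.lm's warning about it is
  # expected there and carries no information
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  ct <- sm$coefficients
  list(
    coefficients = stats::coef(fit),
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    se = ct[, "Std. Error"],
    t_value = ct[, "t value"],
    p_value = ct[, "Pr(>|t|)"],
    sigma = sm$sigma,
    df_residual = fit$df.residual
  )
}

#' Flag residual outliers by Tukey fences
#'
#' A residual is an outlier when it falls below `Q1 - k*IQR` or above
#' `Q3 + k*IQR`, with quartiles by linear interpolation of order
#' statistics ([stats::quantile()] type 7) and `k = 1.5` by default.
#' Values exactly on a fence are inside it.
#'
#' @param residuals Numeric vector (length >= 4).
#' @param ids Optional identifiers aligned with `residuals`; defaults to
#'   indices.
#' @param k Fence multiplier (> 0).
#' @param tol Numerical guard: a residual must exceed a fence by more
#'   than `tol` to be flagged. Defaults to 0; the model fits pass a tiny
#'   response-scale tolerance so that the rounding jitter of an exact
#'   (noise-free) fit is never treated as dispersion.
#' @return The ids of flagged outliers (possibly empty).
#' @export
#' @examples
#' flag_outliers(c(-1, -0.5, 0, 0.5, 1, 10))  # flags the 10
flag_outliers <- function(residuals, ids = NULL, k = 1.5, tol = 0) {
  stopifnot(is.numeric(residuals), length(residuals) >= 4, k > 0, tol >= 0)
  if (is.null(ids)) ids <- seq_along(residuals)
  stopifnot(length(ids) == length(residuals))
  q <- stats::quantile(residuals, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  ids[residuals < q[1] - k * iqr - tol | residuals > q[2] + k * iqr + tol]
}

# Design matrices of the two models.
residual_design <- function(tiv, age) {
  cbind(tiv_sq = tiv^2, age_sq = age^2, tiv_age = tiv * age,
        tiv = tiv, age = age)
}
proportion_design <- function(age) cbind(age_sq = age^2, age = age)

# Shared two-pass engine. `coef_map` maps lm terms to published names.
two_pass_fit <- function(design, response, ids, coef_names, intercept_name,
                         fence_k, alpha = 0.05) {
  pass1 <- least_squares_fit(design, response)
  # response-scale guard: never let pure rounding jitter define the fences
  tol <- 1e-8 * stats::sd(response)
  outlier_ids <- flag_outliers(pass1$residuals, ids = ids, k = fence_k,
                               tol = tol)
  keep <- !(ids %in% outlier_ids)
  pass2 <- least_squares_fit(design[keep, , drop = FALSE], response[keep])
  # reorder: lm puts the intercept first; published order puts it last
  co <- pass2$coefficients
  ord <- c(colnames(design), "(Intercept)")
  nm <- c(coef_names, intercept_name)
  list(
    coefficients = stats::setNames(co[ord], nm),
    se = stats::setNames(pass2$se[ord], nm),
    p_value = stats::setNames(pass2$p_value[ord], nm),
    significant = stats::setNames(pass2$p_value[ord] < alpha, nm),
    residuals = pass2$residuals,
    outlier_ids = outlier_ids,
    n_fit = sum(keep),
    residual_sd = stats::sd(pass2$residuals),
    fit_ids = ids[keep]
  )
}

# Pull validated tiv/age/volume vectors for one ROI out of a table.
fit_inputs <- function(db, roi, min_n) {
  col <- roi_column(roi)
  need <- c("subject_id", "age", "tiv_ml", col)
  missing_cols <- setdiff(need, names(db))
  if (length(missing_cols))
    stop("database lacks column(s): ", paste(missing_cols, collapse = ", "))
  ok <- stats::complete.cases(db[, need])
  db <- db[ok, , drop = FALSE]
  if (nrow(db) < min_n)
    stop("need at least ", min_n, " complete subjects to fit (have ",
         nrow(db), ")")
  db
}

new_tivadj_model <- function(method, roi, fit, age_range, fence_k, min_n) {
  structure(
    list(method = method, roi = roi,
         coefficients = fit$coefficients, se = fit$se,
         p_value = fit$p_value, significant = fit$significant,
         outlier_ids = fit$outlier_ids, n_fit = fit$n_fit,
         residual_sd = fit$residual_sd, fit_ids = fit$fit_ids,
         age_range = age_range, fence_k = fence_k, min_n = min_n),
    class = "tivadj_model"
  )
}

#' Fit the residual-method normative model for one ROI
#'
#' Two-pass ordinary least squares of the regional volume on TIV^2,
#' age^2, TIV*age, TIV and age: pass 1 on all subjects, Tukey-fence
#' outliers of the pass-1 residual excluded, pass 2 (final) on the
#' remainder. The reference residual SD — the z-score denominator — is
#' the SD of the pass-2 residuals over the non-outliers.
#'
#' @param db Volumetric data frame with `subject_id`, `age`, `tiv_ml` and
#'   the ROI's `<roi>_ml` column.
#' @param roi ROI label.
#' @param fence_k Tukey fence multiplier (default 1.5).
#' @param min_n Minimum number of complete subjects (default 30).
#' @return A `tivadj_model` with coefficients named `a` (TIV^2, ml/ml^2),
#'   `b` (age^2, ml/y^2), `c` (TIV*age, 1/y), `d` (TIV, dimensionless),
#'   `e` (age, ml/y), `f` (intercept, ml); plus `outlier_ids`, `n_fit`,
#'   `residual_sd` (ml), per-coefficient p-values and significance flags,
#'   and the fitting database's age range.
#' @export
fit_residual_model <- function(db, roi, fence_k = 1.5, min_n = 30) {
  db <- fit_inputs(db, roi, min_n)
  design <- residual_design(db$tiv_ml, db$age)
  fit <- two_pass_fit(design, db[[roi_column(roi)]], db$subject_id,
                      coef_names = c("a", "b", "c", "d", "e"),
                      intercept_name = "f", fence_k = fence_k)
  new_tivadj_model("residual", roi, fit, range(db$age), fence_k, min_n)
}

#' Fit the proportion-method age model for one ROI
#'
#' Divides the regional volume by TIV to obtain the fraction
#' `ROIF = ROIV/TIV`, then runs the same two-pass scheme on the quadratic
#' age model `ROIF = r*age^2 + s*age + t`. Outliers are flagged
#' separately from the residual method. The residual SD is on the
#' fraction scale.
#'
#' @inheritParams fit_residual_model
#' @return A `tivadj_model` with coefficients `r` (1/y^2), `s` (1/y),
#'   `t` (dimensionless fraction).
#' @export
fit_proportion_model <- function(db, roi, fence_k = 1.5, min_n = 30) {
  db <- fit_inputs(db, roi, min_n)
  frac <- db[[roi_column(roi)]] / db$tiv_ml
  fit <- two_pass_fit(proportion_design(db$age), frac, db$subject_id,
                      coef_names = c("r", "s"),
                      intercept_name = "t", fence_k = fence_k)
  new_tivadj_model("proportion", roi, fit, range(db$age), fence_k, min_n)
}

#' Model prediction for given TIV and age
#'
#' Evaluates the fitted normative surface: the expected regional volume
#' (ml, residual method) or fraction (proportion method).
#'
#' @param object A `tivadj_model`.
#' @param tiv,age Numeric vectors (recycled to common length). `tiv` is
#'   ignored by proportion-method models.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.tivadj_model <- function(object, tiv, age, ...) {
  co <- object$coefficients
  if (object$method == "residual") {
    co[["a"]] * tiv^2 + co[["b"]] * age^2 + co[["c"]] * tiv * age +
      co[["d"]] * tiv + co[["e"]] * age + co[["f"]]
  } else {
    co[["r"]] * age^2 + co[["s"]] * age + co[["t"]]
  }
}

#' @export
print.tivadj_model <- function(x, ...) {
  cat(sprintf("Normative %s-method model for %s\n", x$method, x$roi))
  cat(sprintf("  n_fit = %d (%d outlier%s excluded), residual SD = %.6g %s\n",
              x$n_fit, length(x$outlier_ids),
              if (length(x$outlier_ids) == 1) "" else "s",
              x$residual_sd,
              if (x$method == "residual") "ml" else "(fraction)"))
  co <- x$coefficients
  flag <- ifelse(x$significant, "*", " ")
  for (i in seq_along(co))
    cat(sprintf("  %s = %.6g%s\n", names(co)[i], co[i], flag[i]))
  cat("  (* coefficient p < 0.05, two-sided t-test)\n")
  invisible(x)
}

#' Compute adjusted values (residual and proportion method) for subjects
#'
#' Evaluates both fitted models on arbitrary subjects — typically
#' patients not in the fitting database — giving each subject's
#' residual-method residual `res_roiv_ml` and proportion-method residual
#' `res_roif`. Subjects whose age falls outside the fitting database's
#' age range are flagged as extrapolations; subjects with missing inputs
#' get an error note instead of aborting the run.
#'
#' @param fit_res Residual-method `tivadj_model`.
#' @param fit_prop Proportion-method `tivadj_model` for the same ROI.
#' @param subjects Volumetric data frame.
#' @return Data frame: `subject_id`, `roi`, `age`, `tiv_ml`,
#'   `res_roiv_ml`, `res_roif`, `extrapolation` (logical), `note`
#'   (NA or the reason a subject could not be scored).
#' @export
compute_adjusted <- function(fit_res, fit_prop, subjects) {
  stopifnot(inherits(fit_res, "tivadj_model"), fit_res$method == "residual",
            inherits(fit_prop, "tivadj_model"), fit_prop$method == "proportion")
  if (fit_res$roi != fit_prop$roi)
    stop("models are for different ROIs: ", fit_res$roi, " vs ", fit_prop$roi)
  roi <- fit_res$roi
  col <- roi_column(roi)
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))

  n <- nrow(subjects)
  age <- if ("age" %in% names(subjects)) subjects$age else rep(NA_real_, n)
  tiv <- if ("tiv_ml" %in% names(subjects)) subjects$tiv_ml else rep(NA_real_, n)
  vol <- if (col %in% names(subjects)) subjects[[col]] else rep(NA_real_, n)

  note <- rep(NA_character_, n)
  note[is.na(age)] <- "missing age"
  note[is.na(tiv)] <- "missing TIV"
  note[is.na(vol)] <- paste0("missing ", col)
  ok <- is.na(note)

  res_v <- res_f <- rep(NA_real_, n)
  res_v[ok] <- vol[ok] - predict(fit_res, tiv[ok], age[ok])
  res_f[ok] <- vol[ok] / tiv[ok] - predict(fit_prop, tiv[ok], age[ok])
  extrap <- !is.na(age) &
    (age < fit_res$age_range[1] | age > fit_res$age_range[2])

  data.frame(
    subject_id = subjects$subject_id, roi = roi,
    age = age, tiv_ml = tiv,
    res_roiv_ml = res_v, res_roif = res_f,
    extrapolation = extrap, note = note,
    stringsAsFactors = FALSE
  )
}
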