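# z-scoring of adjusted values.
#
# Residuals are scaled to the SD of the residuals in the normative
# database (the pass-2, non-outlier SD stored in the fitted model), never
# to the target cohort's own SD:
#   z-resROIV = resROIV / SD(resROIV in database)
#   z-resROIF = resROIF / SD(resROIF in database)
# and the method-comparison statistic is the per-subject difference
#   z-diff = z-resROIF - z-resROIV
# (proportion-method z minus residual-method z).

#' Standardize residuals by a reference SD
#'
#' @param values Numeric residuals.
#' @param reference_sd Positive scalar: the normative database's
#'   non-outlier residual SD, in the same units as `values`.
#' @return z-scores (`values / reference_sd`).
#' @export
standardize <- function(values, reference_sd) {
  if (!is_number(reference_sd) || reference_sd <= 0)
    stop("reference_sd must be a positive number")
  values / reference_sd
}

#' Per-subject z-score difference between adjustment methods
#'
#' @param z_prop z-scores from the proportion method (`z-resROIF`).
#' @param z_res z-scores from the residual method (`z-resROIV`).
#' @return `z_prop - z_res`, elementwise; NA where either is missing.
#' @export
z_difference <- function(z_prop, z_res) {
  stopifnot(length(z_prop) == length(z_res))
  z_prop - z_res
}

#' Score subjects against fitted normative models
#'
#' Composes [compute_adjusted()] and [standardize()]: every subject gets
#' residual- and proportion-method residuals, the corresponding z-scores
#' (scaled by each model's stored database residual SD), and their
#' difference `z_diff`. Subjects are never outlier-filtered here and are
#' never refit; they are scored against the frozen database models.
#'
#' @inheritParams compute_adjusted
#' @return Data frame (one row per subject): `subject_id`, `roi`, `age`,
#'   `tiv_ml`, `res_roiv_ml`, `res_roif`, `z_res_roiv`, `z_res_roif`,
#'   `z_diff`, `extrapolation`, `note`.
#' @export
#' @examples
#' params <- calibrate_generator()
#' db <- generate_normal_database(params, n = 300, seed = 7)
#' fr <- fit_residual_model(db, "THAL")
#' fp <- fit_proportion_model(db, "THAL")
#' panel <- score_subjects(fr, fp, db[1:5, ])
#' panel$z_diff
score_subjects <- function(fit_res, fit_prop, subjects) {
  adj <- compute_adjusted(fit_res, fit_prop, subjects)
  adj$z_res_roiv <- standardize(adj$res_roiv_ml, fit_res$residual_sd)
  adj$z_res_roif <- standardize(adj$res_roif, fit_prop$residual_sd)
  adj$z_diff <- z_difference(adj$z_res_roif, adj$z_res_roiv)
  adj[, c("subject_id", "roi", "age", "tiv_ml", "res_roiv_ml", "res_roif",
          "z_res_roiv", "z_res_roif", "z_diff", "extrapolation", "note")]
}
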