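# Evaluation battery: coefficient of variation before/after adjustment,
# residual-nuisance correlations, z-diff summaries, residual normality
# QC, and ROC/AUC for patient-vs-control discrimination.

#' Coefficient of variation (percent)
#'
#' `CoV% = 100 * SD(values) / reference_mean`. For residuals (which have
#' mean ~0) the reference mean must be supplied as the mean of the
#' corresponding raw measure, so that raw and adjusted CoVs are on the
#' same footing.
#'
#' @param values Numeric vector.
#' @param reference_mean Reference mean; defaults to `mean(values)`.
#' @return CoV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(10, 12, 14))
coefficient_of_variation <- function(values, reference_mean = NULL) {
  if (is.null(reference_mean)) reference_mean <- mean(values)
  if (!is_number(reference_mean) || reference_mean == 0)
    stop("reference mean must be a non-zero finite number")
  100 * stats::sd(values) / reference_mean
}

#' Pearson correlation with a nuisance covariate
#'
#' @param values Numeric vector (e.g. adjusted volumes).
#' @param covariate Numeric vector (TIV or age).
#' @param sig_threshold Two-sided p-value threshold for the significance
#'   flag (default 1e-4).
#' @return List with `r`, `p`, `significant`.
#' @export
correlation_with_nuisance <- function(values, covariate, sig_threshold = 1e-4) {
  stopifnot(length(values) == length(covariate), length(values) >= 3)
  if (stats::sd(values) == 0 || stats::sd(covariate) == 0)
    stop("zero variance in values or covariate")
  ct <- stats::cor.test(values, covariate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < sig_threshold)
}

#' Summarize the z-score difference between adjustment methods
#'
#' Per ROI: mean, 95th percentile (linear-interpolation quantile) and
#' maximum of `|z_diff|`, the fraction of subjects with `|z_diff| > 1`,
#' and Pearson correlations of the signed `z_diff` with TIV and age.
#'
#' @param panel A panel from [score_subjects()] (needs `roi`, `z_diff`,
#'   `tiv_ml`, `age`).
#' @return Data frame, one row per ROI: `roi`, `n`, `mean_abs`, `p95_abs`,
#'   `max_abs`, `frac_gt1`, `r_tiv`, `r_age`.
#' @export
zdiff_summary <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("roi", "z_diff", "tiv_ml", "age") %in% names(panel)))
  panel <- panel[!is.na(panel$z_diff), , drop = FALSE]
  if (nrow(panel) < 20)
    warning("z-diff summary over fewer than 20 subjects is unstable")
  out <- lapply(split(panel, panel$roi), function(p) {
    a <- abs(p$z_diff)
    data.frame(
      roi = p$roi[1], n = nrow(p),
      mean_abs = mean(a),
      p95_abs = stats::quantile(a, 0.95, names = FALSE, type = 7),
      max_abs = max(a),
      frac_gt1 = mean(a > 1),
      r_tiv = if (nrow(p) >= 3 && stats::sd(p$z_diff) > 0)
        stats::cor(p$z_diff, p$tiv_ml) else NA_real_,
      r_age = if (nrow(p) >= 3 && stats::sd(p$z_diff) > 0)
        stats::cor(p$z_diff, p$age) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Residual normality quality control
#'
#' Advisory moment-based check of the normative residuals: sample
#' skewness and excess kurtosis with a configurable pass band. A named
#' hypothesis test is deliberately not used — at normative-database
#' sample sizes any formal test rejects trivially.
#'
#' @param residuals Numeric vector (>= 20 values).
#' @param skew_band,kurt_band Half-widths of the pass bands (defaults
#'   0.5 and 1).
#' @return List with `skewness`, `excess_kurtosis`, `pass`.
#' @export
normality_qc <- function(residuals, skew_band = 0.5, kurt_band = 1) {
  stopifnot(is.numeric(residuals), length(residuals) >= 20)
  sk <- e1071::skewness(residuals)
  ku <- e1071::kurtosis(residuals)  # already excess kurtosis
  list(skewness = sk, excess_kurtosis = ku,
       pass = abs(sk) < skew_band && abs(ku) < kurt_band)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random patient scores more "diseased"
#' than a random control, computed from mid-ranks (ties count one half).
#' For z-scores of regional volumes, lower z means atrophy, so the
#' default `direction = "low"` flips the sign internally and the AUC is
#' always reported on the higher-score-is-more-diseased orientation.
#' Curve points are returned at every distinct threshold.
#'
#' @param scores_patients,scores_controls Numeric score vectors.
#' @param direction `"low"` if low scores indicate disease (default, the
#'   z-score convention) or `"high"`.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`, on the oriented scale).
#' @export
#' @examples
#' roc_auc(c(-3, -2.5, -1), c(0, 0.5, 1))$auc  # perfect separation -> 1
roc_auc <- function(scores_patients, scores_controls,
                    direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(length(scores_patients) >= 1, length(scores_controls) >= 1,
            all(is.finite(scores_patients)), all(is.finite(scores_controls)))
  sp <- if (direction == "low") -scores_patients else scores_patients
  sc <- if (direction == "low") -scores_controls else scores_controls
  np <- length(sp); nc <- length(sc)
  r <- rank(c(sp, sc))  # mid-ranks for ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nc)
  thresholds <- sort(unique(c(sp, sc)), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thresholds),
    fpr = c(0, vapply(thresholds, function(t) mean(sc >= t), numeric(1))),
    tpr = c(0, vapply(thresholds, function(t) mean(sp >= t), numeric(1)))
  )
  list(auc = auc, curve = curve, direction = direction)
}

# -- report assembly ---------------------------------------------------------

# Table-1-style statistics for one ROI and one method over the method's
# non-outlier fitting subjects.
method_table_rows <- function(db, roi, fit, adj, scale) {
  col <- roi_column(roi)
  keep <- db$subject_id %in% fit$fit_ids
  raw <- if (scale == "volume") db[[col]][keep] else
    db[[col]][keep] / db$tiv_ml[keep]
  res <- if (scale == "volume") adj$res_roiv_ml[keep] else adj$res_roif[keep]
  tiv <- db$tiv_ml[keep]; age <- db$age[keep]
  row <- function(adjustment, v) {
    rt <- correlation_with_nuisance(v, tiv)
    ra <- correlation_with_nuisance(v, age)
    data.frame(
      roi = roi, method = if (scale == "volume") "residual" else "proportion",
      adjustment = adjustment, n = sum(keep),
      mean = mean(v), sd = stats::sd(v),
      cov_pct = coefficient_of_variation(v, reference_mean = mean(raw)),
      r_tiv = rt$r, sig_tiv = rt$significant,
      r_age = ra$r, sig_age = ra$significant,
      stringsAsFactors = FALSE
    )
  }
  rbind(row("raw", raw), row("adjusted", res))
}

#' Assemble the full method-comparison report
#'
#' Runs the complete battery for each ROI: fits both adjustment models
#' on the normative database, tabulates mean/SD/CoV and nuisance
#' correlations for raw and adjusted values over each method's
#' non-outlier subjects, summarizes the z-score difference over the whole
#' database, checks residual normality, and — when a patient cohort is
#' supplied — computes the ROC AUC of each method's z-score for
#' patient-vs-control discrimination (controls are the non-outlier
#' database subjects of the respective method).
#'
#' @param db Normative volumetric data frame.
#' @param patients Optional patient volumetric data frame.
#' @param rois ROI labels to analyse (default the built-in three).
#' @param fence_k,min_n Passed to the model fits.
#' @param qc_skew_band,qc_kurt_band Passed to [normality_qc()].
#' @return A `tivadj_report`: list with data frames `table` (per
#'   ROI x method x raw/adjusted), `zdiff` (per ROI), `normality`,
#'   optional `auc`, and the fitted `models`.
#' @export
build_report <- function(db, patients = NULL, rois = roi_labels(),
                         fence_k = 1.5, min_n = 30,
                         qc_skew_band = 0.5, qc_kurt_band = 1) {
  stopifnot(length(rois) >= 1)
  missing_cols <- setdiff(roi_column(rois), names(db))
  if (length(missing_cols))
    stop("database lacks ROI column(s): ", paste(missing_cols, collapse = ", "))
  if (!is.null(patients)) {
    missing_p <- setdiff(roi_column(rois), names(patients))
    if (length(missing_p))
      stop("patient table lacks ROI column(s): ",
           paste(missing_p, collapse = ", "))
  }

  tables <- list(); zrows <- list(); qc <- list(); aucs <- list()
  models <- list()
  for (roi in rois) {
    fr <- fit_residual_model(db, roi, fence_k = fence_k, min_n = min_n)
    fp <- fit_proportion_model(db, roi, fence_k = fence_k, min_n = min_n)
    models[[roi]] <- list(residual = fr, proportion = fp)
    panel <- score_subjects(fr, fp, db)
    tables[[roi]] <- rbind(
      method_table_rows(db, roi, fr, panel, scale = "volume"),
      method_table_rows(db, roi, fp, panel, scale = "fraction")
    )
    zrows[[roi]] <- zdiff_summary(panel)
    qc_res <- normality_qc(panel$res_roiv_ml[panel$subject_id %in% fr$fit_ids],
                           qc_skew_band, qc_kurt_band)
    qc_prop <- normality_qc(panel$res_roif[panel$subject_id %in% fp$fit_ids],
                            qc_skew_band, qc_kurt_band)
    qc[[roi]] <- data.frame(
      roi = roi, method = c("residual", "proportion"),
      skewness = c(qc_res$skewness, qc_prop$skewness),
      excess_kurtosis = c(qc_res$excess_kurtosis, qc_prop$excess_kurtosis),
      pass = c(qc_res$pass, qc_prop$pass),
      stringsAsFactors = FALSE
    )
    if (!is.null(patients) && nrow(patients) > 0) {
      ppanel <- score_subjects(fr, fp, patients)
      cpanel <- panel
      roc_v <- roc_auc(ppanel$z_res_roiv,
                       cpanel$z_res_roiv[cpanel$subject_id %in% fr$fit_ids])
      roc_f <- roc_auc(ppanel$z_res_roif,
                       cpanel$z_res_roif[cpanel$subject_id %in% fp$fit_ids])
      aucs[[roi]] <- data.frame(
        roi = roi, auc_residual = roc_v$auc, auc_proportion = roc_f$auc,
        n_patients = nrow(patients), stringsAsFactors = FALSE
      )
    }
  }
  rbindr <- function(x) { y <- do.call(rbind, x); rownames(y) <- NULL; y }
  structure(
    list(table = rbindr(tables), zdiff = rbindr(zrows),
         normality = rbindr(qc),
         auc = if (length(aucs)) rbindr(aucs) else NULL,
         models = models, rois = rois),
    class = "tivadj_report"
  )
}

#' @export
print.tivadj_report <- function(x, digits = 2, ...) {
  cat("Normative adjustment report\n")
  cat("===========================\n\n")
  cat("Per-ROI statistics (adjusted rows over each method's non-outlier subjects;\n")
  cat("CoV of adjusted values referenced to the raw mean; * marks p < 1e-4):\n\n")
  tab <- x$table
  for (m in unique(tab$method)) {
    cat(sprintf("%s method (%s scale)\n", m,
                if (m == "residual") "volume, ml" else "fraction of TIV"))
    sub <- tab[tab$method == m, ]
    cat(sprintf("  %-5s %-9s %6s %10s %9s %7s %7s %7s\n",
                "ROI", "values", "n", "mean", "SD", "CoV%", "r_TIV", "r_age"))
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      cat(sprintf("  %-5s %-9s %6d %10.4g %9.4g %7.2f %6.2f%s %6.2f%s\n",
                  r$roi, r$adjustment, r$n, r$mean, r$sd, r$cov_pct,
                  r$r_tiv, ifelse(r$sig_tiv, "*", " "),
                  r$r_age, ifelse(r$sig_age, "*", " ")))
    }
    cat("\n")
  }
  cat("abs(z-diff) of proportion vs residual method z-scores:\n")
  cat(sprintf("  %-5s %6s %8s %8s %8s %8s %7s %7s\n",
              "ROI", "n", "mean", "p95", "max", ">1", "r_TIV", "r_age"))
  for (i in seq_len(nrow(x$zdiff))) {
    r <- x$zdiff[i, ]
    cat(sprintf("  %-5s %6d %8.2f %8.2f %8.2f %7.1f%% %7.2f %7.2f\n",
                r$roi, r$n, r$mean_abs, r$p95_abs, r$max_abs,
                100 * r$frac_gt1, r$r_tiv, r$r_age))
  }
  if (!is.null(x$auc)) {
    cat("\nPatient-vs-control discrimination (AUC, lower z = atrophy):\n")
    for (i in seq_len(nrow(x$auc))) {
      r <- x$auc[i, ]
      cat(sprintf("  %-5s residual %.3f  proportion %.3f  (%d patients)\n",
                  r$roi, r$auc_residual, r$auc_proportion, r$n_patients))
    }
  }
  invisible(x)
}
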