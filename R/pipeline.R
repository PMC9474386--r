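# End-to-end pipeline: simulate -> fit -> score -> evaluate.

#' Build a validated pipeline configuration
#'
#' @param seed Top-level integer seed; every stage derives its own
#'   substream via [stage_seed()].
#' @param rois ROI labels to process.
#' @param n_normal Normative database size (default 5059).
#' @param n_patients Patient cohort size (default 127); 0 disables the
#'   patient arm.
#' @param atrophy Named per-ROI fractional volume reduction for the
#'   patient cohort.
#' @param fence_k Tukey fence multiplier (> 0).
#' @param min_n Fit floor: minimum complete subjects per fit.
#' @param qc_skew_band,qc_kurt_band Normality QC pass bands.
#' @param generator Optional `tivadj_generator_params`; default is the
#'   built-in normative calibration restricted to `rois`.
#' @param out_dir Output directory (created if absent).
#' @return A `tivadj_config` list.
#' @export
pipeline_config <- function(seed = 1, rois = roi_labels(),
                            n_normal = 5059, n_patients = 127,
                            atrophy = c(THAL = 0.10),
                            fence_k = 1.5, min_n = 30,
                            qc_skew_band = 0.5, qc_kurt_band = 1,
                            generator = NULL, out_dir = "tivadj-output") {
  stopifnot(is.numeric(seed), seed == floor(seed),
            length(rois) >= 1, fence_k > 0, n_normal >= 1, n_patients >= 0)
  if (is.null(generator)) {
    targets <- normative_targets()
    unknown <- setdiff(rois, targets$roi)
    if (length(unknown))
      stop("no built-in calibration for ROI(s) ",
           paste(unknown, collapse = ", "),
           "; supply `generator` explicitly")
    generator <- calibrate_generator(targets[targets$roi %in% rois, ])
  }
  atrophy <- atrophy[names(atrophy) %in% rois]
  structure(
    list(seed = as.integer(seed), rois = rois, n_normal = n_normal,
         n_patients = n_patients, atrophy = atrophy, fence_k = fence_k,
         min_n = min_n, qc_skew_band = qc_skew_band,
         qc_kurt_band = qc_kurt_band, generator = generator,
         out_dir = out_dir),
    class = "tivadj_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `atrophy` is a
#' mapping ROI -> fraction. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `tivadj_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("seed", "rois", "n_normal", "n_patients", "atrophy",
               "fence_k", "min_n", "qc_skew_band", "qc_kurt_band", "out_dir")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$atrophy)) y$atrophy <- unlist(y$atrophy)
  if (!is.null(y$rois)) y$rois <- as.character(y$rois)
  do.call(pipeline_config, y)
}

#' Run the full pipeline and write its artifacts
#'
#' Simulates the normative database and (optionally) the patient cohort,
#' fits residual- and proportion-method models per ROI, scores both
#' cohorts, assembles the evaluation report, and writes every artifact to
#' `config$out_dir`: `normal_db.csv`, `patients.csv`, per-ROI model files
#' `model_<roi>_<method>.json`, z-score panels, and `report.json` (+ a
#' text render). Identical configurations yield identical artifacts.
#'
#' @param config A `tivadj_config` from [pipeline_config()] or
#'   [read_config()].
#' @param verbose Log stage progress via [message()].
#' @return The `tivadj_report`, invisibly; artifact paths in attribute
#'   `"paths"`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "tivadj_config"))
  t0 <- Sys.time()
  log <- function(...) if (verbose)
    message(sprintf("[tivadj +%5.1fs] ", as.numeric(Sys.time() - t0)), ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  path <- function(f) file.path(config$out_dir, f)

  log("simulate: normative database, n = ", config$n_normal)
  db <- generate_normal_database(config$generator, config$n_normal,
                                 stage_seed(config$seed, "simulate-normal"))
  paths$normal_db <- write_volumetric_table(db, path("normal_db.csv"))

  patients <- NULL
  if (config$n_patients > 0) {
    log("simulate: patient cohort, n = ", config$n_patients)
    patients <- generate_patient_cohort(
      config$generator, config$n_patients,
      stage_seed(config$seed, "simulate-patients"),
      atrophy = config$atrophy
    )
    paths$patients <- write_volumetric_table(patients, path("patients.csv"))
  }

  for (roi in config$rois) {
    fr <- fit_residual_model(db, roi, config$fence_k, config$min_n)
    fp <- fit_proportion_model(db, roi, config$fence_k, config$min_n)
    log(sprintf("fit: %s residual n_fit=%d (-%d), proportion n_fit=%d (-%d)",
                roi, fr$n_fit, length(fr$outlier_ids),
                fp$n_fit, length(fp$outlier_ids)))
    paths[[paste0("model_", roi, "_residual")]] <-
      write_model(fr, path(sprintf("model_%s_residual.json", tolower(roi))))
    paths[[paste0("model_", roi, "_proportion")]] <-
      write_model(fp, path(sprintf("model_%s_proportion.json", tolower(roi))))
    panel <- score_subjects(fr, fp, db)
    paths[[paste0("panel_", roi, "_db")]] <-
      write_panel(panel, path(sprintf("panel_%s_normal.csv", tolower(roi))))
    if (!is.null(patients)) {
      ppanel <- score_subjects(fr, fp, patients)
      paths[[paste0("panel_", roi, "_patients")]] <-
        write_panel(ppanel, path(sprintf("panel_%s_patients.csv", tolower(roi))))
    }
  }

  log("evaluate: assembling report")
  report <- build_report(db, patients, rois = config$rois,
                         fence_k = config$fence_k, min_n = config$min_n,
                         qc_skew_band = config$qc_skew_band,
                         qc_kurt_band = config$qc_kurt_band)
  paths$report <- write_report(report, path("report.json"))
  log("done")
  attr(report, "paths") <- paths
  invisible(report)
}
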