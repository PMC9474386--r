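# Synthetic cohort generation.
#
# The generative model per region of interest (ROI) is
#
#   ROIV = beta0 + beta1*TIV + beta2*age + beta3*age^2
#          + beta4*TIV*age + eps,        eps ~ N(0, sigma_eps^2)
#
# with TIV and age drawn independently from truncated normals. beta0 and
# beta1 are positive (regional volumes relate to head size linearly with
# a positive intercept), beta3 and beta4 are small negatives (accelerating
# age-related decline, and a steeper volume-vs-TIV slope in younger
# subjects). The positive intercept is the structural feature that makes
# ROIV/TIV fractions retain a (negative) TIV association; the residual
# method removes the TIV association exactly.

#' Built-in normative target moments
#'
#' Raw per-ROI moments of a large clinical normative database (ages
#' 20-90): mean and SD of the regional volume in ml and its Pearson
#' correlations with TIV and with age. These are the default calibration
#' targets for [calibrate_generator()].
#'
#' @return A data frame with columns `roi`, `mean_ml`, `sd_ml`, `r_tiv`,
#'   `r_age`, one row per ROI (BP, THAL, HIPP).
#' @export
#' @examples
#' normative_targets()
normative_targets <- function() {
  data.frame(
    roi = c("BP", "THAL", "HIPP"),
    mean_ml = c(1112.66, 14.97, 7.16),
    sd_ml = c(117.28, 1.67, 0.81),
    r_tiv = c(0.79, 0.52, 0.42),
    r_age = c(-0.40, -0.57, -0.38),
    stringsAsFactors = FALSE
  )
}

#' Default age distribution of the normative database
#'
#' Truncated normal, mean 49.6 y, SD 16.7 y, support 20-90 y, matching
#' the reference cohort the built-in targets describe.
#'
#' @return List with `mean`, `sd`, `min`, `max` (years).
#' @export
default_age_spec <- function() list(mean = 49.6, sd = 16.7, min = 20, max = 90)

#' Default TIV distribution
#'
#' Truncated normal on positive support. The mean follows from the
#' normative moments themselves: mean brain-parenchyma volume 1112.66 ml
#' at a mean parenchymal fraction of 81.3% of TIV implies a mean TIV of
#' 1112.66/0.813 ~ 1368.6 ml. The SD (140 ml) is a calibration choice
#' that approximately reproduces the normative fraction-scale SDs and
#' fraction-vs-TIV correlations; see the methods vignette.
#'
#' @return List with `mean` and `sd` (ml).
#' @export
default_tiv_spec <- function() list(mean = 1112.66 / 0.813, sd = 140)

#' Default patient age distribution (MS-like cohort)
#'
#' Two-component truncated-normal mixture reflecting two study
#' subsamples: 33/127 subjects at 42.2 +/- 10.1 y and 94/127 at
#' 37.3 +/- 8.9 y, truncated to the model validity range 20-90 y.
#'
#' @return List with a `components` data frame (`weight`, `mean`, `sd`)
#'   and `min`, `max` bounds (years).
#' @export
default_patient_age_spec <- function() {
  list(
    components = data.frame(
      weight = c(33 / 127, 94 / 127),
      mean = c(42.2, 37.3),
      sd = c(10.1, 8.9)
    ),
    min = 20, max = 90
  )
}

#' Calibrate generator coefficients to target moments
#'
#' Solves, in closed form, for per-ROI coefficients of the generative
#' model so that the large-sample raw mean, SD, corr(ROIV, TIV) and
#' corr(ROIV, age) match the targets. With TIV and age independent, the
#' target covariances identify `beta1` and `beta2` given fixed small
#' negative defaults for `beta3` (quadratic age) and `beta4` (TIV x age
#' interaction); `sigma_eps` then absorbs the variance the systematic
#' part does not explain, and `beta0` centres the mean. All moments of
#' the truncated age and TIV laws are computed exactly.
#'
#' @param targets Data frame like [normative_targets()]: columns `roi`,
#'   `mean_ml`, `sd_ml`, `r_tiv`, `r_age`.
#' @param tiv_spec List with `mean`, `sd` (ml); default [default_tiv_spec()].
#' @param age_spec List with `mean`, `sd`, `min`, `max` (years); default
#'   [default_age_spec()].
#' @param female_fraction Fraction of female subjects generated (sex is
#'   carried but enters no model; it exists to support subgroup reruns).
#' @param beta3,beta4 Optional named numeric vectors (per ROI) overriding
#'   the defaults `-1.5e-6 * mean_ml` (ml/year^2) and `-1e-7 * mean_ml`
#'   (1/year). Both default to 0 for an ROI whose target correlations are
#'   both zero.
#' @return An object of class `tivadj_generator_params`: per-ROI
#'   coefficients `beta0`..`beta4` and `sigma_eps`, plus the cohort-level
#'   `tiv`, `age` and `female_fraction` settings.
#' @seealso [generate_normal_database()], [generate_patient_cohort()]
#' @export
#' @examples
#' params <- calibrate_generator()
#' params$rois$BP$beta1   # ml of regional volume per ml of TIV
calibrate_generator <- function(targets = normative_targets(),
                                tiv_spec = default_tiv_spec(),
                                age_spec = default_age_spec(),
                                female_fraction = 0.576,
                                beta3 = NULL, beta4 = NULL) {
  stopifnot(is.data.frame(targets),
            all(c("roi", "mean_ml", "sd_ml", "r_tiv", "r_age") %in% names(targets)),
            all(targets$sd_ml > 0),
            all(abs(targets$r_tiv) < 1), all(abs(targets$r_age) < 1),
            is_number(tiv_spec$mean), is_number(tiv_spec$sd), tiv_spec$sd > 0,
            is_number(age_spec$mean), is_number(age_spec$sd), age_spec$sd > 0,
            age_spec$min >= 20, age_spec$max <= 90, age_spec$min < age_spec$max,
            female_fraction >= 0, female_fraction <= 1)

  mt <- truncnorm_moments(tiv_spec$mean, tiv_spec$sd, lower = 0, order = 2)
  ma <- truncnorm_moments(age_spec$mean, age_spec$sd,
                          lower = age_spec$min, upper = age_spec$max, order = 4)
  e_t <- mt[1]; var_t <- mt[2] - mt[1]^2
  e_a <- ma[1]; var_a <- ma[2] - ma[1]^2
  cov_a2_a <- ma[3] - ma[1] * ma[2]
  var_a2 <- ma[4] - ma[2]^2
  # TIV and age independent, so the interaction term's moments factorize
  var_ta <- mt[2] * ma[2] - (mt[1] * ma[1])^2
  cov_t_ta <- e_a * var_t
  cov_a_ta <- e_t * var_a
  cov_a2_ta <- e_t * cov_a2_a

  rois <- list()
  for (i in seq_len(nrow(targets))) {
    roi <- targets$roi[i]
    m <- targets$mean_ml[i]; s <- targets$sd_ml[i]
    r_t <- targets$r_tiv[i]; r_a <- targets$r_age[i]
    zero_corr <- r_t == 0 && r_a == 0
    b3 <- if (!is.null(beta3) && roi %in% names(beta3)) beta3[[roi]]
          else if (zero_corr) 0 else -1.5e-6 * m
    b4 <- if (!is.null(beta4) && roi %in% names(beta4)) beta4[[roi]]
          else if (zero_corr) 0 else -1e-7 * m
    stopifnot(b3 <= 0, b4 <= 0)

    cov_t_target <- r_t * s * sqrt(var_t)
    cov_a_target <- r_a * s * sqrt(var_a)
    b1 <- (cov_t_target - b4 * cov_t_ta) / var_t
    b2 <- (cov_a_target - b3 * cov_a2_a - b4 * cov_a_ta) / var_a

    var_sys <- b1^2 * var_t + b2^2 * var_a + b3^2 * var_a2 + b4^2 * var_ta +
      2 * b2 * b3 * cov_a2_a + 2 * b1 * b4 * cov_t_ta +
      2 * b2 * b4 * cov_a_ta + 2 * b3 * b4 * cov_a2_ta
    sigma2 <- s^2 - var_sys
    if (sigma2 <= 0) {
      stop("calibration infeasible for ROI '", roi,
           "': requested correlations imply more than the total variance ",
           "(implied sigma_eps^2 = ", format(sigma2), ")")
    }
    b0 <- m - b1 * e_t - b2 * e_a - b3 * ma[2] - b4 * e_t * e_a
    rois[[roi]] <- list(beta0 = b0, beta1 = b1, beta2 = b2, beta3 = b3,
                        beta4 = b4, sigma_eps = sqrt(sigma2),
                        target_mean = m, target_sd = s)
  }

  params <- structure(
    list(rois = rois, tiv = tiv_spec, age = age_spec,
         female_fraction = female_fraction),
    class = "tivadj_generator_params"
  )
  validate_generator_params(params)
  params
}

#' Validate generator parameters
#'
#' Checks the structural invariants of the generative model: positive
#' noise and TIV SDs, non-negative intercept and TIV slope, non-positive
#' quadratic-age and interaction coefficients, and an age support inside
#' 20-90 years.
#'
#' @param params A `tivadj_generator_params` object.
#' @return `params`, invisibly; errors if an invariant is violated.
#' @export
validate_generator_params <- function(params) {
  stopifnot(inherits(params, "tivadj_generator_params"))
  stopifnot(params$tiv$sd > 0, params$age$sd > 0,
            params$age$min >= 20, params$age$max <= 90,
            params$female_fraction >= 0, params$female_fraction <= 1)
  for (roi in names(params$rois)) {
    p <- params$rois[[roi]]
    if (p$sigma_eps < 0) stop("sigma_eps < 0 for ROI ", roi)
    if (p$beta0 < 0 || p$beta1 < 0)
      stop("negative intercept or TIV slope for ROI ", roi)
    if (p$beta3 > 0 || p$beta4 > 0)
      stop("beta3 and beta4 must be <= 0 for ROI ", roi)
  }
  invisible(params)
}

#' @export
print.tivadj_generator_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  TIV ~ TN(%.1f, %.1f ml), age ~ TN(%.1f, %.1f y) on [%g, %g], %.1f%% female\n",
              x$tiv$mean, x$tiv$sd, x$age$mean, x$age$sd,
              x$age$min, x$age$max, 100 * x$female_fraction))
  for (roi in names(x$rois)) {
    p <- x$rois[[roi]]
    cat(sprintf("  %-5s beta0=%.4g beta1=%.4g beta2=%.4g beta3=%.3g beta4=%.3g sigma_eps=%.4g\n",
                roi, p$beta0, p$beta1, p$beta2, p$beta3, p$beta4, p$sigma_eps))
  }
  invisible(x)
}

# Systematic (noise-free) part of the model for one ROI.
roi_systematic <- function(p, tiv, age) {
  p$beta0 + p$beta1 * tiv + p$beta2 * age + p$beta3 * age^2 +
    p$beta4 * tiv * age
}

# Draw ages from either a single truncated normal or a mixture spec.
draw_ages <- function(n, spec) {
  if (!is.null(spec$components)) {
    comp <- sample.int(nrow(spec$components), n, replace = TRUE,
                       prob = spec$components$weight)
    age <- numeric(n)
    for (k in seq_len(nrow(spec$components))) {
      idx <- which(comp == k)
      if (length(idx))
        age[idx] <- rtruncnorm(length(idx), spec$components$mean[k],
                               spec$components$sd[k], spec$min, spec$max)
    }
    age
  } else {
    rtruncnorm(n, spec$mean, spec$sd, spec$min, spec$max)
  }
}

# Shared engine for normal and patient cohorts. Records violating
# 0 < ROIV < TIV are redrawn wholly (rejection, not clipping, so the
# joint distribution is a clean conditional law).
generate_cohort <- function(params, n, seed, atrophy = NULL, age_spec = NULL,
                            id_prefix = "S", provenance = "synthetic") {
  validate_generator_params(params)
  stopifnot(n >= 1, n == floor(n))
  rois <- names(params$rois)
  shrink <- stats::setNames(rep(1, length(rois)), rois)
  if (!is.null(atrophy)) {
    stopifnot(!is.null(names(atrophy)), all(names(atrophy) %in% rois),
              all(atrophy >= 0), all(atrophy < 1))
    shrink[names(atrophy)] <- 1 - atrophy
  }
  aspec <- if (is.null(age_spec)) params$age else age_spec

  with_seed(seed, {
    draw <- function(m) {
      age <- draw_ages(m, aspec)
      sex <- ifelse(stats::runif(m) < params$female_fraction, "F", "M")
      tiv <- rtruncnorm(m, params$tiv$mean, params$tiv$sd, lower = 0)
      vols <- sapply(rois, function(roi) {
        p <- params$rois[[roi]]
        shrink[[roi]] * roi_systematic(p, tiv, age) +
          stats::rnorm(m, 0, p$sigma_eps)
      })
      vols <- matrix(vols, nrow = m, dimnames = list(NULL, rois))
      list(age = age, sex = sex, tiv = tiv, vols = vols)
    }
    d <- draw(n)
    bad <- rowSums(d$vols <= 0 | d$vols >= d$tiv) > 0
    tries <- 0
    while (any(bad)) {
      tries <- tries + 1
      if (tries > 1000) stop("rejection sampling failed to converge; ",
                             "parameters leave almost no valid support")
      r <- draw(sum(bad))
      d$age[bad] <- r$age; d$sex[bad] <- r$sex; d$tiv[bad] <- r$tiv
      d$vols[bad, ] <- r$vols
      bad[bad] <- rowSums(r$vols <= 0 | r$vols >= r$tiv) > 0
    }
    tab <- data.frame(
      subject_id = sprintf("%s%05d", id_prefix, seq_len(n)),
      age = d$age, sex = d$sex, tiv_ml = d$tiv,
      stringsAsFactors = FALSE
    )
    for (roi in rois) tab[[roi_column(roi)]] <- d$vols[, roi]
    attr(tab, "provenance") <- provenance
    attr(tab, "seed") <- seed
    tab
  })
}

#' Generate a synthetic normative database
#'
#' Draws `n` subjects from the calibrated generative model: age and TIV
#' from independent truncated normals, sex by the female fraction, and
#' each regional volume from the linear-plus-quadratic model with
#' Gaussian noise. Records violating `0 < ROIV < TIV` are redrawn.
#' Identical `(params, n, seed)` give identical tables.
#'
#' @param params Generator parameters from [calibrate_generator()].
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return A volumetric data frame (`subject_id`, `age`, `sex`, `tiv_ml`,
#'   one `<roi>_ml` column per ROI) with `provenance` and `seed`
#'   attributes.
#' @export
#' @examples
#' db <- generate_normal_database(calibrate_generator(), n = 100, seed = 1)
#' summary(db$bp_ml)
generate_normal_database <- function(params, n, seed) {
  generate_cohort(params, n, seed, id_prefix = "N",
                  provenance = "synthetic normative database")
}

#' Generate a synthetic patient cohort with regional atrophy
#'
#' As [generate_normal_database()], but the systematic part of each
#' affected ROI is multiplied by `1 - atrophy[roi]`, and ages come from a
#' patient-specific distribution (by default a two-component mixture of
#' younger adults typical of an MS sample). The default thalamic atrophy
#' fraction (0.10) is calibrated so that the cohort's mean
#' residual-method thalamus z-score is close to -1.5.
#'
#' @inheritParams generate_normal_database
#' @param atrophy Named vector of fractional volume reductions in `[0, 1)`
#'   per ROI, e.g. `c(THAL = 0.10)`.
#' @param age_spec Patient age distribution; default
#'   [default_patient_age_spec()].
#' @return A volumetric data frame as in [generate_normal_database()].
#' @export
generate_patient_cohort <- function(params, n, seed,
                                    atrophy = c(THAL = 0.10),
                                    age_spec = default_patient_age_spec()) {
  generate_cohort(params, n, seed, atrophy = atrophy, age_spec = age_spec,
                  id_prefix = "P", provenance = "synthetic patient cohort")
}
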