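#' @keywords internal
"_PACKAGE"

#' Canonical region-of-interest labels
#'
#' The three regions handled by the built-in normative calibration:
#' brain parenchyma (`"BP"`), bilateral thalamus (`"THAL"`), and bilateral
#' hippocampus (`"HIPP"`). User-defined labels are accepted throughout as
#' long as the volumetric table carries a matching `<label>_ml` column.
#'
#' @return Character vector of ROI labels.
#' @export
roi_labels <- function() c("BP", "THAL", "HIPP")

#' Column name holding a region's volume in a volumetric table
#'
#' @param roi ROI label, e.g. `"BP"`.
#' @return Column name, e.g. `"bp_ml"`.
#' @export
roi_column <- function(roi) {
  stopifnot(is.character(roi), nchar(roi) > 0)
  paste0(tolower(roi), "_ml")
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from one top-level seed
#'
#' All pipeline randomness flows from a single seed; each stage draws from
#' its own named substream so that adding or reordering stages never
#' perturbs another stage's draws.
#'
#' @param seed Integer top-level seed.
#' @param stage Stage name, e.g. `"simulate-normal"`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == floor(seed))
  stopifnot(is.character(stage), length(stage) == 1)
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Internal: validate that x is a single finite number.
is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
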