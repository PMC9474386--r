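# Table, model and report serialization.
#
# One canonical table dialect: comma-separated, header row, UTF-8,
# decimal point, LF line endings — no dialect sniffing, since silent
# guessing is how unit errors happen. Numeric columns are written with
# full double precision so write/read round-trips are lossless. All
# writers go through a temp-then-rename step so a failed write never
# leaves a partial artifact.

required_table_columns <- c("subject_id", "age", "tiv_ml")

# Atomic write: materialize into path.tmp, then rename.
write_atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("failed to move temp file onto ", path)
  invisible(path)
}

# Full-precision decimal rendering of doubles (round-trips exactly).
format_double <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read a volumetric table
#'
#' Reads the canonical comma-separated table (`subject_id`, `age`,
#' optional `sex`, `tiv_ml`, and any number of `<roi>_ml` volume
#' columns). Rows violating the record invariants — non-positive TIV,
#' volumes that are non-positive or not below TIV, unparseable age — are
#' removed and collected into a rejects report (attribute `"rejects"`)
#' with their file row numbers and reasons. Ages outside the 20-90 y
#' model validity range are kept but trigger a warning; such subjects are
#' flagged as extrapolations when scored.
#'
#' @param path File path.
#' @return The validated data frame, with attribute `"rejects"` (a data
#'   frame `row`, `subject_id`, `reason`). Retrieve it with
#'   `attr(x, "rejects")`.
#' @export
read_volumetric_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop("empty table: ", path)
  missing_cols <- setdiff(required_table_columns, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  vol_cols <- grep("_ml$", names(raw), value = TRUE)
  vol_cols <- setdiff(vol_cols, "tiv_ml")
  num_cols <- c("age", "tiv_ml", vol_cols)
  tab <- raw
  for (cc in num_cols)
    tab[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  if (!"sex" %in% names(tab)) tab$sex <- "unknown"
  tab$sex[!tab$sex %in% c("F", "M")] <- "unknown"

  reasons <- vector("list", nrow(tab))
  add_reason <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
    reasons
  }
  reasons <- add_reason(is.na(tab$age) & nzchar(raw$age), "unparseable age")
  reasons <- add_reason(!is.na(tab$tiv_ml) & tab$tiv_ml <= 0,
                        "non-positive TIV")
  reasons <- add_reason(is.na(tab$tiv_ml) & nzchar(raw$tiv_ml),
                        "unparseable TIV")
  for (cc in vol_cols) {
    v <- tab[[cc]]
    reasons <- add_reason(!is.na(v) & v <= 0, paste0("non-positive ", cc))
    reasons <- add_reason(!is.na(v) & !is.na(tab$tiv_ml) & tab$tiv_ml > 0 &
                            v >= tab$tiv_ml, paste0(cc, " not below TIV"))
  }
  bad <- !vapply(reasons, is.null, logical(1))
  rejects <- data.frame(
    row = which(bad) + 1L,  # +1 for the header line
    subject_id = tab$subject_id[bad],
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  tab <- tab[!bad, , drop = FALSE]
  rownames(tab) <- NULL

  out_of_range <- !is.na(tab$age) & (tab$age < 20 | tab$age > 90)
  if (any(out_of_range))
    warning(sum(out_of_range), " subject(s) outside the 20-90 y model ",
            "validity range; they will be flagged as extrapolations")
  if (nrow(rejects))
    warning(nrow(rejects), " row(s) rejected; see attr(x, \"rejects\")")
  attr(tab, "rejects") <- rejects
  tab
}

#' Write a volumetric table
#'
#' Inverse of [read_volumetric_table()]; numeric columns keep full
#' double precision, so a write-then-read round-trip reproduces the
#' table exactly.
#'
#' @param table Volumetric data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volumetric_table <- function(table, path) {
  stopifnot(is.data.frame(table),
            all(required_table_columns %in% names(table)))
  out <- table
  for (cc in names(out))
    if (is.numeric(out[[cc]])) out[[cc]] <- format_double(out[[cc]])
  write_atomically(path, function(tmp) {
    utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE, eol = "\n",
                     fileEncoding = "UTF-8")
  })
}

#' Serialize a fitted normative model
#'
#' Writes a `tivadj_model` to structured text (JSON) with full float
#' precision, so patient scoring can run later without refitting; the
#' [read_model()] round-trip is lossless.
#'
#' @param model A `tivadj_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tivadj_model"))
  payload <- unclass(model)
  # named vectors must travel as JSON objects, and doubles need all 17
  # significant digits to round-trip exactly
  for (f in c("coefficients", "se", "p_value", "significant"))
    payload[[f]] <- as.list(payload[[f]])
  payload$format <- "tivadj_model"
  payload$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp, digits = I(17), auto_unbox = TRUE,
                         pretty = TRUE)
  })
}

#' Read a serialized normative model
#'
#' @param path Path written by [write_model()].
#' @return A `tivadj_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "tivadj_model")
    stop("not a serialized tivadj model: ", path)
  x$format <- NULL
  x$created <- NULL
  # scalars inside JSON objects come back as lists; restore atomic vectors
  for (f in c("coefficients", "se", "p_value"))
    x[[f]] <- unlist(x[[f]])
  x$significant <- unlist(x$significant)
  x$outlier_ids <- as.character(x$outlier_ids)
  x$fit_ids <- as.character(x$fit_ids)
  x$age_range <- as.numeric(x$age_range)
  x$n_fit <- as.integer(x$n_fit)
  structure(x, class = "tivadj_model")
}

#' Write a z-score panel
#'
#' @param panel Data frame from [score_subjects()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel
  for (cc in names(out))
    if (is.numeric(out[[cc]])) out[[cc]] <- format_double(out[[cc]])
  write_atomically(path, function(tmp) {
    utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE, eol = "\n",
                     fileEncoding = "UTF-8")
  })
}

#' Write an evaluation report
#'
#' Writes the machine-readable report as JSON (data frames of the report,
#' without the fitted model objects, which have their own serialization)
#' and, alongside it, a human-readable render as `<path>.txt`.
#'
#' @param report A `tivadj_report`.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "tivadj_report"))
  payload <- list(format = "tivadj_report",
                  table = report$table, zdiff = report$zdiff,
                  normality = report$normality, auc = report$auc)
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  })
  write_atomically(paste0(path, ".txt"), function(tmp) {
    writeLines(utils::capture.output(print(report)), tmp)
  })
  invisible(path)
}
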