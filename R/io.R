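#' Read a patient cohort from CSV
#'
#' Reads a delimited cohort file (header row, one row per patient, empty
#' field = missing) and validates it against the patient-record invariants:
#' the five scoring predictors must be present as columns; `age` and
#' `albumin` must be positive numbers; flag columns must be 0/1; `mural`,
#' when present, must be 0/1. Malformed rows are rejected with their line
#' numbers rather than silently dropped; with `skip_invalid = TRUE` they
#' are dropped and the skipped count reported via a message.
#'
#' @param path CSV file path.
#' @param require_outcome Require a `mural` outcome column.
#' @param skip_invalid Drop malformed rows instead of erroring.
#' @return A validated data.frame.
#' @export
read_cohort <- function(path, require_outcome = FALSE, skip_invalid = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- mural_required_predictors()
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("cohort file is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (require_outcome && !"mural" %in% names(df)) {
    stop("cohort file is missing required column(s): mural", call. = FALSE)
  }

  bad <- rep(FALSE, nrow(df))
  flag_cols <- intersect(c("atherosclerosis", "ckd", "antiplatelet", "sex",
                           "diabetes", "chronic_liver_disease",
                           "immunocompromised", "cancer_history", "nsaids",
                           "anticoagulant", "overt_bleeding",
                           "abdominal_pain", "weight_loss", "mural"),
                         names(df))
  for (f in c("age", "albumin")) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- bad | is.na(v) | v <= 0
    df[[f]] <- v
  }
  for (f in flag_cols) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    ok <- is.na(df[[f]]) & !(f %in% c("atherosclerosis", "ckd",
                                      "antiplatelet"))
    bad <- bad | (!ok & (is.na(v) | !v %in% c(0, 1)))
    df[[f]] <- v
  }
  if ("hemoglobin" %in% names(df)) {
    df$hemoglobin <- suppressWarnings(as.numeric(df$hemoglobin))
  }
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header row
    if (!skip_invalid) {
      stop(sprintf("malformed cohort row(s) at line(s): %s",
                   paste(utils::head(lines, 20L), collapse = ", ")),
           call. = FALSE)
    }
    message(sprintf("read_cohort: skipped %d malformed row(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]; numeric columns are written with 17
#' significant digits so doubles round-trip exactly.
#'
#' @param cohort Data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- ""
      df[[nm]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
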