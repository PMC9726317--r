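#' The MURAL logistic risk model
#'
#' Constructs a five-predictor logistic model for the probability that a
#' patient with potential small bowel bleeding (PSBB) bleeds from a
#' mural-based lesion (small-bowel tumor) rather than a mucosal one.
#' Defaults are the published coefficients:
#'
#' \deqn{P = 100 \cdot \mathrm{logit}^{-1}(-3.7207 - 0.00696\,\mathrm{age}
#'   - 1.0531\,\mathrm{athero} - 0.6161\,\mathrm{CKD}
#'   - 0.8276\,\mathrm{antiplatelet} + 0.8627\,\mathrm{albumin})}
#'
#' with classification cutoff 24.2 (percent). Younger age and higher serum
#' albumin push the score up; atherosclerosis, chronic kidney disease and
#' antiplatelet use push it down (those conditions predispose to mucosal
#' angiodysplasia instead).
#'
#' @param intercept Intercept on the log-odds scale.
#' @param coef_age Log-odds per year of age.
#' @param coef_atherosclerosis Log-odds for large-vessel atherosclerotic
#'   disease (0/1).
#' @param coef_ckd Log-odds for chronic kidney disease (0/1).
#' @param coef_antiplatelet Log-odds for antiplatelet use (0/1).
#' @param coef_albumin Log-odds per g/dL of serum albumin.
#' @param cutoff Classification cutoff in percent, strictly inside (0, 100).
#' @return An object of class `mural_model`: a list with a named
#'   `coefficients` vector (intercept first) and `cutoff`.
#' @export
#' @examples
#' m <- mural_model()
#' mural_probability(data.frame(age = 60, atherosclerosis = 0, ckd = 0,
#'                              antiplatelet = 0, albumin = 3.5), m)
mural_model <- function(intercept = -3.7207,
                        coef_age = -0.00696,
                        coef_atherosclerosis = -1.0531,
                        coef_ckd = -0.6161,
                        coef_antiplatelet = -0.8276,
                        coef_albumin = 0.8627,
                        cutoff = 24.2) {
  coefs <- c(intercept = intercept,
             age = coef_age,
             atherosclerosis = coef_atherosclerosis,
             ckd = coef_ckd,
             antiplatelet = coef_antiplatelet,
             albumin = coef_albumin)
  if (!all(is.finite(coefs))) {
    stop("all model coefficients must be finite", call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      !is.finite(cutoff) || cutoff <= 0 || cutoff >= 100) {
    stop("'cutoff' must be a percent strictly inside (0, 100)", call. = FALSE)
  }
  structure(list(coefficients = coefs, cutoff = cutoff),
            class = "mural_model")
}

#' @export
print.mural_model <- function(x, ...) {
  cat("MURAL logistic model (probability of mural-based lesion, percent)\n")
  cat(sprintf("  linear predictor: %.4f %+.5f*age %+.4f*atherosclerosis %+.4f*ckd %+.4f*antiplatelet %+.4f*albumin\n",
              x$coefficients[["intercept"]], x$coefficients[["age"]],
              x$coefficients[["atherosclerosis"]], x$coefficients[["ckd"]],
              x$coefficients[["antiplatelet"]], x$coefficients[["albumin"]]))
  cat(sprintf("  classification cutoff: %.1f%%\n", x$cutoff))
  invisible(x)
}

# the five predictors every scoring call must supply
mural_required_predictors <- function() {
  c("age", "atherosclerosis", "ckd", "antiplatelet", "albumin")
}

#' Probability of a mural-based lesion, in percent
#'
#' Scores one or more patients with a [mural_model()]. Input validation is
#' strict: a missing predictor column, a missing value, a non-binary flag or
#' a non-positive age/albumin is an error (the derivation study excluded
#' incomplete records rather than imputing them, and this package does the
#' same).
#'
#' @param cohort A data.frame (or coercible list) with columns `age`,
#'   `atherosclerosis`, `ckd`, `antiplatelet`, `albumin`.
#' @param model A [mural_model()].
#' @return Numeric vector of probabilities in percent, strictly in (0, 100).
#' @export
mural_probability <- function(cohort, model = mural_model()) {
  if (!inherits(model, "mural_model")) {
    stop("'model' must be a mural_model object", call. = FALSE)
  }
  cohort <- as.data.frame(cohort)
  req <- mural_required_predictors()
  for (f in req) {
    if (!f %in% names(cohort)) {
      stop(sprintf("required predictor '%s' is missing from the cohort", f),
           call. = FALSE)
    }
    if (anyNA(cohort[[f]]) || !is.numeric(cohort[[f]])) {
      stop(sprintf("predictor '%s' contains missing or non-numeric values", f),
           call. = FALSE)
    }
  }
  for (f in c("atherosclerosis", "ckd", "antiplatelet")) {
    check_binary(cohort[[f]], f)
  }
  if (any(cohort$age <= 0) || any(!is.finite(cohort$age))) {
    stop("'age' must be positive and finite", call. = FALSE)
  }
  if (any(cohort$albumin <= 0) || any(!is.finite(cohort$albumin))) {
    stop("'albumin' must be positive and finite", call. = FALSE)
  }
  b <- model$coefficients
  lp <- b[["intercept"]] +
    b[["age"]] * cohort$age +
    b[["atherosclerosis"]] * cohort$atherosclerosis +
    b[["ckd"]] * cohort$ckd +
    b[["antiplatelet"]] * cohort$antiplatelet +
    b[["albumin"]] * cohort$albumin
  100 * stats::plogis(lp)
}

#' Classify a patient from a percent probability
#'
#' Applies the cutoff rule: predicted mural if and only if the probability
#' is greater than or equal to the cutoff (a tie at the cutoff classifies as
#' mural, so the published cutoff itself is actionable).
#'
#' @param prob Percent probabilities, strictly inside (0, 100).
#' @param cutoff Percent cutoff, strictly inside (0, 100).
#' @return Character vector, `"mural"` or `"non-mural"`.
#' @export
classify_patient <- function(prob, cutoff = mural_model()$cutoff) {
  if (!is.numeric(prob) || anyNA(prob) || any(prob <= 0 | prob >= 100)) {
    stop("'prob' must be percent probabilities strictly inside (0, 100)",
         call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= 0 || cutoff >= 100) {
    stop("'cutoff' must be a percent strictly inside (0, 100)", call. = FALSE)
  }
  ifelse(prob >= cutoff, "mural", "non-mural")
}

#' Read / write a model as JSON
#'
#' The on-disk format is a flat JSON object with keys `intercept`,
#' `coef_age`, `coef_atherosclerosis`, `coef_ckd`, `coef_antiplatelet`,
#' `coef_albumin`, `cutoff_percent`.
#'
#' @param path File path.
#' @return `read_mural_model()` returns a [mural_model()];
#'   `write_mural_model()` returns `path` invisibly.
#' @export
read_mural_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "coef_age", "coef_atherosclerosis", "coef_ckd",
            "coef_antiplatelet", "coef_albumin", "cutoff_percent")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop(sprintf("model file is missing keys: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  mural_model(intercept = obj$intercept,
              coef_age = obj$coef_age,
              coef_atherosclerosis = obj$coef_atherosclerosis,
              coef_ckd = obj$coef_ckd,
              coef_antiplatelet = obj$coef_antiplatelet,
              coef_albumin = obj$coef_albumin,
              cutoff = obj$cutoff_percent)
}

#' @rdname read_mural_model
#' @param model A [mural_model()].
#' @export
write_mural_model <- function(model, path) {
  stopifnot(inherits(model, "mural_model"))
  b <- model$coefficients
  obj <- list(intercept = b[["intercept"]],
              coef_age = b[["age"]],
              coef_atherosclerosis = b[["atherosclerosis"]],
              coef_ckd = b[["ckd"]],
              coef_antiplatelet = b[["antiplatelet"]],
              coef_albumin = b[["albumin"]],
              cutoff_percent = model$cutoff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
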