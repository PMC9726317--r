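#' Candidate covariates for univariate screening
#'
#' The screening list used in model derivation: demographics, comorbidity
#' and medication flags, presentation features and the two laboratory
#' values. `sex` is coded 1 = male.
#'
#' @return Character vector of cohort column names.
#' @export
mural_candidate_covariates <- function() {
  c("age", "sex", "diabetes", "atherosclerosis", "ckd",
    "chronic_liver_disease", "immunocompromised", "cancer_history",
    "nsaids", "antiplatelet", "anticoagulant", "overt_bleeding",
    "abdominal_pain", "weight_loss", "hemoglobin", "albumin")
}

#' Split a cohort into derivation and validation subsets
#'
#' Seeded permutation followed by a prefix take of
#' `round(n * derivation_fraction)` rows; the split is a disjoint,
#' exhaustive partition and is reproducible from the seed. The global RNG
#' state is left untouched.
#'
#' @param cohort A data.frame, one row per patient.
#' @param derivation_fraction Fraction allocated to the derivation cohort,
#'   strictly inside (0, 1). Default 0.7, the conventional allocation; the
#'   realized split of a given study can be reproduced by passing its exact
#'   fraction.
#' @param seed Integer seed.
#' @return A list with data.frames `derivation` and `validation`.
#' @export
split_cohort <- function(cohort, derivation_fraction = 0.7, seed) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  if (n == 0L) stop("cohort is empty", call. = FALSE)
  if (!is.numeric(derivation_fraction) || length(derivation_fraction) != 1L ||
      is.na(derivation_fraction) ||
      derivation_fraction <= 0 || derivation_fraction >= 1) {
    stop("'derivation_fraction' must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  nd <- round(n * derivation_fraction)
  nd <- max(1L, min(n - 1L, as.integer(nd)))
  list(derivation = cohort[perm[seq_len(nd)], , drop = FALSE],
       validation = cohort[perm[-seq_len(nd)], , drop = FALSE])
}

#' Univariate screening by single-covariate logistic regression
#'
#' Fits one logistic model per candidate covariate against the `mural`
#' outcome and reports the odds ratio, 95% Wald confidence interval and
#' Wald p-value. Candidates on which the likelihood diverges (complete or
#' quasi-complete separation, e.g. zero exposed cases) are reported as
#' not computable rather than failing the screen.
#'
#' @param cohort Data.frame with the candidate columns and a 0/1 `mural`
#'   outcome column.
#' @param candidates Character vector of covariate names to screen.
#' @param outcome Name of the outcome column (default `"mural"`).
#' @param alpha Significance level for the `significant` flag.
#' @return A data.frame of class `univariate_screen` with columns
#'   `covariate`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`, `computable`.
#' @export
univariate_screen <- function(cohort, candidates = mural_candidate_covariates(),
                              outcome = "mural", alpha = 0.05) {
  cohort <- as.data.frame(cohort)
  if (length(candidates) == 0L) {
    stop("empty candidate list", call. = FALSE)
  }
  if (!outcome %in% names(cohort)) {
    stop(sprintf("outcome column '%s' is missing", outcome), call. = FALSE)
  }
  miss <- setdiff(candidates, names(cohort))
  if (length(miss)) {
    stop(sprintf("candidate covariates missing from cohort: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  y <- cohort[[outcome]]
  check_binary(y, outcome)
  rows <- lapply(candidates, function(cv) {
    fit <- tryCatch(fit_logistic_ml(cohort[[cv]], y), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(data.frame(covariate = cv, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        computable = FALSE))
    }
    b <- fit$coefficients[2L]
    se <- fit$se[2L]
    p <- 2 * stats::pnorm(-abs(b / se))
    data.frame(covariate = cv,
               odds_ratio = exp(b),
               ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se),
               p_value = p,
               significant = is.finite(p) && p < alpha,
               computable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("univariate_screen", "data.frame")
  out
}

# multivariate logistic fit reported in the same OR/CI/p shape
multivariate_table <- function(cohort, covariates, outcome = "mural") {
  fit <- fit_logistic_ml(as.matrix(cohort[covariates]), cohort[[outcome]])
  b <- fit$coefficients[-1L]
  se <- fit$se[-1L]
  out <- data.frame(covariate = covariates,
                    odds_ratio = exp(b),
                    ci_low = exp(b - 1.96 * se),
                    ci_high = exp(b + 1.96 * se),
                    p_value = 2 * stats::pnorm(-abs(b / se)),
                    row.names = NULL)
  list(table = out, fit = fit)
}

#' Derive a mural-lesion risk model from a labelled cohort
#'
#' Runs the full derivation pipeline: (1) seeded split into derivation and
#' validation cohorts; (2) univariate screen of all candidates on the
#' derivation cohort; (3) multivariate fit of the univariately significant
#' covariates; (4) the final model is always a logistic refit of the five
#' prespecified covariates (age, atherosclerosis, CKD, antiplatelet,
#' albumin) regardless of multivariate significance -- univariately
#' significant predictors are retained for clinical meaning even when
#' multivariate parsimony would drop them; (5) Youden-optimal cutoff chosen
#' on derivation-cohort scores; (6) classification metrics and ROC on the
#' held-out validation cohort at that cutoff.
#'
#' @param cohort Data.frame carrying all candidate covariates plus the 0/1
#'   `mural` outcome.
#' @param seed Integer seed controlling the split.
#' @param derivation_fraction Passed to [split_cohort()].
#' @param candidates Covariates to screen.
#' @param final_covariates The prespecified model covariates.
#' @return A list of class `mural_derivation`: `model` (a [mural_model()]
#'   with fitted coefficients and the Youden cutoff), `fit`, `univariate`,
#'   `multivariate`, `roc_derivation`, `roc_validation`,
#'   `validation_metrics`, `split_sizes`, `seed`.
#' @export
derive_mural_model <- function(cohort, seed, derivation_fraction = 0.7,
                               candidates = mural_candidate_covariates(),
                               final_covariates = c("age", "atherosclerosis",
                                                    "ckd", "antiplatelet",
                                                    "albumin")) {
  cohort <- as.data.frame(cohort)
  candidates <- intersect(candidates, names(cohort))
  if (!all(final_covariates %in% names(cohort))) {
    stop("cohort lacks one of the prespecified model covariates",
         call. = FALSE)
  }
  parts <- split_cohort(cohort, derivation_fraction, seed)
  deriv <- parts$derivation
  valid <- parts$validation

  uni <- univariate_screen(deriv, candidates)
  sig <- uni$covariate[uni$computable & uni$significant]
  multi <- if (length(sig) >= 1L) multivariate_table(deriv, sig)$table else NULL

  fit <- fit_logistic_ml(as.matrix(deriv[final_covariates]), deriv$mural)
  b <- fit$coefficients
  model <- mural_model(intercept = b[["(Intercept)"]],
                       coef_age = b[["age"]],
                       coef_atherosclerosis = b[["atherosclerosis"]],
                       coef_ckd = b[["ckd"]],
                       coef_antiplatelet = b[["antiplatelet"]],
                       coef_albumin = b[["albumin"]],
                       cutoff = 50)  # placeholder until Youden below

  deriv_scores <- mural_probability(deriv, model)
  roc_d <- roc_curve(deriv_scores, deriv$mural)
  model$cutoff <- roc_d$youden_cutoff

  valid_scores <- mural_probability(valid, model)
  roc_v <- roc_curve(valid_scores, valid$mural)
  pred_v <- as.numeric(classify_patient(valid_scores, model$cutoff) == "mural")
  metrics_v <- confusion_metrics(valid$mural, pred_v)

  structure(list(model = model,
                 fit = fit,
                 univariate = uni,
                 multivariate = multi,
                 roc_derivation = roc_d,
                 roc_validation = roc_v,
                 validation_metrics = metrics_v,
                 split_sizes = c(derivation = nrow(deriv),
                                 validation = nrow(valid)),
                 seed = seed),
            class = "mural_derivation")
}

#' @export
print.mural_derivation <- function(x, ...) {
  cat(sprintf("mural-model derivation (seed %s): %d derivation / %d validation patients\n",
              format(x$seed), x$split_sizes[["derivation"]],
              x$split_sizes[["validation"]]))
  sig <- x$univariate$covariate[x$univariate$computable & x$univariate$significant]
  cat("univariately significant:", paste(sig, collapse = ", "), "\n")
  print(x$model)
  cat(sprintf("AUROC derivation %.3f, validation %.3f\n",
              x$roc_derivation$auc, x$roc_validation$auc))
  cat(sprintf("validation at cutoff: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              100 * x$validation_metrics$sensitivity,
              100 * x$validation_metrics$specificity,
              100 * x$validation_metrics$accuracy))
  invisible(x)
}
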