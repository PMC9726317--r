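#' Decision-model parameters
#'
#' Bundles every input of the six-strategy expected-value decision model:
#' the lesion-prevalence mix of the cohort, per-lesion sensitivity and
#' specificity of video capsule endoscopy (VCE) and computed tomography
#' enterography (CTE), the triage classifier's performance (its
#' "positive" call routes a patient to CTE; the tumor class is the mural
#' class), and unit costs per modality in each currency. Defaults are the
#' base case: a 100-patient cohort with 50% angiodysplasia, 30%
#' ulcer/inflammation and 20% tumor, literature-based test performance,
#' triage sensitivity 73.5% / specificity 79.0% (the derivation-cohort
#' operating point of the MURAL score at its published cutoff), and 2019
#' unit costs in USD and Thai baht.
#'
#' @param cohort_size Number of patients evaluated (default 100).
#' @param prevalence Named probabilities over
#'   `c("angiodysplasia", "ulcer", "tumor")`, summing to 1.
#' @param vce_sens,vce_spec,cte_sens,cte_spec Named per-lesion sensitivity /
#'   specificity of each modality. A modality's tumor specificity governs
#'   false tumor calls in non-tumor patients.
#' @param triage_sens,triage_spec Performance of the triage model at
#'   identifying tumor (mural) patients.
#' @param costs Named list of currencies, each a named vector
#'   `c(vce = , cte = )` of positive unit costs.
#' @return A validated list of class `cea_parameters`.
#' @export
cea_parameters <- function(cohort_size = 100,
                           prevalence = c(angiodysplasia = 0.50,
                                          ulcer = 0.30,
                                          tumor = 0.20),
                           vce_sens = c(angiodysplasia = 0.90,
                                        ulcer = 0.85,
                                        tumor = 0.55),
                           vce_spec = c(angiodysplasia = 0.90,
                                        ulcer = 0.99,
                                        tumor = 0.90),
                           cte_sens = c(angiodysplasia = 0.20,
                                        ulcer = 0.30,
                                        tumor = 0.90),
                           cte_spec = c(angiodysplasia = 0.99,
                                        ulcer = 0.99,
                                        tumor = 0.99),
                           triage_sens = 0.735,
                           triage_spec = 0.790,
                           costs = list(USD = c(vce = 1247, cte = 518),
                                        THB = c(vce = 42000, cte = 15400))) {
  lesions <- c("angiodysplasia", "ulcer", "tumor")
  as_lesion_vec <- function(x, what) {
    x <- unlist(x)
    if (is.null(names(x)) || !all(lesions %in% names(x))) {
      stop(sprintf("'%s' must be named over %s", what,
                   paste(lesions, collapse = ", ")), call. = FALSE)
    }
    check_prob(x[lesions], what)
  }
  prevalence <- as_lesion_vec(prevalence, "prevalence")
  if (abs(sum(prevalence) - 1) > 1e-9) {
    stop("lesion prevalences must sum to 1", call. = FALSE)
  }
  vce_sens <- as_lesion_vec(vce_sens, "vce_sens")
  vce_spec <- as_lesion_vec(vce_spec, "vce_spec")
  cte_sens <- as_lesion_vec(cte_sens, "cte_sens")
  cte_spec <- as_lesion_vec(cte_spec, "cte_spec")
  check_prob(triage_sens, "triage_sens")
  check_prob(triage_spec, "triage_spec")
  if (!is.numeric(cohort_size) || length(cohort_size) != 1L ||
      is.na(cohort_size) || cohort_size <= 0) {
    stop("'cohort_size' must be a positive number", call. = FALSE)
  }
  if (!is.list(costs) || length(costs) == 0L || is.null(names(costs))) {
    stop("'costs' must be a named list of currencies", call. = FALSE)
  }
  costs <- lapply(costs, function(cc) {
    cc <- unlist(cc)
    if (!all(c("vce", "cte") %in% names(cc)) || any(cc[c("vce", "cte")] <= 0)) {
      stop("each currency needs positive unit costs named 'vce' and 'cte'",
           call. = FALSE)
    }
    cc[c("vce", "cte")]
  })
  structure(list(cohort_size = cohort_size,
                 prevalence = prevalence,
                 vce_sens = vce_sens, vce_spec = vce_spec,
                 cte_sens = cte_sens, cte_spec = cte_spec,
                 triage_sens = triage_sens, triage_spec = triage_spec,
                 costs = costs),
            class = "cea_parameters")
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat(sprintf("decision-model parameters: %g patients, prevalence %s\n",
              x$cohort_size,
              paste(sprintf("%s %.0f%%", names(x$prevalence),
                            100 * x$prevalence), collapse = ", ")))
  cat(sprintf("triage sensitivity %.1f%% / specificity %.1f%%\n",
              100 * x$triage_sens, 100 * x$triage_spec))
  perf <- rbind(vce_sens = x$vce_sens, vce_spec = x$vce_spec,
                cte_sens = x$cte_sens, cte_spec = x$cte_spec)
  print(perf)
  for (cur in names(x$costs)) {
    cat(sprintf("%s: VCE %g, CTE %g per exam\n",
                cur, x$costs[[cur]][["vce"]], x$costs[[cur]][["cte"]]))
  }
  invisible(x)
}

#' Read / write decision-model parameters as JSON
#'
#' @param path File path to a JSON file mirroring the [cea_parameters()]
#'   fields.
#' @return `read_cea_parameters()` returns a `cea_parameters` object;
#'   `write_cea_parameters()` returns `path` invisibly.
#' @export
read_cea_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- formals(cea_parameters)
  args <- obj[intersect(names(obj), names(defaults))]
  if ("costs" %in% names(args)) {
    args$costs <- lapply(args$costs, unlist)
  }
  do.call(cea_parameters, args)
}

#' @rdname read_cea_parameters
#' @param params A `cea_parameters` object.
#' @export
write_cea_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_parameters"))
  obj <- lapply(unclass(params), function(x) {
    if (is.list(x)) lapply(x, as.list) else as.list(x)
  })
  # scalars back to bare values
  obj$cohort_size <- params$cohort_size
  obj$triage_sens <- params$triage_sens
  obj$triage_spec <- params$triage_spec
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# set one scalar parameter addressed by a dotted path such as
# "vce_sens.tumor" or "triage_sens"; revalidates via the constructor
set_cea_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "cea_parameters"))
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  obj <- unclass(params)
  if (length(parts) == 1L) {
    if (!parts %in% c("triage_sens", "triage_spec", "cohort_size")) {
      stop(sprintf("unknown scalar parameter '%s'", name), call. = FALSE)
    }
    obj[[parts]] <- value
  } else if (length(parts) == 2L) {
    if (!parts[1] %in% c("prevalence", "vce_sens", "vce_spec",
                         "cte_sens", "cte_spec") ||
        !parts[2] %in% names(obj[[parts[1]]])) {
      stop(sprintf("unknown parameter path '%s'", name), call. = FALSE)
    }
    obj[[parts[1]]][[parts[2]]] <- value
  } else if (length(parts) == 3L && parts[1] == "costs") {
    obj$costs[[parts[2]]][[parts[3]]] <- value
  } else {
    stop(sprintf("unknown parameter path '%s'", name), call. = FALSE)
  }
  do.call(cea_parameters, obj)
}
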