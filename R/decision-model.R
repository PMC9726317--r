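#' The six diagnostic strategies
#'
#' @return Character vector of strategy identifiers, in report order:
#'   `VCE` (capsule first for everyone, CTE only to stage called tumors),
#'   `CTE` (enterography only), `MURAL-1` (triage model routes each patient
#'   to CTE if predicted mural, else VCE), `VCE-CTE` and `CTE-VCE`
#'   (sequential strategies, second test for negatives of the first), and
#'   `MURAL-2` (MURAL-1 plus crossover of first-test negatives).
#' @export
mural_strategies <- function() {
  c("VCE", "CTE", "MURAL-1", "VCE-CTE", "CTE-VCE", "MURAL-2")
}

#' Evaluate one diagnostic strategy by expected-value arithmetic
#'
#' Deterministic decision-tree computation over a cohort in which each
#' patient carries exactly one lesion (angiodysplasia, ulcer/inflammation
#' or tumor, per the prevalence mix). A test detects the patient's own
#' lesion with the lesion-specific sensitivity; in non-tumor patients a
#' test additionally raises a false tumor call with probability
#' 1 - tumor specificity, independently of own-lesion detection. Every
#' tumor call on a VCE (true or false) triggers a staging CTE. Test counts
#' are administrations and add up: a patient whose lesion was missed and
#' who also drew a false tumor call contributes both a crossover and a
#' staging CTE.
#'
#' Strategy conventions:
#' \itemize{
#'  \item `VCE`: all patients get VCE; CTE count = tumor calls (staging
#'    CTEs do not rescue missed lesions).
#'  \item `CTE`: all patients get CTE only.
#'  \item `MURAL-1`: triage routes tumor patients to CTE with probability
#'    `triage_sens` and non-tumor patients with probability
#'    `1 - triage_spec`; the VCE arm applies the tumor-staging rule.
#'  \item `VCE-CTE`: VCE for all; crossover CTE for every patient whose
#'    own lesion the VCE missed, plus staging CTEs.
#'  \item `CTE-VCE`: CTE for all; crossover VCE for the CTE-negative pool,
#'    i.e. expected misses multiplied by the CTE (tumor) specificity --
#'    patients with a false tumor call on CTE are worked up as positives
#'    and do not cross over.
#'  \item `MURAL-2`: MURAL-1 plus crossover: CTE-arm negatives (misses
#'    times CTE specificity) get VCE, VCE-arm negatives (all misses) get
#'    CTE; staging CTEs arise from the VCE arm's primary capsule exams.
#' }
#'
#' Missed(lesion) is the expected count of that lesion left undetected
#' after every test the strategy allows that patient. Reported integers use
#' [round_half_down()]; exact expected values are retained alongside.
#'
#' @param strategy One of [mural_strategies()].
#' @param params A [cea_parameters()] object.
#' @param compat_mural1_followup If TRUE, replicate a published shortcut
#'   for the MURAL-1 CTE count: apply the VCE strategy's per-patient
#'   follow-up CTE rate to the MURAL-1 VCE arm instead of computing staging
#'   calls from first principles. Default FALSE (first principles).
#' @return A list of class `strategy_outcome` with elements `strategy`,
#'   `missed` / `missed_rounded` (named per lesion), `total_missed` /
#'   `total_missed_rounded`, `vce_count`, `cte_count` (+ `_rounded`),
#'   `total_investigations` (sum of rounded counts), `cost_per_patient` and
#'   `cost_per_patient_rounded` (named per currency).
#' @export
evaluate_strategy <- function(strategy, params = cea_parameters(),
                              compat_mural1_followup = FALSE) {
  if (!is.character(strategy) || length(strategy) != 1L ||
      !strategy %in% mural_strategies()) {
    stop(sprintf("unknown strategy '%s'; must be one of %s",
                 paste(strategy, collapse = ","),
                 paste(mural_strategies(), collapse = ", ")), call. = FALSE)
  }
  stopifnot(inherits(params, "cea_parameters"))
  size <- params$cohort_size
  N <- params$prevalence * size            # expected patients per lesion
  sv <- params$vce_sens
  sc <- params$cte_sens
  spv_t <- params$vce_spec[["tumor"]]      # governs false tumor calls on VCE
  spc_t <- params$cte_spec[["tumor"]]      # governs false tumor calls on CTE
  is_tumor <- names(N) == "tumor"

  # expected staging CTEs generated by VCE exams given to `n_arm` patients
  # of each lesion type: true tumor detections plus false tumor calls
  staging_ct <- function(n_arm) {
    sum(n_arm[is_tumor] * sv[is_tumor]) +
      sum(n_arm[!is_tumor] * (1 - spv_t))
  }

  if (strategy == "VCE") {
    missed <- N * (1 - sv)
    vce_n <- size
    cte_n <- staging_ct(N)
  } else if (strategy == "CTE") {
    missed <- N * (1 - sc)
    vce_n <- 0
    cte_n <- size
  } else if (strategy == "MURAL-1") {
    q <- ifelse(is_tumor, params$triage_sens, 1 - params$triage_spec)
    missed <- N * (q * (1 - sc) + (1 - q) * (1 - sv))
    vce_arm <- N * (1 - q)
    vce_n <- sum(vce_arm)
    cte_n <- sum(N * q) +
      if (compat_mural1_followup) {
        # published shortcut: reuse the VCE strategy's follow-up rate
        vce_n * staging_ct(N) / size
      } else {
        staging_ct(vce_arm)
      }
  } else if (strategy == "VCE-CTE") {
    miss1 <- N * (1 - sv)
    missed <- miss1 * (1 - sc)
    vce_n <- size
    cte_n <- sum(miss1) + staging_ct(N)
  } else if (strategy == "CTE-VCE") {
    miss1 <- N * (1 - sc)
    crossover <- miss1 * spc_t
    missed <- miss1 * (1 - spc_t * sv)
    vce_n <- sum(crossover)
    cte_n <- size
  } else {  # MURAL-2
    q <- ifelse(is_tumor, params$triage_sens, 1 - params$triage_spec)
    cte_arm <- N * q
    vce_arm <- N * (1 - q)
    miss_cte_arm <- cte_arm * (1 - sc)
    miss_vce_arm <- vce_arm * (1 - sv)
    cross_vce <- miss_cte_arm * spc_t       # CTE-negatives sent to VCE
    cross_cte <- miss_vce_arm               # VCE-negatives sent to CTE
    missed <- miss_cte_arm * (1 - spc_t * sv) + miss_vce_arm * (1 - sc)
    vce_n <- sum(vce_arm) + sum(cross_vce)
    cte_n <- sum(cte_arm) + sum(cross_cte) + staging_ct(vce_arm)
  }

  cost <- vapply(params$costs, function(cc) {
    (vce_n * cc[["vce"]] + cte_n * cc[["cte"]]) / size
  }, numeric(1))

  structure(list(strategy = strategy,
                 missed = missed,
                 missed_rounded = round_half_down(missed),
                 total_missed = sum(missed),
                 total_missed_rounded = sum(round_half_down(missed)),
                 detected = N - missed,
                 vce_count = vce_n,
                 cte_count = cte_n,
                 vce_count_rounded = round_half_down(vce_n),
                 cte_count_rounded = round_half_down(cte_n),
                 total_investigations = round_half_down(vce_n) +
                   round_half_down(cte_n),
                 cost_per_patient = cost,
                 cost_per_patient_rounded = round_half_down(cost)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("strategy %s\n", x$strategy))
  cat(sprintf("  missed: %s (total %d)\n",
              paste(sprintf("%s %d", names(x$missed), x$missed_rounded),
                    collapse = ", "),
              x$total_missed_rounded))
  cat(sprintf("  investigations: %d VCE + %d CTE = %d\n",
              x$vce_count_rounded, x$cte_count_rounded,
              x$total_investigations))
  cat(sprintf("  cost per patient: %s\n",
              paste(sprintf("%s %d", names(x$cost_per_patient_rounded),
                            x$cost_per_patient_rounded), collapse = ", ")))
  invisible(x)
}

#' Compare all six strategies
#'
#' Evaluates every strategy in [mural_strategies()] and assembles the
#' report table (one row per strategy: rounded missed counts, test counts,
#' per-patient costs, and the cost difference versus the VCE strategy),
#' with the exact expected values retained in additional columns.
#'
#' @inheritParams evaluate_strategy
#' @return A data.frame of class `cea_comparison`; the full
#'   `strategy_outcome` objects are attached as attribute `"outcomes"`.
#' @export
compare_strategies <- function(params = cea_parameters(),
                               compat_mural1_followup = FALSE) {
  outs <- lapply(mural_strategies(), evaluate_strategy, params = params,
                 compat_mural1_followup = compat_mural1_followup)
  names(outs) <- mural_strategies()
  currencies <- names(params$costs)
  tab <- do.call(rbind, lapply(outs, function(o) {
    row <- data.frame(strategy = o$strategy,
                      missed_angiodysplasia = o$missed_rounded[["angiodysplasia"]],
                      missed_ulcer = o$missed_rounded[["ulcer"]],
                      missed_tumor = o$missed_rounded[["tumor"]],
                      total_missed = o$total_missed_rounded,
                      vce = o$vce_count_rounded,
                      cte = o$cte_count_rounded,
                      total_investigations = o$total_investigations)
    for (cur in currencies) {
      row[[paste0("cost_", cur)]] <- o$cost_per_patient_rounded[[cur]]
      row[[paste0("cost_", cur, "_expected")]] <- o$cost_per_patient[[cur]]
    }
    row$expected_missed_angiodysplasia <- o$missed[["angiodysplasia"]]
    row$expected_missed_ulcer <- o$missed[["ulcer"]]
    row$expected_missed_tumor <- o$missed[["tumor"]]
    row$expected_vce <- o$vce_count
    row$expected_cte <- o$cte_count
    row
  }))
  for (cur in currencies) {
    tab[[paste0("cost_", cur, "_diff_vs_VCE")]] <-
      tab[[paste0("cost_", cur, "_expected")]] -
      tab[[paste0("cost_", cur, "_expected")]][tab$strategy == "VCE"]
  }
  rownames(tab) <- NULL
  attr(tab, "outcomes") <- outs
  class(tab) <- c("cea_comparison", "data.frame")
  tab
}

#' @export
print.cea_comparison <- function(x, ...) {
  cols <- c("strategy", "missed_angiodysplasia", "missed_ulcer",
            "missed_tumor", "total_missed", "vce", "cte",
            "total_investigations",
            grep("^cost_[A-Za-z]+$", names(x), value = TRUE))
  print.data.frame(x[, cols], row.names = FALSE)
  invisible(x)
}

#' Default one-way sensitivity ranges
#'
#' Published plausible ranges for each test-performance parameter
#' (sensitivity and specificity of each modality for each lesion type).
#'
#' @return Named list of `c(low, high)` ranges keyed by dotted parameter
#'   paths such as `"vce_sens.tumor"`.
#' @export
default_sensitivity_ranges <- function() {
  list("vce_sens.angiodysplasia" = c(0.60, 1.00),
       "vce_spec.angiodysplasia" = c(0.86, 1.00),
       "vce_sens.ulcer" = c(0.81, 1.00),
       "vce_spec.ulcer" = c(0.99, 1.00),
       "vce_sens.tumor" = c(0.33, 0.70),
       "vce_spec.tumor" = c(0.86, 1.00),
       "cte_sens.angiodysplasia" = c(0.00, 0.80),
       "cte_spec.angiodysplasia" = c(0.99, 1.00),
       "cte_sens.ulcer" = c(0.09, 0.667),
       "cte_spec.ulcer" = c(0.99, 1.00),
       "cte_sens.tumor" = c(0.70, 1.00),
       "cte_spec.tumor" = c(0.97, 1.00))
}

#' One-way sensitivity analysis
#'
#' Re-evaluates all strategies at the low and high endpoint of each
#' parameter range, holding every other parameter at base case, and returns
#' a tidy long table.
#'
#' @param params Base-case [cea_parameters()].
#' @param ranges Named list of `c(low, high)` numeric ranges keyed by dotted
#'   parameter paths (see [default_sensitivity_ranges()]). Probability
#'   parameters must stay inside `[0, 1]`.
#' @param strategies Strategies to evaluate.
#' @return A data.frame with columns `parameter`, `endpoint` (`"low"` /
#'   `"high"`), `value` (the parameter value used), `strategy`, `outcome`,
#'   `result` (expected, unrounded). Outcomes are the expected per-lesion
#'   and total missed counts, test counts and per-currency costs.
#' @export
one_way_sensitivity <- function(params = cea_parameters(),
                                ranges = default_sensitivity_ranges(),
                                strategies = mural_strategies()) {
  if (!is.list(ranges) || length(ranges) == 0L || is.null(names(ranges))) {
    stop("'ranges' must be a non-empty named list", call. = FALSE)
  }
  out <- list()
  for (pname in names(ranges)) {
    r <- ranges[[pname]]
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop(sprintf("malformed range for '%s': need numeric c(low, high)",
                   pname), call. = FALSE)
    }
    if (!startsWith(pname, "costs.") && any(r < 0 | r > 1)) {
      stop(sprintf("range for probability parameter '%s' must lie in [0, 1]",
                   pname), call. = FALSE)
    }
    for (k in 1:2) {
      p2 <- set_cea_parameter(params, pname, r[k])
      for (st in strategies) {
        o <- evaluate_strategy(st, p2)
        vals <- c(missed_angiodysplasia = o$missed[["angiodysplasia"]],
                  missed_ulcer = o$missed[["ulcer"]],
                  missed_tumor = o$missed[["tumor"]],
                  total_missed = o$total_missed,
                  vce_count = o$vce_count,
                  cte_count = o$cte_count,
                  stats::setNames(o$cost_per_patient,
                                  paste0("cost_", names(o$cost_per_patient))))
        out[[length(out) + 1L]] <- data.frame(
          parameter = pname,
          endpoint = c("low", "high")[k],
          value = r[k],
          strategy = st,
          outcome = names(vals),
          result = unname(vals))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
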