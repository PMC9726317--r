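#' Patient-level Monte-Carlo simulation of a diagnostic strategy
#'
#' Stochastic counterpart of [evaluate_strategy()], and its independent
#' oracle: each patient draws a lesion class from the prevalence mix, a
#' triage call (for the MURAL strategies) from the triage sensitivity /
#' specificity, and for every administered test an own-lesion detection
#' Bernoulli(sensitivity) plus -- in non-tumor patients -- an independent
#' false tumor call Bernoulli(1 - tumor specificity). Test conventions
#' (staging CTEs, crossover rules, additive test counting) mirror
#' [evaluate_strategy()] exactly, so per-patient tallies divided by `n`
#' converge to the analytic expected values per patient.
#'
#' @param n Number of simulated patients (> 0).
#' @param params A [cea_parameters()] object.
#' @param strategy One of [mural_strategies()].
#' @param seed Integer seed.
#' @param keep_trajectories Attach the per-patient data.frame (lesion,
#'   triage routing, test administrations, detection, miss flag). Defaults
#'   to TRUE for n <= 10000 to keep large runs lean.
#' @return A list of class `diagnostic_simulation`: `n`, `strategy`,
#'   `tallies` (a list with named `missed` counts, `lesion_counts`,
#'   `vce_count`, `cte_count`, `cost_total` and `cost_per_patient` per
#'   currency) and, optionally, `trajectories`.
#' @export
simulate_diagnostic_cohort <- function(n, params = cea_parameters(), strategy,
                                       seed,
                                       keep_trajectories = n <= 10000) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0 ||
      n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (!strategy %in% mural_strategies()) {
    stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
  }
  stopifnot(inherits(params, "cea_parameters"))
  n <- as.integer(n)
  lesions <- names(params$prevalence)
  sv <- params$vce_sens
  sc <- params$cte_sens
  spv_t <- params$vce_spec[["tumor"]]
  spc_t <- params$cte_spec[["tumor"]]

  withr::with_seed(seed, {
    les <- sample.int(length(lesions), n, replace = TRUE,
                      prob = params$prevalence)
    tumor <- les == which(lesions == "tumor")

    # one VCE exam for patients in `on`: own detection + tumor call
    vce_exam <- function(on) {
      det <- logical(n)
      call <- logical(n)
      det[on] <- stats::rbinom(sum(on), 1L, sv[les[on]]) == 1L
      nt <- on & !tumor
      call[nt] <- stats::rbinom(sum(nt), 1L, 1 - spv_t) == 1L
      call[on & tumor] <- det[on & tumor]
      list(det = det, call = call)
    }
    # one CTE exam: own detection + "CTE positive for something else"
    # (false tumor call), which blocks crossover of a missed patient
    cte_exam <- function(on) {
      det <- logical(n)
      fpos <- logical(n)
      det[on] <- stats::rbinom(sum(on), 1L, sc[les[on]]) == 1L
      fpos[on] <- stats::rbinom(sum(on), 1L, 1 - spc_t) == 1L
      list(det = det, fpos = fpos)
    }

    all_on <- rep(TRUE, n)
    to_cte <- logical(n)
    vce_n <- 0
    cte_n <- 0
    detected <- logical(n)

    if (strategy == "VCE") {
      v <- vce_exam(all_on)
      detected <- v$det
      vce_n <- n
      cte_n <- sum(v$call)
    } else if (strategy == "CTE") {
      ct <- cte_exam(all_on)
      detected <- ct$det
      cte_n <- n
    } else if (strategy == "MURAL-1") {
      q <- ifelse(tumor, params$triage_sens, 1 - params$triage_spec)
      to_cte <- stats::rbinom(n, 1L, q) == 1L
      ct <- cte_exam(to_cte)
      v <- vce_exam(!to_cte)
      detected <- ifelse(to_cte, ct$det, v$det)
      vce_n <- sum(!to_cte)
      cte_n <- sum(to_cte) + sum(v$call[!to_cte])
    } else if (strategy == "VCE-CTE") {
      v <- vce_exam(all_on)
      cross <- !v$det
      ct <- cte_exam(cross)
      detected <- v$det | (cross & ct$det)
      vce_n <- n
      cte_n <- sum(cross) + sum(v$call)
    } else if (strategy == "CTE-VCE") {
      ct <- cte_exam(all_on)
      cross <- !ct$det & !ct$fpos   # negatives without a false call cross over
      v <- vce_exam(cross)
      detected <- ct$det | (cross & v$det)
      cte_n <- n
      vce_n <- sum(cross)
    } else {  # MURAL-2
      q <- ifelse(tumor, params$triage_sens, 1 - params$triage_spec)
      to_cte <- stats::rbinom(n, 1L, q) == 1L
      ct1 <- cte_exam(to_cte)
      v1 <- vce_exam(!to_cte)
      cross_vce <- to_cte & !ct1$det & !ct1$fpos
      cross_cte <- !to_cte & !v1$det
      v2 <- vce_exam(cross_vce)
      ct2 <- cte_exam(cross_cte)
      detected <- (to_cte & (ct1$det | (cross_vce & v2$det))) |
        (!to_cte & (v1$det | (cross_cte & ct2$det)))
      vce_n <- sum(!to_cte) + sum(cross_vce)
      cte_n <- sum(to_cte) + sum(cross_cte) + sum(v1$call[!to_cte])
    }

    missed <- tabulate(les[!detected], nbins = length(lesions))
    names(missed) <- lesions
    lesion_counts <- tabulate(les, nbins = length(lesions))
    names(lesion_counts) <- lesions
    cost_total <- vapply(params$costs, function(cc) {
      vce_n * cc[["vce"]] + cte_n * cc[["cte"]]
    }, numeric(1))

    out <- list(n = n, strategy = strategy,
                tallies = list(missed = missed,
                               lesion_counts = lesion_counts,
                               vce_count = vce_n,
                               cte_count = cte_n,
                               cost_total = cost_total,
                               cost_per_patient = cost_total / n))
    if (keep_trajectories) {
      out$trajectories <- data.frame(lesion = lesions[les],
                                     triaged_to_cte = to_cte,
                                     detected = detected,
                                     missed = !detected)
    }
    structure(out, class = "diagnostic_simulation")
  })
}

#' @export
print.diagnostic_simulation <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("simulated %s strategy, n = %d patients\n", x$strategy, x$n))
  cat(sprintf("  missed: %s\n",
              paste(sprintf("%s %d/%d", names(t$missed), t$missed,
                            t$lesion_counts), collapse = ", ")))
  cat(sprintf("  tests: %d VCE + %d CTE; cost per patient %s\n",
              t$vce_count, t$cte_count,
              paste(sprintf("%s %.2f", names(t$cost_per_patient),
                            t$cost_per_patient), collapse = ", ")))
  invisible(x)
}
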