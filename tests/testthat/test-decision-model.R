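# six-strategy expected-value engine and one-way sensitivity analysis

test_that("perfect tests miss nothing in any strategy", {
  for (st in mural_strategies()) {
    o <- evaluate_strategy(st, perfect_params())
    expect_equal(unname(o$missed), c(0, 0, 0))
  }
})

test_that("expected detected + missed = prevalence * cohort size", {
  withr::with_seed(8, {
    for (i in 1:15) {
      pr <- rgamma(3, 2) + 0.05
      pr <- pr / sum(pr)
      p <- cea_parameters(
        cohort_size = sample(c(50, 100, 250), 1),
        prevalence = c(angiodysplasia = pr[1], ulcer = pr[2], tumor = pr[3]),
        vce_sens = c(angiodysplasia = runif(1), ulcer = runif(1),
                     tumor = runif(1)),
        cte_sens = c(angiodysplasia = runif(1), ulcer = runif(1),
                     tumor = runif(1)),
        triage_sens = runif(1), triage_spec = runif(1))
      for (st in mural_strategies()) {
        o <- evaluate_strategy(st, p)
        expect_equal(o$detected + o$missed, p$prevalence * p$cohort_size)
        expect_true(all(o$missed >= 0))
        expect_gte(o$vce_count, 0)
        expect_gte(o$cte_count, 0)
      }
    }
  })
})

test_that("adding a second test never increases misses", {
  withr::with_seed(14, {
    for (i in 1:10) {
      p <- cea_parameters(
        vce_sens = c(angiodysplasia = runif(1), ulcer = runif(1),
                     tumor = runif(1)),
        cte_sens = c(angiodysplasia = runif(1), ulcer = runif(1),
                     tumor = runif(1)))
      expect_true(all(evaluate_strategy("VCE-CTE", p)$missed <=
                        evaluate_strategy("VCE", p)$missed))
      expect_true(all(evaluate_strategy("CTE-VCE", p)$missed <=
                        evaluate_strategy("CTE", p)$missed))
      expect_true(all(evaluate_strategy("MURAL-2", p)$missed <=
                        evaluate_strategy("MURAL-1", p)$missed))
    }
  })
})

test_that("a perfect triage collapses MURAL-1 onto the per-class arms", {
  p <- cea_parameters(triage_sens = 1, triage_spec = 1)
  o <- evaluate_strategy("MURAL-1", p)
  cte <- evaluate_strategy("CTE", p)
  vce <- evaluate_strategy("VCE", p)
  # tumors all routed to CTE; mucosal lesions all routed to VCE
  expect_equal(o$missed[["tumor"]], cte$missed[["tumor"]])
  expect_equal(o$missed[["tumor"]],
               p$prevalence[["tumor"]] * 100 * (1 - p$cte_sens[["tumor"]]))
  expect_equal(o$missed[["angiodysplasia"]], vce$missed[["angiodysplasia"]])
  expect_equal(o$missed[["ulcer"]], vce$missed[["ulcer"]])
})

test_that("cost per patient is linear in unit costs", {
  p1 <- cea_parameters()
  p2 <- cea_parameters(costs = list(USD = c(vce = 2 * 1247, cte = 2 * 518),
                                    THB = c(vce = 2 * 42000,
                                            cte = 2 * 15400)))
  for (st in mural_strategies()) {
    expect_equal(evaluate_strategy(st, p2)$cost_per_patient,
                 2 * evaluate_strategy(st, p1)$cost_per_patient)
  }
})

test_that("invalid strategies and parameters are rejected", {
  expect_error(evaluate_strategy("DAE"), "unknown strategy")
  expect_error(cea_parameters(prevalence = c(angiodysplasia = 0.5,
                                             ulcer = 0.4, tumor = 0.2)),
               "sum to 1")
  expect_error(cea_parameters(triage_sens = 1.2), "probability")
  expect_error(cea_parameters(costs = list(USD = c(vce = -1, cte = 518))))
})

test_that("compare_strategies assembles the six-row report", {
  tab <- compare_strategies()
  expect_equal(tab$strategy, mural_strategies())
  expect_equal(nrow(tab), 6)
  # headline comparison: triage is cheaper than capsule-first in both
  # currencies
  m1 <- tab[tab$strategy == "MURAL-1", ]
  vce <- tab[tab$strategy == "VCE", ]
  expect_lt(m1$cost_USD_expected, vce$cost_USD_expected)
  expect_lt(m1$cost_THB_expected, vce$cost_THB_expected)
  expect_equal(vce$cost_USD_diff_vs_VCE, 0)
  expect_lt(m1$cost_USD_diff_vs_VCE, 0)
  # total investigations = rounded VCE + rounded CTE
  expect_equal(tab$total_investigations, tab$vce + tab$cte)
})

test_that("the compat flag reproduces the published MURAL-1 follow-up heuristic", {
  first <- evaluate_strategy("MURAL-1")
  compat <- evaluate_strategy("MURAL-1", compat_mural1_followup = TRUE)
  # first principles: 31.5 triaged CTEs + staging calls from the VCE arm
  expect_equal(first$cte_count, 31.5 + (5.3 * 0.55 + 63.2 * 0.10),
               tolerance = 1e-9)
  # heuristic: 19 follow-up CTEs per 100 capsule patients applied to the arm
  expect_equal(compat$cte_count, 31.5 + 68.5 * 0.19, tolerance = 1e-9)
  expect_identical(first$missed, compat$missed)
})

test_that("one_way_sensitivity spans parameter ranges correctly", {
  base <- evaluate_strategy("VCE")
  # collapsed range reproduces the base case
  s0 <- one_way_sensitivity(ranges = list("vce_sens.tumor" = c(0.55, 0.55)),
                            strategies = "VCE")
  expect_equal(unique(s0$result[s0$outcome == "missed_tumor"]),
               base$missed[["tumor"]])
  # endpoints: expected missed tumors are 20 * (1 - sens)
  s1 <- one_way_sensitivity(ranges = list("vce_sens.tumor" = c(0.33, 0.70)),
                            strategies = "VCE")
  got <- s1$result[s1$outcome == "missed_tumor"]
  expect_equal(got[s1$endpoint[s1$outcome == "missed_tumor"] == "low"], 13.4)
  expect_equal(got[s1$endpoint[s1$outcome == "missed_tumor"] == "high"], 6.0)
  s2 <- one_way_sensitivity(ranges = list("cte_sens.tumor" = c(0.70, 1.00)),
                            strategies = "CTE")
  expect_equal(s2$result[s2$outcome == "missed_tumor" &
                           s2$endpoint == "low"], 6.0)
  # default ranges give the tidy long schema over all strategies
  full <- one_way_sensitivity()
  expect_setequal(names(full), c("parameter", "endpoint", "value",
                                 "strategy", "outcome", "result"))
  expect_equal(length(unique(full$parameter)),
               length(default_sensitivity_ranges()))
  expect_error(one_way_sensitivity(ranges = list(bad = c(0.9, 0.1))),
               "malformed")
  expect_error(one_way_sensitivity(ranges = list("vce_sens.tumor" = c(0, 2))),
               "0, 1")
})

test_that("analytic expected values match patient-level simulation", {
  # mutual-oracle check at moderate n; the acceptance suite runs n = 1e6
  p <- cea_parameters()
  for (st in c("MURAL-1", "CTE-VCE")) {
    sim <- simulate_diagnostic_cohort(2e5, p, st, seed = 123,
                                      keep_trajectories = FALSE)
    ana <- evaluate_strategy(st, p)
    t <- sim$tallies
    mf <- t$missed / t$lesion_counts
    ef <- ana$missed / (p$prevalence * p$cohort_size)
    se <- sqrt(ef * (1 - ef) / t$lesion_counts)
    expect_true(all(abs(mf - ef) < 3 * se))
    expect_equal(t$vce_count / sim$n * 100, ana$vce_count, tolerance = 0.02)
    expect_equal(t$cte_count / sim$n * 100, ana$cte_count, tolerance = 0.02)
  }
})
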