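# synthetic cohort generation and the patient-level diagnostic simulator

test_that("generation is seed-deterministic and respects bounds", {
  spec <- synthetic_cohort_spec("group", n = 500, seed = 31)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c2 <- generate_cohort(synthetic_cohort_spec("group", n = 500, seed = 32))
  expect_false(identical(a, c2))

  expect_true(all(a$age >= 18 & a$age <= 100))
  expect_true(all(a$albumin >= 1 & a$albumin <= 6))
  flags <- c("sex", "diabetes", "atherosclerosis", "ckd", "antiplatelet",
             "mural")
  for (f in flags) expect_true(all(a[[f]] %in% c(0, 1)))

  expect_equal(nrow(generate_cohort(synthetic_cohort_spec("group", n = 0,
                                                          seed = 1))), 0)
  expect_error(synthetic_cohort_spec("group", n = -1, seed = 1))
  bad <- mural_group_distributions()
  bad$mural$normals$age[["sd"]] <- -1
  expect_error(synthetic_cohort_spec("group", n = 10, seed = 1,
                                     group_distributions = bad), "age")
})

test_that("group-conditional moments converge to their targets", {
  # closed-form mean of a truncated Normal: the exact target of the
  # rejection sampler (for the mural group's age the shift from 57.7 is
  # < 0.03 years, so the published mean is recovered within Monte-Carlo
  # error)
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  coh <- generate_cohort(synthetic_cohort_spec("group", n = 1e5, seed = 77))
  mural <- coh[coh$mural == 1, ]
  nonm <- coh[coh$mural == 0, ]
  # mural-group mean age within 3 standard errors of 57.7
  expect_lt(abs(mean(mural$age) - 57.7), 3 * 13.0 / sqrt(nrow(mural)) + 0.03)
  expect_lt(abs(mean(nonm$age) - trunc_mean(65.3, 15.4, 18, 100)),
            3 * 15.4 / sqrt(nrow(nonm)))
  expect_lt(abs(mean(mural$albumin) - trunc_mean(3.87, 0.71, 1, 6)),
            3 * 0.71 / sqrt(nrow(mural)))
  expect_lt(abs(mean(coh$mural) - 34 / 196),
            3 * sqrt((34 / 196) * (1 - 34 / 196) / 1e5))
  # per-group Bernoulli rates
  expect_lt(abs(mean(mural$antiplatelet) - 0.088),
            3 * sqrt(0.088 * 0.912 / nrow(mural)))
  expect_lt(abs(mean(nonm$atherosclerosis) - 0.389),
            3 * sqrt(0.389 * 0.611 / nrow(nonm)))
  expect_equal(sum(mural$immunocompromised), 0)
})

test_that("mechanism mode labels follow the logistic probabilities", {
  spec <- synthetic_cohort_spec("mechanism", n = 1e5, seed = 55)
  coh <- generate_cohort(spec)
  p <- mural_probability(coh, spec$coefficients) / 100
  # empirical mural fraction within 3 SE of the mean model probability
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(coh$mural) - mean(p)), 3 * se)
})

test_that("diagnostic simulation honors its contracts", {
  # perfect sensitivity: deterministically zero missed
  for (st in mural_strategies()) {
    sim <- simulate_diagnostic_cohort(2000, perfect_params(), st, seed = 5)
    expect_equal(unname(sim$tallies$missed), c(0, 0, 0))
  }
  # determinism
  s1 <- simulate_diagnostic_cohort(3000, base_params(), "MURAL-2", seed = 8)
  s2 <- simulate_diagnostic_cohort(3000, base_params(), "MURAL-2", seed = 8)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$trajectories), 3000)
  expect_true(all(c("lesion", "triaged_to_cte", "detected", "missed") %in%
                    names(s1$trajectories)))
  # tumor patients detected by a capsule-only strategy at its sensitivity
  sim <- simulate_diagnostic_cohort(1e5, base_params(), "VCE", seed = 99,
                                    keep_trajectories = TRUE)
  tum <- sim$trajectories[sim$trajectories$lesion == "tumor", ]
  expect_lt(abs(mean(tum$detected) - 0.55),
            3 * sqrt(0.55 * 0.45 / nrow(tum)))
  # cost identity
  t <- sim$tallies
  expect_equal(unname(t$cost_total[["USD"]]),
               t$vce_count * 1247 + t$cte_count * 518)
  expect_error(simulate_diagnostic_cohort(0, base_params(), "VCE", 1))
  expect_error(simulate_diagnostic_cohort(10, base_params(), "PET", 1),
               "unknown")
})
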