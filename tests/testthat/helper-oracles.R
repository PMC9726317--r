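# Independent oracles used across the suite. Each is deliberately naive
# (brute force / enumeration / grid refinement) and never shares code with
# the implementation it checks.

# Mann-Whitney statistic P(score_pos > score_neg) + P(tie)/2, by full
# enumeration of positive-negative pairs
oracle_mann_whitney <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over every observed threshold (>= rule), ties
# broken towards the larger cutoff
oracle_youden_exhaustive <- function(scores, labels) {
  best_j <- -Inf
  best_c <- NA_real_
  for (thr in sort(unique(scores), decreasing = TRUE)) {
    pred <- as.numeric(scores >= thr)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    # ties within numerical noise go to the first (largest) threshold
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- thr
    }
  }
  list(cutoff = best_c, j = best_j)
}

# iterative grid-refinement maximizer of the intercept+slope logistic
# log-likelihood; independent of any Newton iteration
oracle_grid_logistic <- function(x, y, center = c(0, 0), half_width = 5) {
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  best <- center
  hw <- half_width
  for (step in c(0.1, 0.01, 0.001, 1e-4)) {
    g0 <- seq(best[1] - hw, best[1] + hw, by = step)
    g1 <- seq(best[2] - hw, best[2] + hw, by = step)
    vals <- outer(g0, g1, Vectorize(ll))
    k <- arrayInd(which.max(vals), dim(vals))
    best <- c(g0[k[1]], g1[k[2]])
    hw <- 2 * step
  }
  best
}

# expand a 2x2 exposure-outcome table into patient rows:
# a = exposed cases, b = exposed controls, c = unexposed cases,
# d = unexposed controls
expand_2x2 <- function(a, b, c, d) {
  data.frame(x = c(rep(1, a + b), rep(0, c + d)),
             y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

# small labelled cohort with a clean albumin-driven outcome, for pipeline
# plumbing tests
fixture_cohort <- function(n = 80, seed = 7, deterministic_albumin = FALSE) {
  withr::with_seed(seed, {
    coh <- data.frame(
      age = runif(n, 25, 90),
      sex = rbinom(n, 1, 0.5),
      diabetes = rbinom(n, 1, 0.3),
      atherosclerosis = rbinom(n, 1, 0.35),
      ckd = rbinom(n, 1, 0.3),
      chronic_liver_disease = rbinom(n, 1, 0.1),
      immunocompromised = rbinom(n, 1, 0.05),
      cancer_history = rbinom(n, 1, 0.15),
      nsaids = rbinom(n, 1, 0.06),
      antiplatelet = rbinom(n, 1, 0.3),
      anticoagulant = rbinom(n, 1, 0.15),
      overt_bleeding = rbinom(n, 1, 0.65),
      abdominal_pain = rbinom(n, 1, 0.05),
      weight_loss = rbinom(n, 1, 0.08),
      hemoglobin = rnorm(n, 7.3, 2),
      albumin = runif(n, 1.5, 5.5))
    coh$mural <- if (deterministic_albumin) {
      as.numeric(coh$albumin > 3.5)
    } else {
      rbinom(n, 1, plogis(-4 + 1 * coh$albumin))
    }
    coh
  })
}

base_params <- function() cea_parameters()

# perfect tests: every sensitivity 1
perfect_params <- function() {
  cea_parameters(vce_sens = c(angiodysplasia = 1, ulcer = 1, tumor = 1),
                 cte_sens = c(angiodysplasia = 1, ulcer = 1, tumor = 1))
}
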