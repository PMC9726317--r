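#' Maximum-likelihood logistic regression
#'
#' Newton-Raphson (IRLS) fit of a binary-outcome logistic model, written to
#' a fixed numerical contract: convergence when the score (gradient) norm
#' falls below `score_tol` or the relative log-likelihood change falls below
#' `loglik_tol`, at most `max_iter` iterations; standard errors from the
#' inverse observed information; and an explicit divergence detector -- any
#' coefficient exceeding `coef_limit` in absolute value during iteration is
#' treated as complete or quasi-complete separation and raised as an error
#' (this is what produces the "cannot calculate" rows of a univariate
#' screen when a covariate has zero exposed cases).
#'
#' @param x Predictor matrix (or vector), one row per observation, without
#'   an intercept column unless `add_intercept = FALSE`.
#' @param y 0/1 outcome vector.
#' @param add_intercept Prepend an intercept column (default TRUE).
#' @param max_iter Maximum Newton iterations.
#' @param score_tol Convergence tolerance on the max-abs score.
#' @param loglik_tol Convergence tolerance on the relative log-likelihood
#'   change.
#' @param coef_limit Separation guard on abs(coefficient).
#' @return A list of class `fitted_logistic`: `coefficients` (intercept
#'   first), `se`, `vcov`, `log_likelihood`, `converged`, `iterations`, `n`.
#' @export
fit_logistic_ml <- function(x, y, add_intercept = TRUE, max_iter = 100L,
                            score_tol = 1e-8, loglik_tol = 1e-10,
                            coef_limit = 15) {
  y <- as.numeric(y)
  check_binary(y, "y")
  if (all(y == y[1])) {
    stop("outcome is constant: logistic model is not identifiable",
         call. = FALSE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) {
    stop("'x' and 'y' dimensions do not match", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("'x' must be finite with no missing values", call. = FALSE)
  }
  X <- if (add_intercept) cbind("(Intercept)" = 1, x) else x
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(X)[colnames(X) == ""] <- paste0("x", which(colnames(X) == ""))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank-deficient", call. = FALSE)
  }

  beta <- numeric(ncol(X))
  ll_old <- NA_real_
  converged <- FALSE
  it <- 0L
  H <- NULL
  repeat {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
    H <- crossprod(X, X * (p * (1 - p)))
    if (max(abs(score)) < score_tol ||
        (!is.na(ll_old) &&
         abs(ll - ll_old) < loglik_tol * (abs(ll_old) + loglik_tol))) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    it <- it + 1L
    beta <- beta + solve(H, score)
    if (any(abs(beta) > coef_limit)) {
      stop("separation detected: a coefficient diverged beyond the limit; ",
           "the maximum-likelihood estimate does not exist", call. = FALSE)
    }
    ll_old <- ll
  }

  vcov <- solve(H)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 se = sqrt(diag(vcov)),
                 vcov = vcov,
                 log_likelihood = sum(stats::dbinom(
                   y, 1, stats::plogis(drop(X %*% beta)), log = TRUE)),
                 converged = converged,
                 iterations = it,
                 n = length(y)),
            class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, logLik = %.4f, %s in %d iterations\n",
              x$n, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}
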