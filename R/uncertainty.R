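#' Nonparametric bootstrap confidence intervals
#'
#' Subjects are resampled with replacement and the model is refitted to
#' each replicate; percentile intervals are formed from the converged
#' replicates, with non-converged replicates counted and excluded.  A
#' resample's likelihood is the multiplicity-weighted sum of the unique
#' subjects' contributions, so each refit re-optimises the weighted FOCE
#' objective directly (warm-started at the original estimates with the
#' original fit's curvature as the initial Hessian approximation) instead
#' of materialising a resampled dataset.
#'
#' @param fit A [pkfit()] object fitted with standard errors
#'   (`control se = TRUE`), whose curvature seeds the refits.
#' @param dataset The dataset the fit used (retained for interface
#'   symmetry; the fit's prepared data are used).
#' @param n_reps Number of bootstrap replicates.
#' @param level Confidence level (default 0.95).
#' @param maxit,tol Refit optimiser budget per replicate.
#' @param indices Optional list of subject-index vectors, one per
#'   replicate, overriding the random resampling (used for deterministic
#'   checks).
#' @return List with `ci` (data frame: parameter, estimate, lower,
#'   upper), `reps` (matrix of replicate estimates), `n_failed`.
#' @export
bootstrap_ci <- function(fit, dataset = NULL, n_reps = 1000, level = 0.95,
                         maxit = 40, tol = 1e-3, indices = NULL) {
  stopifnot(n_reps >= 1)
  n <- fit$data$n
  # refits tolerate a looser conditional-mode gradient stop: the BFGS
  # uses coarse finite-difference steps that are insensitive to the
  # residual objective noise this leaves behind
  fit$control$inner_gtol <- max(fit$control$inner_gtol, 1e-5)
  tr <- transformed_estimates(fit)
  Hinv <- tr$vcov
  if (is.null(Hinv))
    Hinv <- diag((0.05 * pmax(abs(tr$z), 0.1))^2, length(tr$z))
  free_names <- names(tr$z)
  reps <- matrix(NA_real_, n_reps, length(free_names),
                 dimnames = list(NULL, free_names))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    take <- if (is.null(indices)) sample.int(n, replace = TRUE) else
      indices[[r]]
    w <- tabulate(take, nbins = n)
    fn <- weighted_objective(fit, w)
    res <- try(warm_bfgs(fn, tr$z, Hinv, maxit = maxit, tol = tol),
               silent = TRUE)
    if (inherits(res, "try-error") || !res$converged ||
        !is.finite(res$objective) || res$objective >= 1e10) {
      n_failed <- n_failed + 1L
      next
    }
    reps[r, ] <- ifelse(tr$is_var, exp(res$par), res$par)
  }
  a <- (1 - level) / 2
  ok <- stats::complete.cases(reps)
  if (!any(ok)) stop("no bootstrap replicate converged")
  ci <- data.frame(
    parameter = free_names,
    estimate = fit$estimates[fit$free],
    lower = apply(reps[ok, , drop = FALSE], 2, quantile, a),
    upper = apply(reps[ok, , drop = FALSE], 2, quantile, 1 - a)
  )
  rownames(ci) <- NULL
  list(ci = ci, reps = reps, n_failed = n_failed, level = level)
}

#' Sampling-importance-resampling intervals for a general objective
#'
#' Draws proposals from a multivariate normal around `center` with
#' covariance `vcov`, weights each draw by the ratio of the model
#' likelihood `exp(-obj/2)` to the proposal density, resamples
#' `n_resample` draws without replacement with probability proportional
#' to the weights, and returns percentile intervals of the resample.
#'
#' @param objfun Function mapping a parameter vector to the -2
#'   log-likelihood objective.
#' @param center Parameter vector at the objective minimum.
#' @param vcov Proposal covariance matrix.
#' @param n_samples Number of proposal draws.
#' @param n_resample Number of draws retained (without replacement).
#' @param level Confidence level.
#' @param inflate Proposal covariance inflation factor.
#' @return List with `ci` (data frame), `ess` (effective sample size),
#'   `degenerate` (TRUE when ESS < 10 percent of `n_samples`) and the
#'   resampled matrix.
#' @export
sir_intervals <- function(objfun, center, vcov, n_samples = 1000,
                          n_resample = max(1, round(n_samples / 10)),
                          level = 0.95, inflate = 1) {
  p <- length(center)
  stopifnot(n_resample <= n_samples)
  S <- inflate * (vcov + t(vcov)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) stop("proposal covariance must be positive definite")
  A <- e$vectors %*% diag(sqrt(e$values), p)
  Z <- matrix(rnorm(n_samples * p), p)
  X <- t(center + A %*% Z)
  Sinv <- e$vectors %*% diag(1 / e$values, p) %*% t(e$vectors)
  # log proposal density (constant terms cancel in the weights)
  d <- X - matrix(center, n_samples, p, byrow = TRUE)
  logq <- -0.5 * rowSums((d %*% Sinv) * d)
  obj <- apply(X, 1, objfun)
  obj[!is.finite(obj)] <- Inf
  logw <- -obj / 2 - logq
  logw <- logw - max(logw[is.finite(logw)])
  w <- exp(logw)
  w[!is.finite(w)] <- 0
  ess <- sum(w)^2 / sum(w^2)
  idx <- sample.int(n_samples, n_resample, replace = FALSE,
                    prob = pmax(w, 1e-300))
  R <- X[idx, , drop = FALSE]
  a <- (1 - level) / 2
  nm <- names(center)
  if (is.null(nm)) nm <- paste0("p", seq_len(p))
  ci <- data.frame(parameter = nm,
                   estimate = center,
                   lower = apply(R, 2, quantile, a),
                   upper = apply(R, 2, quantile, 1 - a))
  rownames(ci) <- NULL
  list(ci = ci, ess = ess, degenerate = ess < 0.1 * n_samples,
       resample = R, weights = w)
}

#' SIR intervals for a fitted population PK model
#'
#' Applies [sir_intervals()] to a [pkfit()] object: proposals come from
#' the asymptotic normal approximation at the estimates (curvature-based
#' covariance), the weight numerator is the FOCE likelihood, and
#' variance parameters are handled on the estimation (log) scale.
#'
#' @param fit A converged [pkfit()] with a valid `vcov`.
#' @param dataset The dataset the fit used.
#' @param n_samples,n_resample,level,inflate See [sir_intervals()].
#' @return As [sir_intervals()], on the natural parameter scale.
#' @export
sir_ci <- function(fit, dataset, n_samples = 1000,
                   n_resample = max(1, round(n_samples / 10)),
                   level = 0.95, inflate = 1) {
  if (is.null(fit$vcov))
    stop("fit has no curvature estimate; rerun pkfit with control se = TRUE")
  tr <- transformed_estimates(fit)
  objfun <- weighted_objective(fit, rep(1, fit$data$n))
  res <- sir_intervals(objfun, tr$z, tr$vcov, n_samples, n_resample,
                       level, inflate)
  # back-transform the interval to the natural scale
  for (cn in c("estimate", "lower", "upper"))
    res$ci[[cn]] <- ifelse(tr$is_var, exp(res$ci[[cn]]), res$ci[[cn]])
  res$resample[, tr$is_var] <- exp(res$resample[, tr$is_var])
  res
}
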