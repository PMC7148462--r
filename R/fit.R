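# --- dataset preparation -----------------------------------------------------

prep_nlme_data <- function(dataset, analyte = "PIPC",
                           blq = c("exclude", "loq2"), loq = 0.5) {
  blq <- match.arg(blq)
  ds <- dataset[dataset$analyte == analyte, , drop = FALSE]
  if (!nrow(ds)) stop("no records for analyte ", analyte)
  obs <- ds[ds$evid == 0L, , drop = FALSE]
  if (blq == "exclude") {
    obs <- obs[!obs$blq, , drop = FALSE]
  } else {
    obs$dv[obs$blq] <- loq / 2
  }
  doses <- ds[ds$evid == 1L, , drop = FALSE]
  ids <- unique(ds$id)
  obs <- obs[order(match(obs$id, ids), obs$time), , drop = FALSE]
  doses <- doses[order(match(doses$id, ids), doses$time), , drop = FALSE]
  n_obs_i <- vapply(ids, function(i) sum(obs$id == i), 0L)
  if (any(n_obs_i == 0))
    stop("every subject needs at least one usable observation")
  # keep every non-record column as a potential covariate
  subjects <- ds[!duplicated(ds$id),
                 setdiff(names(ds), c("analyte", "time", "evid", "amt",
                                      "dur", "dv", "blq")),
                 drop = FALSE]
  subjects <- subjects[match(ids, subjects$id), , drop = FALSE]
  list(y = obs$dv, tobs = obs$time,
       obs_start = c(0L, cumsum(n_obs_i)),
       dtd = doses$time, damt = doses$amt, ddur = doses$dur,
       dose_start = c(0L, cumsum(vapply(ids, function(i)
         sum(doses$id == i), 0L))),
       subjects = subjects, ids = ids, n = length(ids))
}

typ_matrix <- function(theta_struct, cov_specs, subjects, n_cmt) {
  pn <- struct_param_names(n_cmt)
  n <- nrow(subjects)
  typ <- matrix(rep(theta_struct[pn], each = n), nrow = n,
                dimnames = list(NULL, pn))
  for (spec in cov_specs) {
    x <- subjects[[spec$cov]]
    typ[, spec$param] <- apply_covariate(typ[, spec$param], spec, x)
  }
  typ
}

# --- objective ---------------------------------------------------------------

#' FOCE marginal likelihood approximation
#'
#' Per subject, the conditional mode of the random effects minimises the
#' penalised weighted deviance
#' `sum_j [(y - f(eta))^2 / v(eta) + log v(eta)] + eta' Omega^-1 eta`
#' with `v = sigma2_prop * f^2 + sigma2_add` evaluated at the conditional
#' prediction (FOCE with interaction).  The subject's -2 log marginal
#' likelihood is then the Laplace expansion at the mode using the
#' Gauss-Newton (expected) curvature:
#' `g(eta_hat) + log det(Omega_active) + n_i log(2 pi) +
#'  log det(H(eta_hat) / 2)`,
#' summed over subjects.  All 2 pi constants are kept, so the value is
#' directly comparable to quadrature evaluations of -2 log L.
#'
#' @param dataset Concentration dataset (see [generate_dataset()]).
#' @param analyte Which analyte's records to use.
#' @param n_cmt Number of compartments (1 or 2).
#' @param covariates List of [covariate_spec()] objects whose `theta`
#'   slots hold the covariate coefficients to evaluate.
#' @param theta Named structural typical values.
#' @param omega2 Named inter-individual variances (0 = no random effect).
#' @param sigma2 `c(prop = , add = )` residual variances.
#' @param blq Below-LOQ handling, `"exclude"` (default) or `"loq2"`.
#' @return List with `obj` (total OBJ), `obj_i` (per subject), `eta`
#'   (conditional modes, one row per subject) and `conv` (inner
#'   convergence flags).
#' @export
foce_objective <- function(dataset, analyte = "PIPC", n_cmt = 2,
                           covariates = list(), theta, omega2,
                           sigma2, blq = "exclude") {
  d <- prep_nlme_data(dataset, analyte, blq)
  pn <- struct_param_names(n_cmt)
  typ <- typ_matrix(theta[pn], covariates, d$subjects, n_cmt)
  res <- cpp_foce_obj(d$y, d$tobs, d$obs_start, d$dtd, d$damt, d$ddur,
                      d$dose_start, typ, as.integer(n_cmt),
                      as.numeric(omega2[pn]),
                      as.numeric(sigma2[c("prop", "add")]),
                      matrix(0, d$n, length(pn)), 100L, 1e-8, FALSE,
                      rep(1, d$n), 1e-7)
  list(obj = res$obj, obj_i = as.numeric(res$obj_i), eta = res$eta,
       conv = as.logical(res$conv))
}

#' Optimiser and standard-error settings for [pkfit()]
#'
#' @param iter_max,eval_max Outer optimiser budget (nlminb).
#' @param rel_tol Outer relative convergence tolerance.
#' @param inner_maxit,inner_tol Conditional-mode search budget per subject.
#' @param inner_gtol Gradient-norm (relative) stop for the
#'   conditional-mode search.
#' @param se Compute asymptotic standard errors from a central-difference
#'   Hessian of OBJ/2 at the optimum?
#' @return A list of control settings.
#' @export
pkfit_control <- function(iter_max = 200, eval_max = 800, rel_tol = 1e-8,
                          inner_maxit = 100, inner_tol = 1e-8,
                          inner_gtol = 1e-7, se = TRUE) {
  list(iter_max = iter_max, eval_max = eval_max, rel_tol = rel_tol,
       inner_maxit = inner_maxit, inner_tol = inner_tol,
       inner_gtol = inner_gtol, se = se)
}

cov_par_names <- function(covariates) {
  if (!length(covariates)) return(character())
  paste0("theta.", vapply(covariates, function(s)
    paste0(s$param, ":", s$cov), ""))
}

default_init <- function(n_cmt, covariates) {
  th <- if (n_cmt == 1L) c(CL = 5, Vc = 15) else c(CL = 5, Vc = 5, Q = 20, Vp = 7)
  cov_init <- vapply(covariates, `[[`, 0, "theta")
  init <- c(setNames(th, paste0("theta.", names(th))),
            setNames(cov_init, cov_par_names(covariates)),
            setNames(rep(0.1, length(th)),
                     paste0("omega2.", struct_param_names(n_cmt))),
            sigma2.prop = 0.01, sigma2.add = 5)
  if (n_cmt == 2L) init["omega2.Vp"] <- 0
  init
}

#' Fit a population pharmacokinetic model by FOCE
#'
#' Minimises the [foce_objective()] over the fixed effects, the diagonal
#' inter-individual variances and the combined residual variances.
#' Variance parameters are estimated on the log scale to enforce
#' positivity; a variance given as 0 in `init` and listed in `fixed`
#' carries no random effect at all (e.g. the peripheral volume in the
#' final models).
#'
#' @param dataset Concentration dataset (see [generate_dataset()]).
#' @param analyte `"PIPC"` or `"TAZ"`.
#' @param n_cmt 1 or 2 compartments.
#' @param covariates List of [covariate_spec()] objects to estimate
#'   coefficients for (their `theta` slots are used as initial values).
#' @param init Named vector of initial values overriding the defaults;
#'   names follow `theta.CL`, `theta.CL:clcr`, `omega2.CL`,
#'   `sigma2.prop`, ...
#' @param fixed Character vector of parameter names to hold at their
#'   initial values (default fixes `omega2.Vp` to 0 for two-compartment
#'   fits).
#' @param blq Below-LOQ handling.
#' @param control See [pkfit_control()].
#' @return An object of class `"pkfit"` with methods for `print`,
#'   `summary`, `coef`, `logLik`, `vcov`, `predict`, `residuals` (CWRES)
#'   and `plot` (goodness-of-fit).
#' @export
pkfit <- function(dataset, analyte = "PIPC", n_cmt = 2, covariates = list(),
                  init = NULL, fixed = if (n_cmt == 2) "omega2.Vp" else
                    character(), blq = "exclude",
                  control = pkfit_control()) {
  n_cmt <- as.integer(n_cmt)
  pn <- struct_param_names(n_cmt)
  d <- prep_nlme_data(dataset, analyte, blq)

  start <- default_init(n_cmt, covariates)
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(start))
    if (length(bad)) stop("unknown init parameter(s): ",
                          paste(bad, collapse = ", "))
    start[names(init)] <- init
  }
  pnames <- names(start)
  is_var <- grepl("^(omega2|sigma2)\\.", pnames)
  is_free <- !(pnames %in% fixed)
  if (any(start[is_var & !is_free & grepl("^sigma2", pnames)] < 0))
    stop("fixed variances must be non-negative")
  if (any(start[is_var & is_free] <= 0))
    stop("free variance parameters need positive initial values")

  cov_names <- cov_par_names(covariates)

  # transform free parameters: log scale for variances
  to_trans <- function(x) {
    z <- x
    z[is_var] <- log(x[is_var])
    z[is_free]
  }
  from_trans <- function(z) {
    x <- start
    x[is_free] <- z
    x[is_var & is_free] <- exp(z[is_var[is_free]])
    x
  }

  eta0 <- matrix(0, d$n, length(pn))

  unpack <- function(x) {
    th <- x[paste0("theta.", pn)]
    names(th) <- pn
    specs <- covariates
    for (k in seq_along(specs)) specs[[k]]$theta <- x[[cov_names[k]]]
    list(theta = th, covariates = specs,
         omega2 = setNames(x[paste0("omega2.", pn)], pn),
         sigma2 = c(prop = x[["sigma2.prop"]], add = x[["sigma2.add"]]))
  }

  # deterministic (cold-started) objective: the conditional-mode search
  # always starts from eta = 0, so repeated evaluation at the same
  # parameters is bit-identical and finite-difference gradients are clean
  w1 <- rep(1, d$n)
  objective_nat <- function(x, detail = FALSE) {
    p <- unpack(x)
    typ <- try(typ_matrix(p$theta, p$covariates, d$subjects, n_cmt),
               silent = TRUE)
    if (inherits(typ, "try-error") || any(!is.finite(typ)) || any(typ <= 0))
      return(if (detail) NULL else 1e10)
    res <- cpp_foce_obj(d$y, d$tobs, d$obs_start, d$dtd, d$damt, d$ddur,
                        d$dose_start, typ, n_cmt, as.numeric(p$omega2),
                        as.numeric(p$sigma2), eta0,
                        as.integer(control$inner_maxit), control$inner_tol,
                        detail, w1, control$inner_gtol)
    if (detail) return(res)
    if (!is.finite(res$obj)) return(1e10)
    res$obj
  }
  objective <- function(z) objective_nat(from_trans(z))

  lower <- ifelse(grepl("^theta\\.(CL|Vc|Q|Vp)$", pnames), 1e-6, -Inf)
  lower[is_var] <- log(1e-12)
  upper <- rep(Inf, length(pnames))
  upper[is_var] <- log(1e6)

  opt <- if (any(is_free)) {
    z0 <- to_trans(start)
    nlminb(z0, objective,
           scale = 1 / pmax(abs(z0), 0.05),
           lower = lower[is_free], upper = upper[is_free],
           control = list(iter.max = control$iter_max,
                          eval.max = control$eval_max,
                          rel.tol = control$rel_tol))
  } else {
    list(par = numeric(0), convergence = 0L,
         message = "all parameters fixed", iterations = 0L)
  }
  est <- from_trans(opt$par)
  names(est) <- pnames
  final <- objective_nat(est, detail = TRUE)
  if (is.null(final))
    stop("model invalid at the returned optimum (non-positive typical ",
         "values); check covariate specifications and initial values")
  n_est <- sum(is_free)
  obj <- final$obj
  aic <- obj + 2 * n_est

  se <- vcov_mat <- NULL
  if (isTRUE(control$se)) {
    h <- try(fd_hessian(function(x) {
      xx <- est; xx[is_free] <- x
      v <- xx[is_var & is_free]
      if (any(v <= 0)) return(NA_real_)
      objective_nat(xx) / 2
    }, est[is_free]), silent = TRUE)
    if (!inherits(h, "try-error") && all(is.finite(h))) {
      vc <- try(solve(h), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
        vcov_mat <- vc
        dimnames(vcov_mat) <- list(pnames[is_free], pnames[is_free])
        se <- setNames(sqrt(diag(vc)), pnames[is_free])
      }
    }
  }

  structure(list(
    analyte = analyte, n_cmt = n_cmt,
    coef = unpack(est), estimates = est, free = is_free, is_var = is_var,
    fixed = fixed, init = start,
    obj = obj, aic = aic, n_est = n_est,
    n_obs = length(d$y), n_subj = d$n,
    eta = final$eta, detail = final$detail,
    inner_conv = as.logical(final$conv),
    convergence = opt$convergence, message = opt$message,
    iterations = opt$iterations,
    se = se, vcov = vcov_mat,
    data = d, blq = blq, covariate_names = cov_names,
    control = control
  ), class = "pkfit")
}

# Objective of the transformed free parameters for a fitted model, with
# per-subject multiplicity weights.  A bootstrap resample's likelihood is
# the weighted sum of the unique subjects' contributions, so refits never
# need to materialise a resampled dataset.
weighted_objective <- function(fit, weights) {
  d <- fit$data
  pn <- struct_param_names(fit$n_cmt)
  eta0 <- matrix(0, d$n, length(pn))
  est <- fit$estimates
  is_var <- fit$is_var
  is_free <- fit$free
  ctl <- fit$control
  function(z) {
    x <- est
    x[is_free] <- z
    x[is_var & is_free] <- exp(z[is_var[is_free]])
    th <- setNames(x[paste0("theta.", pn)], pn)
    specs <- fit$coef$covariates
    for (k in seq_along(specs)) specs[[k]]$theta <- x[[fit$covariate_names[k]]]
    typ <- try(typ_matrix(th, specs, d$subjects, fit$n_cmt), silent = TRUE)
    if (inherits(typ, "try-error") || any(!is.finite(typ)) || any(typ <= 0))
      return(1e10)
    res <- cpp_foce_obj(d$y, d$tobs, d$obs_start, d$dtd, d$damt, d$ddur,
                        d$dose_start, typ, fit$n_cmt,
                        as.numeric(setNames(x[paste0("omega2.", pn)], pn)),
                        c(x[["sigma2.prop"]], x[["sigma2.add"]]),
                        eta0, as.integer(ctl$inner_maxit), ctl$inner_tol,
                        FALSE, weights, ctl$inner_gtol)
    if (!is.finite(res$obj)) return(1e10)
    res$obj
  }
}

# transformed-scale estimates and proposal covariance of a fit
transformed_estimates <- function(fit) {
  free_names <- names(fit$estimates)[fit$free]
  center <- fit$estimates[fit$free]
  is_var <- fit$is_var[fit$free]
  z <- center
  z[is_var] <- log(center[is_var])
  names(z) <- free_names
  grad <- ifelse(is_var, 1 / center, 1)
  vc <- if (is.null(fit$vcov)) NULL else fit$vcov * outer(grad, grad)
  list(z = z, vcov = vc, is_var = is_var)
}

# Warm-started BFGS with a supplied initial inverse Hessian; forward-
# difference gradients.  Built for refits that start near an optimum with
# good curvature information (bootstrap replicates).
warm_bfgs <- function(fn, x0, Hinv, maxit = 40, tol = 1e-3) {
  p <- length(x0)
  h <- 1e-4 * pmax(abs(x0), 0.01)
  grad <- function(x, f0) {
    g <- numeric(p)
    for (i in seq_len(p)) {
      xp <- x
      xp[i] <- x[i] + h[i]
      g[i] <- (fn(xp) - f0) / h[i]
    }
    g
  }
  x <- x0
  f <- fn(x)
  if (!is.finite(f) || f >= 1e10)
    return(list(par = x0, objective = f, converged = FALSE))
  g <- grad(x, f)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    dir <- -as.numeric(Hinv %*% g)
    step <- 1
    fn1 <- Inf
    ok <- FALSE
    for (ls in 1:10) {
      xn <- x + step * dir
      fn1 <- fn(xn)
      if (is.finite(fn1) && fn1 < f) { ok <- TRUE; break }
      step <- step / 3
    }
    if (!ok) { converged <- TRUE; break }  # no further descent
    gn <- grad(xn, fn1)
    s <- xn - x
    yv <- gn - g
    sy <- sum(s * yv)
    if (is.finite(sy) && sy > 1e-10) {
      Hy <- as.numeric(Hinv %*% yv)
      Hinv <- Hinv + outer(s, s) * ((sy + sum(yv * Hy)) / sy^2) -
        (outer(Hy, s) + outer(s, Hy)) / sy
    }
    dec <- f - fn1
    x <- xn
    f <- fn1
    g <- gn
    if (dec < tol) { converged <- TRUE; break }  # absolute, in OBJ units
  }
  list(par = x, objective = f, converged = converged)
}

# Central-difference Hessian.  The objective is computed through an
# iterative conditional-mode search, so its values carry ~1e-6 numerical
# noise; the relative step is chosen large enough that the quadratic
# curvature signal dominates that noise.
fd_hessian <- function(f, x, rel = 5e-3) {
  p <- length(x)
  h <- rel * pmax(abs(x), 1e-3)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Rank fitted models by AIC
#'
#' `AIC = OBJ + 2 * (number of estimated parameters)`; ties are broken
#' towards fewer parameters.
#'
#' @param fits List of [pkfit()] objects fitted to the same dataset.
#' @return Data frame sorted by ascending AIC.
#' @export
compare_models_aic <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  tab <- data.frame(
    model = names(fits),
    n_cmt = vapply(fits, `[[`, 0L, "n_cmt"),
    n_params = vapply(fits, `[[`, 0L, "n_est"),
    obj = vapply(fits, `[[`, 0, "obj"),
    aic = vapply(fits, `[[`, 0, "aic")
  )
  tab <- tab[order(tab$aic, tab$n_params), ]
  rownames(tab) <- NULL
  tab
}

# --- S3 methods --------------------------------------------------------------

#' @export
print.pkfit <- function(x, ...) {
  cat("Population PK fit (FOCE) --", x$analyte, "--", x$n_cmt,
      "compartment(s)\n")
  cat(sprintf("  %d subjects, %d observations\n", x$n_subj, x$n_obs))
  cat(sprintf("  OBJ = %.3f, AIC = %.3f (%d estimated parameters)\n",
              x$obj, x$aic, x$n_est))
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$coef$theta),
                                x$coef$theta), collapse = ", "), "\n")
  cv <- vapply(x$coef$covariates, function(s)
    sprintf("%s:%s=%.4g", s$param, s$cov, s$theta), "")
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  cat("  omega2:", paste(sprintf("%s=%.4g", names(x$coef$omega2),
                                 x$coef$omega2), collapse = ", "), "\n")
  cat("  sigma2:", paste(sprintf("%s=%.4g", names(x$coef$sigma2),
                                 x$coef$sigma2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pkfit <- function(object, ...) object$estimates

#' @export
logLik.pkfit <- function(object, ...) {
  structure(-object$obj / 2, df = object$n_est, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.pkfit <- function(object, ...) object$vcov

#' @export
summary.pkfit <- function(object, ...) {
  est <- object$estimates[object$free]
  tab <- data.frame(estimate = est,
                    se = if (is.null(object$se)) NA_real_ else
                      object$se[names(est)])
  tab$rse_pct <- 100 * tab$se / abs(tab$estimate)
  out <- list(fit = object, table = tab)
  class(out) <- "summary.pkfit"
  out
}

#' @export
print.summary.pkfit <- function(x, ...) {
  print(x$fit)
  cat("\nEstimated parameters:\n")
  print(round(x$table, 5))
  w2 <- x$fit$coef$omega2
  cv <- lognormal_cv(w2[w2 > 0])
  if (length(cv))
    cat("\nInter-individual CV%:",
        paste(sprintf("%s=%.1f%%", names(cv), cv), collapse = ", "), "\n")
  invisible(x)
}

#' Predictions from a fitted population PK model
#'
#' @param object A [pkfit()] object.
#' @param type `"individual"` (at the conditional modes) or
#'   `"population"` (random effects at zero).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations, one per
#'   observation record used in the fit.
#' @export
predict.pkfit <- function(object, type = c("individual", "population"),
                          ...) {
  type <- match.arg(type)
  d <- object$data
  pn <- struct_param_names(object$n_cmt)
  typ <- typ_matrix(object$coef$theta, object$coef$covariates, d$subjects,
                    object$n_cmt)
  eta <- if (type == "individual") object$eta else
    matrix(0, d$n, length(pn))
  as.numeric(cpp_pred_eta(d$tobs, d$obs_start, d$dtd, d$damt, d$ddur,
                          d$dose_start, typ, object$n_cmt, eta))
}
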