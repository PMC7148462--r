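#' Conditional weighted residuals
#'
#' FOCE-linearised standardised residuals: per subject the model is
#' expanded at the conditional mode `eta_hat`, giving marginal mean
#' `f(eta_hat) - J eta_hat` and covariance
#' `J Omega J' + diag(v(eta_hat))`; CWRES is the inverse matrix square
#' root of that covariance applied to the centred observations.  Under a
#' correctly specified model CWRES are approximately standard normal.
#'
#' @param object A [pkfit()] object.
#' @param type `"cwres"` (default) or `"iwres"` (individual weighted
#'   residuals `(y - f(eta_hat)) / sqrt(v)`).
#' @param ... Unused.
#' @return Data frame with `id`, `time`, `dv`, population and individual
#'   predictions, and the requested residual column.
#' @export
residuals.pkfit <- function(object, type = c("cwres", "iwres"), ...) {
  type <- match.arg(type)
  d <- object$data
  pn <- struct_param_names(object$n_cmt)
  act <- which(object$coef$omega2 > 0)
  pred_pop <- predict(object, "population")
  pred_ind <- predict(object, "individual")
  out <- data.frame(id = rep(d$ids, diff(d$obs_start)),
                    time = d$tobs, dv = d$y,
                    pred = pred_pop, ipred = pred_ind)
  res <- numeric(length(d$y))
  for (i in seq_len(d$n)) {
    idx <- (d$obs_start[i] + 1):d$obs_start[i + 1]
    det <- object$detail[[i]]
    yv <- d$y[idx]
    if (type == "iwres") {
      res[idx] <- (yv - det$f) / sqrt(det$v)
      next
    }
    if (length(act)) {
      J <- det$J
      eta <- object$eta[i, act]
      mu <- det$f - as.numeric(J %*% eta)
      V <- J %*% diag(object$coef$omega2[act],
                      nrow = length(act)) %*% t(J) + diag(det$v,
                                                          nrow = length(yv))
      e <- eigen(V, symmetric = TRUE)
      Vmhalf <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                   nrow = length(yv)) %*% t(e$vectors)
      res[idx] <- as.numeric(Vmhalf %*% (yv - mu))
    } else {
      res[idx] <- (yv - det$f) / sqrt(det$v)
    }
  }
  out[[type]] <- res
  out
}

#' Goodness-of-fit plots
#'
#' Four standard panels: observed vs population predictions, observed vs
#' individual predictions, CWRES vs population predictions and CWRES vs
#' time after dose.
#'
#' @param x A [pkfit()] object.
#' @param ... Passed to [plot()].
#' @return Invisibly, the CWRES table.
#' @export
plot.pkfit <- function(x, ...) {
  r <- residuals(x, "cwres")
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  lim <- range(c(r$dv, r$pred, r$ipred))
  plot(r$pred, r$dv, xlab = "Population prediction (ug/mL)",
       ylab = "Observed (ug/mL)", xlim = lim, ylim = lim, ...)
  abline(0, 1, lty = 2)
  plot(r$ipred, r$dv, xlab = "Individual prediction (ug/mL)",
       ylab = "Observed (ug/mL)", xlim = lim, ylim = lim, ...)
  abline(0, 1, lty = 2)
  plot(r$pred, r$cwres, xlab = "Population prediction (ug/mL)",
       ylab = "CWRES", ...)
  abline(h = 0, lty = 2)
  plot(r$time, r$cwres, xlab = "Time (h)", ylab = "CWRES", ...)
  abline(h = 0, lty = 2)
  invisible(r)
}
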