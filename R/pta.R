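# Random-effect draws for the Monte Carlo PTA (lognormal inter-individual
# variability, no residual error).  The stream depends only on
# (model, n, current RNG state), never on dose, MIC or the clearance
# level, so common random numbers across regimens, MICs and renal-function
# levels are automatic.
draw_eta <- function(model, n) {
  pn <- struct_param_names(model$n_cmt)
  eta <- matrix(0, n, length(pn), dimnames = list(NULL, pn))
  for (k in seq_along(pn)) {
    w2 <- model$omega2[[pn[k]]]
    if (w2 > 0) eta[, k] <- rnorm(n, 0, sqrt(w2))
  }
  eta
}

apply_eta <- function(model, clcr, eta) {
  tp <- as_param_vector(typical_params(model, data.frame(clcr = clcr)))
  sweep(exp(eta), 2, tp, `*`)
}

draw_population <- function(model, clcr, n) {
  apply_eta(model, clcr, draw_eta(model, n))
}

#' Probability of attaining the fT>MIC target
#'
#' Monte Carlo PTA for the time-dependent (piperacillin) target: the
#' fraction of simulated patients whose steady-state unbound
#' concentration stays above the MIC for at least
#' `100 * target_fraction` percent of the dosing interval.
#'
#' @param model A [pop_model()] object (the piperacillin final model).
#' @param regimen An [infusion_regimen()] for the analyte.
#' @param clcr Creatinine clearance of the simulated population (mL/min);
#'   fixed, not resampled.
#' @param mic MIC (ug/mL).
#' @param n Number of simulated patients.
#' @param seed RNG seed (mandatory; recorded in the result).
#' @param config A [pd_config()] object.
#' @return One-row data frame: `regimen`, `clcr`, `mic`, `target`,
#'   `pta`, `n`, `seed`.
#' @export
pta_ft_mic <- function(model, regimen, clcr, mic, n = 1000, seed,
                       config = pd_config()) {
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- draw_population(model, clcr, n)
  ft <- cpp_ft_mic(draws, model$n_cmt, regimen$dose, regimen$t_inf,
                   regimen$tau, config$fu, mic, 1e-9)
  data.frame(regimen = sprintf("%g mg q%gh", regimen$dose, regimen$tau),
             clcr = clcr, mic = mic,
             target = sprintf("fT>MIC >= %g%%", 100 * config$target_fraction),
             pta = 100 * mean(ft >= 100 * config$target_fraction),
             n = n, seed = seed)
}

#' Probability of attaining the fAUC target
#'
#' Monte Carlo PTA for the exposure (tazobactam) target: the fraction of
#' simulated patients with steady-state unbound 24-h AUC at or above
#' `fauc_target`.  Because the steady-state AUC depends only on
#' clearance (`fAUC = fu * daily_dose / CL`), the target is evaluated
#' through that identity for each draw.
#'
#' @inheritParams pta_ft_mic
#' @param model The tazobactam final [pop_model()] (or compatible).
#' @return One-row data frame as in [pta_ft_mic()].
#' @export
pta_fauc <- function(model, regimen, clcr, n = 1000, seed,
                     config = pd_config()) {
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- draw_population(model, clcr, n)
  fauc <- config$fu * regimen$dose * (24 / regimen$tau) / draws[, "CL"]
  data.frame(regimen = sprintf("%g mg q%gh", regimen$dose, regimen$tau),
             clcr = clcr, mic = NA_real_,
             target = sprintf("fAUC0-24 >= %g", config$fauc_target),
             pta = 100 * mean(fauc >= config$fauc_target),
             n = n, seed = seed)
}

#' Closed-form fAUC attainment probability
#'
#' Analytic twin of [pta_fauc()]: with a single lognormal random effect
#' on clearance, attainment of `fAUC0-24 >= target` is
#' `Phi(log((fu * daily_dose / target) / CL_typ(clcr)) / omega_CL)`.
#' Exact (no Monte Carlo error), so it is the default source of the
#' tazobactam attainment grid in de-novo analyses.
#'
#' @inheritParams pta_fauc
#' @return Attainment probability in percent.
#' @export
pta_fauc_closed_form <- function(model, regimen, clcr,
                                 config = pd_config()) {
  cl_typ <- typical_params(model, data.frame(clcr = clcr))$CL
  cl_max <- config$fu * regimen$dose * (24 / regimen$tau) /
    config$fauc_target
  w <- sqrt(model$omega2[["CL"]])
  if (w == 0) return(if (cl_typ <= cl_max) 100 else 0)
  100 * pnorm(log(cl_max / cl_typ) / w)
}

#' PK/PD breakpoint table
#'
#' For every regimen and creatinine-clearance level, the highest MIC on
#' the grid at which PTA for the fT>MIC target is at or above the
#' threshold.  One set of random-effect draws is shared across all
#' regimens, MICs and clearance levels (common random numbers), so the
#' dose-doubling dilution-shift identity holds exactly and PTA is exactly
#' monotone in MIC and in the clearance level.  Internally each draw is
#' summarised by its protective MIC (the concentration level exceeded for
#' exactly the target fraction of the interval), from which PTA at every
#' grid MIC follows by counting.
#'
#' @param model The piperacillin final [pop_model()] (or compatible).
#' @param regimens List of [product_regimen()] objects (their `pipc`
#'   components are simulated); defaults to [candidate_regimens()].
#' @param clcr_grid Creatinine-clearance levels (mL/min).
#' @param mic_grid Ascending MIC grid (ug/mL); default two-fold dilutions
#'   0.0625-64.
#' @param n Simulated patients per cell.
#' @param seed Base RNG seed; the per-clearance streams are derived from
#'   it.
#' @param threshold PTA threshold in percent (90 for the reference
#'   tables).
#' @param config A [pd_config()] object.
#' @return A `"breakpoint_table"` object: data frame `regimen` x `clcr`
#'   with the breakpoint (`NA` when even the lowest grid MIC fails, i.e.
#'   below the lowest tested MIC), with the full PTA grid in
#'   `attr(, "pta")`.
#' @export
breakpoint_table <- function(model, regimens = candidate_regimens(),
                             clcr_grid = c(60, 50, 40, 30, 20, 10),
                             mic_grid = 2^seq(-4, 6), n = 1000, seed,
                             threshold = 90, config = pd_config()) {
  if (is.unsorted(mic_grid, strictly = TRUE))
    stop("mic_grid must be sorted ascending")
  rows <- list(); pta_rows <- list()
  set.seed(seed)
  eta <- draw_eta(model, n)
  for (ci in seq_along(clcr_grid)) {
    clcr <- clcr_grid[ci]
    draws <- apply_eta(model, clcr, eta)
    for (reg in regimens) {
      pipc <- reg$pipc
      m50 <- cpp_mic50(draws, model$n_cmt, pipc$dose, pipc$t_inf,
                       pipc$tau, config$fu, config$target_fraction, 1e-9)
      pta <- vapply(mic_grid, function(m) 100 * mean(m50 >= m), 0)
      ok <- pta >= threshold
      bp <- if (any(ok)) max(mic_grid[ok]) else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(regimen = reg$label, clcr = clcr, breakpoint = bp)
      pta_rows[[length(pta_rows) + 1]] <-
        data.frame(regimen = reg$label, clcr = clcr, mic = mic_grid,
                   pta = pta, n = n, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, pta = do.call(rbind, pta_rows), mic_grid = mic_grid,
            threshold = threshold, n = n, seed = seed,
            class = c("breakpoint_table", "data.frame"))
}
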