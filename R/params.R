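#' Compartmental disposition parameters
#'
#' Container for subject-level disposition constants of a one- or
#' two-compartment intravenous model.  All values are strictly positive;
#' `Q` and `Vp` are only present for the two-compartment case.
#'
#' @param CL Clearance (L/h).
#' @param Vc Central volume of distribution (L).  For a one-compartment
#'   model this is the single volume `V`.
#' @param Q Intercompartmental clearance (L/h), two-compartment only.
#' @param Vp Peripheral volume of distribution (L), two-compartment only.
#' @return An object of class `"cmt_params"`.
#' @examples
#' cmt_params(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96)
#' cmt_params(CL = 5, Vc = 10) # one-compartment
#' @export
cmt_params <- function(CL, Vc, Q = NULL, Vp = NULL) {
  two <- !is.null(Q) || !is.null(Vp)
  if (two && (is.null(Q) || is.null(Vp)))
    stop("two-compartment parameters need both Q and Vp")
  vals <- c(CL = CL, Vc = Vc)
  if (two) vals <- c(vals, Q = Q, Vp = Vp)
  for (nm in names(vals)) {
    if (!is.finite(vals[[nm]]) || vals[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive")
  }
  structure(list(n_compartments = if (two) 2L else 1L,
                 CL = CL, Vc = Vc, Q = Q, Vp = Vp),
            class = "cmt_params")
}

as_param_vector <- function(params) {
  stopifnot(inherits(params, "cmt_params"))
  if (params$n_compartments == 1L) c(params$CL, params$Vc)
  else c(params$CL, params$Vc, params$Q, params$Vp)
}

#' Intravenous infusion regimen
#'
#' One analyte's repeated zero-order infusion schedule.  Dosing intervals
#' that do not divide 24 h evenly are accepted but flagged with a warning,
#' because the per-interval fT>MIC fraction then differs from the 24-h
#' cumulative fraction.
#'
#' @param dose Dose per administration (mg).
#' @param tau Dosing interval (h).
#' @param t_inf Infusion duration (h), default 1 h.
#' @param analyte `"PIPC"` or `"TAZ"`.
#' @return An object of class `"infusion_regimen"`.
#' @examples
#' infusion_regimen(4000, tau = 8) # piperacillin 4 g q8h, 1-h infusion
#' @export
infusion_regimen <- function(dose, tau, t_inf = 1, analyte = c("PIPC", "TAZ")) {
  analyte <- match.arg(analyte)
  if (dose <= 0) stop("dose must be positive")
  if (t_inf <= 0 || t_inf > tau) stop("need 0 < t_inf <= tau")
  if (24 %% tau != 0)
    warning("dosing interval ", tau, " h does not divide 24 h evenly; ",
            "fT>MIC is computed over an explicit 24-h window")
  structure(list(dose = dose, tau = tau, t_inf = t_inf, analyte = analyte),
            class = "infusion_regimen")
}

#' Paired piperacillin + tazobactam product regimen
#'
#' The clinical product combines both analytes at a fixed 8:1 ratio; the
#' two components share the infusion duration and dosing interval.
#'
#' @param product_g Product dose per administration in grams (4.5 or 2.25
#'   in the reference regimens; any positive value with an 8:1 split is
#'   accepted).
#' @param tau Dosing interval (h).
#' @param t_inf Infusion duration (h).
#' @return An object of class `"product_regimen"` with `pipc` and `taz`
#'   [infusion_regimen()] components, a display label, and the total daily
#'   product dose in grams.
#' @examples
#' product_regimen(4.5, tau = 6)
#' @export
product_regimen <- function(product_g, tau, t_inf = 1) {
  pipc_mg <- product_g * 1000 * 8 / 9
  taz_mg <- product_g * 1000 / 9
  structure(list(
    label = sprintf("%.3g g q%dh", product_g, as.integer(tau)),
    product_g = product_g,
    daily_g = product_g * 24 / tau,
    pipc = infusion_regimen(pipc_mg, tau, t_inf, "PIPC"),
    taz = infusion_regimen(taz_mg, tau, t_inf, "TAZ")
  ), class = "product_regimen")
}

#' The six candidate product regimens
#'
#' 4.5 g and 2.25 g product doses at 6-, 8- and 12-h intervals, all 1-h
#' infusions, as screened in the breakpoint and recommendation tables.
#'
#' @return A named list of [product_regimen()] objects.
#' @export
candidate_regimens <- function() {
  grid <- expand.grid(product_g = c(4.5, 2.25), tau = c(6, 8, 12))
  out <- lapply(seq_len(nrow(grid)), function(i)
    product_regimen(grid$product_g[i], grid$tau[i]))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Pharmacodynamic target settings
#'
#' @param fu Unbound fraction (plasma protein binding is 30 percent for
#'   both analytes, so `fu = 0.70`).
#' @param target_fraction Required fraction of the dosing interval with
#'   unbound concentration above the MIC (bactericidal target 0.50 for
#'   piperacillin).
#' @param fauc_target Tazobactam target for the unbound 24-h AUC
#'   (ug h/mL); 96 = 4 ug/mL x 24 h from in vitro susceptibility testing.
#' @return An object of class `"pd_config"`.
#' @export
pd_config <- function(fu = 0.70, target_fraction = 0.50, fauc_target = 96) {
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must be in (0, 1]")
  if (fauc_target <= 0) stop("fauc_target must be positive")
  structure(list(fu = fu, target_fraction = target_fraction,
                 fauc_target = fauc_target), class = "pd_config")
}
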