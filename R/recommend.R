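#' Tazobactam attainment grid
#'
#' Pass/fail attainment of the tazobactam fAUC target for the six
#' candidate regimens over a creatinine-clearance grid.  Sources:
#' `"closed_form"` (default, deterministic, via
#' [pta_fauc_closed_form()]), `"monte_carlo"` (via [pta_fauc()]), or
#' `"reference"` (the packaged grid transcribed from the reference
#' study's attainment results).
#'
#' @param model The tazobactam final [pop_model()]; unused for
#'   `"reference"`.
#' @param clcr_grid Creatinine-clearance levels (mL/min).
#' @param method Attainment source (see above).
#' @param threshold PTA threshold in percent.
#' @param n,seed Monte Carlo settings for `method = "monte_carlo"`.
#' @param config A [pd_config()] object.
#' @return Data frame `taz_dose_g`, `tau`, `clcr`, `pta` (NA for the
#'   reference grid), `attain`.
#' @export
taz_attainment <- function(model = taz_model(),
                           clcr_grid = c(60, 50, 40, 30, 20, 10),
                           method = c("closed_form", "monte_carlo",
                                      "reference"),
                           threshold = 90, n = 10000, seed = 1,
                           config = pd_config()) {
  method <- match.arg(method)
  if (method == "reference") {
    ref <- load_fixture("taz_attainment_reference")
    ref$pta <- NA_real_
    return(ref[ref$clcr %in% clcr_grid,
               c("taz_dose_g", "tau", "clcr", "pta", "attain")])
  }
  grid <- expand.grid(taz_dose_g = c(0.5, 0.25), tau = c(6, 8, 12),
                      clcr = clcr_grid)
  grid$pta <- NA_real_
  for (i in seq_len(nrow(grid))) {
    reg <- infusion_regimen(grid$taz_dose_g[i] * 1000, grid$tau[i],
                            analyte = "TAZ")
    grid$pta[i] <- if (method == "closed_form")
      pta_fauc_closed_form(model, reg, grid$clcr[i], config)
    else
      pta_fauc(model, reg, grid$clcr[i], n = n,
               seed = seed + i, config = config)$pta
  }
  grid$attain <- grid$pta >= threshold
  grid
}

lookup_bp <- function(breakpoints, label, clcr) {
  hit <- breakpoints$regimen == label & breakpoints$clcr == clcr
  if (sum(hit) != 1)
    stop("no breakpoint entry for ", label, " at clcr ", clcr)
  breakpoints$breakpoint[hit]
}

lookup_taz <- function(taz_pass, taz_dose_g, tau, clcr) {
  hit <- abs(taz_pass$taz_dose_g - taz_dose_g) < 1e-9 &
    taz_pass$tau == tau & taz_pass$clcr == clcr
  if (sum(hit) != 1)
    stop("no tazobactam attainment entry for ", taz_dose_g, " g q", tau,
         "h at clcr ", clcr)
  isTRUE(taz_pass$attain[hit])
}

#' Joint two-analyte dosing recommendation
#'
#' Among the candidate regimens whose piperacillin PK/PD breakpoint is at
#' or above the MIC **and** whose tazobactam component attains its fAUC
#' target, returns the one with the lowest total daily product dose
#' (ties broken towards the shorter dosing interval).  A caution flag
#' accompanies any recommendation at creatinine clearance below
#' 40 mL/min, where nephrotoxicity requires attention.
#'
#' @param mic MIC (ug/mL).
#' @param clcr Creatinine clearance (mL/min).
#' @param breakpoints Breakpoint data frame (`regimen`, `clcr`,
#'   `breakpoint`): a [breakpoint_table()] or the packaged reference
#'   grid.
#' @param taz_pass Tazobactam attainment grid from [taz_attainment()].
#' @param regimens Candidate [product_regimen()] list.
#' @return List with `regimen` (label or `NA` for "not recommended"),
#'   `caution`, and `daily_g`.
#' @export
recommend <- function(mic, clcr, breakpoints, taz_pass,
                      regimens = candidate_regimens()) {
  ord <- order(vapply(regimens, `[[`, 0, "daily_g"),
               vapply(regimens, function(r) r$pipc$tau, 0))
  for (k in ord) {
    reg <- regimens[[k]]
    bp <- lookup_bp(breakpoints, reg$label, clcr)
    taz_ok <- lookup_taz(taz_pass, reg$product_g / 9, reg$pipc$tau, clcr)
    if (!is.na(bp) && bp >= mic && taz_ok)
      return(list(regimen = reg$label, caution = clcr < 40,
                  daily_g = reg$daily_g))
  }
  list(regimen = NA_character_, caution = FALSE, daily_g = NA_real_)
}

#' Recommendation table over a MIC x creatinine-clearance grid
#'
#' Applies [recommend()] per cell and, when requested, diffs the result
#' against the packaged reference recommendation table.
#'
#' @param breakpoints,taz_pass,regimens See [recommend()].
#' @param mic_grid,clcr_grid Grids (defaults match the reference table).
#' @param diff Compare against the packaged reference table?
#' @return A `"recommendation_table"` data frame (`mic`, `clcr`,
#'   `regimen` with `"-"` for not recommended, `caution`); when
#'   `diff = TRUE` the mismatching cells are in `attr(, "diff")`.
#' @export
recommendation_table <- function(breakpoints, taz_pass,
                                 regimens = candidate_regimens(),
                                 mic_grid = c(2, 4, 8, 16, 32, 64),
                                 clcr_grid = c(60, 50, 40, 30, 20, 10),
                                 diff = TRUE) {
  cells <- expand.grid(mic = mic_grid, clcr = clcr_grid)
  cells$regimen <- NA_character_
  cells$caution <- FALSE
  for (i in seq_len(nrow(cells))) {
    r <- recommend(cells$mic[i], cells$clcr[i], breakpoints, taz_pass,
                   regimens)
    cells$regimen[i] <- if (is.na(r$regimen)) "-" else r$regimen
    cells$caution[i] <- r$caution && !is.na(r$regimen)
  }
  out <- structure(cells, class = c("recommendation_table", "data.frame"))
  if (diff) {
    ref <- load_fixture("table5_recommendations")
    m <- merge(cells, ref, by = c("mic", "clcr"),
               suffixes = c("", "_ref"))
    mism <- m[m$regimen != m$regimen_ref | m$caution != m$caution_ref, ,
              drop = FALSE]
    mism <- mism[order(mism$mic, -mism$clcr),
                 c("mic", "clcr", "regimen", "regimen_ref",
                   "caution", "caution_ref")]
    rownames(mism) <- NULL
    attr(out, "diff") <- mism
  }
  out
}
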