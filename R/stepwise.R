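#' Stepwise covariate model building
#'
#' Forward inclusion followed by backward elimination on the FOCE
#' objective.  At each forward step every remaining candidate is added to
#' the current model in turn; the candidate with the largest objective
#' drop is included if the drop exceeds `forward_dobj` (3.84, p < 0.05 on
#' one degree of freedom).  Candidates whose covariate correlates with an
#' already-included covariate beyond `collinearity_r` (in absolute value)
#' are screened out.  Backward elimination then removes included
#' covariates one at a time, retaining a covariate only if its removal
#' raises the objective by more than `backward_dobj` (6.63, p < 0.01).
#'
#' @param dataset Concentration dataset.
#' @param analyte Analyte to model.
#' @param n_cmt Structural model size of the base model.
#' @param candidates List of [covariate_spec()] objects to screen.
#' @param forward_dobj,backward_dobj Objective-change thresholds.
#' @param collinearity_r Absolute-correlation screen limit.
#' @param base_fit Optional pre-computed base-model [pkfit()].
#' @param init,fixed,blq,control Passed to [pkfit()].
#' @return List with `fit` (the final model), `trace` (a data frame
#'   recording every tested candidate, its objective change and the
#'   decision) and `included` (the retained covariate specs).
#' @export
stepwise_covariates <- function(dataset, analyte = "PIPC", n_cmt = 2,
                                candidates = list(),
                                forward_dobj = 3.84, backward_dobj = 6.63,
                                collinearity_r = 0.5,
                                base_fit = NULL, init = NULL,
                                fixed = if (n_cmt == 2) "omega2.Vp" else
                                  character(),
                                blq = "exclude",
                                control = pkfit_control(se = FALSE)) {
  if (is.null(base_fit))
    base_fit <- pkfit(dataset, analyte, n_cmt, covariates = list(),
                      init = init, fixed = fixed, blq = blq,
                      control = control)
  trace <- data.frame(step = character(), param = character(),
                      cov = character(), form = character(),
                      dobj = numeric(), decision = character(),
                      stringsAsFactors = FALSE)
  cand_label <- function(s) paste0(s$param, ":", s$cov, ":", s$form)
  subj <- prep_nlme_data(dataset, analyte, blq)$subjects

  included <- list()
  current <- base_fit
  remaining <- candidates

  refit <- function(specs, from_fit) {
    ini <- from_fit$estimates
    keep <- intersect(names(ini), names(default_init(n_cmt, specs)))
    pkfit(dataset, analyte, n_cmt, covariates = specs,
          init = ini[keep], fixed = fixed, blq = blq, control = control)
  }

  # forward inclusion, largest objective drop first
  repeat {
    if (!length(remaining)) break
    # collinearity screen against already-included covariates
    usable <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      s <- remaining[[k]]
      rmax <- 0
      for (inc in included) {
        if (identical(inc$cov, s$cov)) { rmax <- 1; break }
        r <- abs(cor(subj[[s$cov]], subj[[inc$cov]]))
        rmax <- max(rmax, r)
      }
      usable[k] <- rmax <= collinearity_r
      if (!usable[k])
        trace <- rbind(trace, data.frame(
          step = "forward", param = s$param, cov = s$cov, form = s$form,
          dobj = NA_real_, decision = "collinear"))
    }
    pool <- remaining[usable]
    if (!length(pool)) break
    fits <- vector("list", length(pool))
    dobj <- rep(NA_real_, length(pool))
    for (k in seq_along(pool)) {
      f <- try(refit(c(included, pool[k]), current), silent = TRUE)
      if (!inherits(f, "try-error")) {
        fits[[k]] <- f
        dobj[k] <- current$obj - f$obj
      }
      trace <- rbind(trace, data.frame(
        step = "forward", param = pool[[k]]$param, cov = pool[[k]]$cov,
        form = pool[[k]]$form, dobj = dobj[k],
        decision = "tested"))
    }
    if (all(is.na(dobj)) || max(dobj, na.rm = TRUE) <= forward_dobj) break
    best <- which.max(dobj)
    trace <- rbind(trace, data.frame(
      step = "forward", param = pool[[best]]$param, cov = pool[[best]]$cov,
      form = pool[[best]]$form, dobj = dobj[best], decision = "included"))
    included <- c(included, pool[best])
    current <- fits[[best]]
    remaining <- remaining[!vapply(remaining, function(s)
      cand_label(s) == cand_label(pool[[best]]), TRUE)]
  }

  # backward elimination from the full model
  repeat {
    if (!length(included)) break
    rises <- rep(NA_real_, length(included))
    fits <- vector("list", length(included))
    for (k in seq_along(included)) {
      f <- try(refit(included[-k], current), silent = TRUE)
      if (!inherits(f, "try-error")) {
        fits[[k]] <- f
        rises[k] <- f$obj - current$obj
      }
    }
    worst <- which.min(rises)
    if (!length(worst) || is.na(rises[worst]) ||
        rises[worst] > backward_dobj) {
      for (k in seq_along(included))
        trace <- rbind(trace, data.frame(
          step = "backward", param = included[[k]]$param,
          cov = included[[k]]$cov, form = included[[k]]$form,
          dobj = rises[k], decision = "retained"))
      break
    }
    trace <- rbind(trace, data.frame(
      step = "backward", param = included[[worst]]$param,
      cov = included[[worst]]$cov, form = included[[worst]]$form,
      dobj = rises[worst], decision = "eliminated"))
    current <- fits[[worst]]
    included <- included[-worst]
  }

  list(fit = current, trace = trace, included = included)
}
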