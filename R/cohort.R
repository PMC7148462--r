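#' Configuration of the synthetic study cohort
#'
#' Defaults reproduce the reference study conditions: 18 late elderly
#' subjects (14 male / 4 female), covariates drawn from normal
#' distributions truncated to the reported ranges, 1-h infusions three
#' times daily (8-h intervals) with the product dose reduced from 4.5 g to
#' 2.25 g below the renal-function threshold of 50 mL/min, plasma sampling
#' at 0, 1, 1.5, 2, 3 and 5 h after the start of the reference
#' administration (by default the first dose of day 2, an approximate
#' steady state; the 0-h sample is the pre-dose trough), and a
#' quantification range of 0.5-1000 ug/mL.
#'
#' @param n Number of subjects.
#' @param covariates Data frame with columns `variable`, `mean`, `sd`,
#'   `min`, `max`; defaults to the packaged demographics table.
#' @param p_male Probability a subject is male (14/18 by default).
#' @param dose_rule_threshold Renal-function threshold (mL/min) below
#'   which the product dose is reduced (strict `<`).
#' @param dose_rule_metric Covariate used by the dose rule; creatinine
#'   clearance stands in for the study's unspecified eGFR formula.
#' @param tau Dosing interval in hours (8 = three times daily).
#' @param t_inf Infusion duration (h).
#' @param sampling_times Sampling times (h) relative to the start of the
#'   reference administration.
#' @param reference_dose Index of the administration the samples bracket
#'   (4 = first dose of day 2; 1 = first-dose sampling).
#' @param loq Lower and upper limits of quantification (ug/mL).
#' @param blq_rule `"exclude"` drops below-LOQ records from estimation;
#'   `"loq2"` replaces them by LOQ/2.
#' @return A `"cohort_config"` list.
#' @export
cohort_config <- function(n = 18,
                          covariates = NULL,
                          p_male = 14 / 18,
                          dose_rule_threshold = 50,
                          dose_rule_metric = "clcr",
                          tau = 8,
                          t_inf = 1,
                          sampling_times = c(0, 1, 1.5, 2, 3, 5),
                          reference_dose = 4,
                          loq = c(0.5, 1000),
                          blq_rule = c("exclude", "loq2")) {
  if (is.null(covariates)) covariates <- load_fixture("table1_cohort")
  stopifnot(n >= 0, all(sampling_times >= 0), loq[1] < loq[2],
            reference_dose >= 1)
  with_rng <- covariates[covariates$variable %in%
                           c("age", "height", "weight", "scr", "albumin"), ]
  if (any(with_rng$min > with_rng$mean) || any(with_rng$max < with_rng$mean))
    stop("covariate ranges must bracket their means")
  structure(list(n = n, covariates = covariates, p_male = p_male,
                 dose_rule_threshold = dose_rule_threshold,
                 dose_rule_metric = dose_rule_metric, tau = tau,
                 t_inf = t_inf, sampling_times = sampling_times,
                 reference_dose = as.integer(reference_dose), loq = loq,
                 blq_rule = match.arg(blq_rule)),
            class = "cohort_config")
}

# exact truncated-normal draws by inverse-CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  if (phi <= plo) stop("infeasible truncation range")
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Moments of a truncated normal distribution
#'
#' Analytic mean and standard deviation of a normal distribution truncated
#' to `[lo, hi]`; the oracle for the covariate generator's moments.
#'
#' @param mean,sd Parent normal parameters.
#' @param lo,hi Truncation bounds.
#' @return `c(mean = , sd = )` of the truncated distribution.
#' @export
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  d1 <- (dnorm(a) - dnorm(b)) / Z
  mu <- mean + sd * d1
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - d1^2)
  c(mean = mu, sd = sqrt(v))
}


#' Sample a cohort of subjects
#'
#' Age, height, weight, serum creatinine and albumin are drawn from
#' truncated normals per the configured demographics; sex at the
#' configured ratio; creatinine clearance is derived by Cockcroft-Gault
#' and body mass index from height and weight.
#'
#' @param config A [cohort_config()] object.
#' @param n Number of subjects (defaults to `config$n`).
#' @return Data frame of subjects (one row each).
#' @export
sample_covariates <- function(config, n = config$n) {
  cov <- config$covariates
  row <- function(v) cov[cov$variable == v, ]
  if (n == 0)
    return(data.frame(id = integer(), age = numeric(), sex = character(),
                      weight = numeric(), height = numeric(),
                      scr = numeric(), albumin = numeric(), bmi = numeric(),
                      clcr = numeric()))
  draw <- function(v) {
    r <- row(v)
    if (r$min > r$mean + 6 * r$sd || r$max < r$mean - 6 * r$sd)
      stop("infeasible truncation for ", v)
    rtruncnorm(n, r$mean, r$sd, r$min, r$max)
  }
  age <- draw("age"); height <- draw("height"); weight <- draw("weight")
  scr <- draw("scr"); albumin <- draw("albumin")
  sex <- ifelse(runif(n) < config$p_male, "male", "female")
  data.frame(id = seq_len(n), age = age, sex = sex, weight = weight,
             height = height, scr = scr, albumin = albumin,
             bmi = weight / (height / 100)^2,
             clcr = cockcroft_gault(age, weight, scr, sex))
}

#' Renal-function-based product dose assignment
#'
#' 4.5 g of product (4000 mg piperacillin + 500 mg tazobactam) per
#' administration by default; reduced to 2.25 g (2000/250 mg) when the
#' renal-function metric is strictly below the threshold.
#'
#' @param subject One-row data frame (needs the configured renal metric).
#' @param config A [cohort_config()] object.
#' @return A [product_regimen()] object.
#' @examples
#' cfg <- cohort_config()
#' assign_regimen(data.frame(clcr = 60), cfg)$label  # "4.5 g q8h"
#' assign_regimen(data.frame(clcr = 49.9), cfg)$label # "2.25 g q8h"
#' @export
assign_regimen <- function(subject, config = cohort_config()) {
  metric <- subject[[config$dose_rule_metric]]
  if (is.null(metric) || is.na(metric))
    stop("subject lacks renal-function metric '", config$dose_rule_metric, "'")
  g <- if (metric < config$dose_rule_threshold) 2.25 else 4.5
  product_regimen(g, config$tau, config$t_inf)
}

#' Generate a concentration-time dataset
#'
#' For each subject: dosing history up to the reference administration,
#' true concentrations for both analytes from the closed-form kinetics at
#' independently sampled individual parameters, combined residual error,
#' and below-LOQ flagging of raw values under the lower quantification
#' limit (including negative noisy values, which are never clamped).
#'
#' @param pipc_model,taz_model [pop_model()] objects.
#' @param cohort Data frame from [sample_covariates()].
#' @param config A [cohort_config()] object.
#' @return Data frame in a NONMEM-like long layout: `id`, `analyte`,
#'   `time`, `evid` (1 dose / 0 observation), `amt`, `dur`, `dv`, `blq`,
#'   plus subject covariates.
#' @export
generate_dataset <- function(pipc_model, taz_model, cohort,
                             config = cohort_config()) {
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    reg <- assign_regimen(subj, config)
    dose_times <- (seq_len(config$reference_dose) - 1) * config$tau
    t_ref <- dose_times[config$reference_dose]
    obs_times <- t_ref + config$sampling_times
    for (analyte in c("PIPC", "TAZ")) {
      model <- if (analyte == "PIPC") pipc_model else taz_model
      comp <- if (analyte == "PIPC") reg$pipc else reg$taz
      ip <- sample_individual(model, subj)
      truec <- conc_infusion(ip, comp$dose, comp$t_inf, obs_times,
                             config$tau, n_doses = length(dose_times))
      obsc <- apply_residual_error(truec, model)
      blq <- obsc < config$loq[1]
      rec <- rbind(
        data.frame(id = subj$id, analyte = analyte, time = dose_times,
                   evid = 1L, amt = comp$dose, dur = comp$t_inf,
                   dv = NA_real_, blq = FALSE),
        data.frame(id = subj$id, analyte = analyte, time = obs_times,
                   evid = 0L, amt = NA_real_, dur = NA_real_,
                   dv = obsc, blq = blq)
      )
      rec$age <- subj$age; rec$sex <- subj$sex; rec$weight <- subj$weight
      rec$height <- subj$height; rec$scr <- subj$scr
      rec$albumin <- subj$albumin; rec$bmi <- subj$bmi
      rec$clcr <- subj$clcr
      out[[length(out) + 1]] <- rec
    }
  }
  if (!length(out)) stop("empty cohort: no dataset to generate")
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  ds
}

#' Write / read a concentration dataset as CSV
#'
#' Values round-trip bit-identically (written with 17 significant digits).
#'
#' @param dataset Data frame from [generate_dataset()].
#' @param path File path.
#' @return `read_dataset` returns the data frame; `write_dataset` its
#'   path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  ds <- dataset
  for (col in names(ds))
    if (is.double(ds[[col]]))
      ds[[col]] <- ifelse(is.na(dataset[[col]]), NA,
                          sprintf("%.17g", dataset[[col]]))
  write.csv(ds, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- read.csv(path, stringsAsFactors = FALSE)
  ds$blq <- as.logical(ds$blq)
  ds$evid <- as.integer(ds$evid)
  for (col in setdiff(names(ds), c("id", "analyte", "sex", "evid", "blq")))
    ds[[col]] <- as.numeric(ds[[col]])
  ds
}
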