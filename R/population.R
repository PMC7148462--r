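#' Cockcroft-Gault creatinine clearance
#'
#' `(140 - age) * weight / (72 * scr)`, multiplied by 0.85 for females.
#'
#' @param age Age in years.
#' @param weight Body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(40, 72, 1.0, "male") # 100
#' @export
cockcroft_gault <- function(age, weight, scr, sex = "male") {
  if (any(age <= 0) || any(weight <= 0) || any(scr <= 0))
    stop("age, weight and scr must all be positive")
  sex <- tolower(as.character(sex))
  sex[sex == "m"] <- "male"
  sex[sex == "f"] <- "female"
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  clcr <- (140 - age) * weight / (72 * scr)
  ifelse(sex == "female", 0.85 * clcr, clcr)
}

#' Covariate effect on a structural parameter
#'
#' @param param Structural parameter name (`"CL"`, `"Vc"`, `"Q"`, `"Vp"`).
#' @param cov Covariate column name in the subject data (e.g. `"clcr"`).
#' @param form `"linear"` (`tha + thb * (x - center)`), `"exponential"`
#'   (`tha * exp(thb * (x - center))`) or `"power"`
#'   (`tha * (x / center)^thb`, the allometric form).
#' @param center Centering constant; the covariate median (37.4 mL/min for
#'   creatinine clearance in the final models).
#' @param theta Effect coefficient `thb`.
#' @return A `"covariate_spec"` list.
#' @export
covariate_spec <- function(param, cov, form = c("linear", "exponential", "power"),
                           center, theta = 0) {
  form <- match.arg(form)
  if (form == "power" && center <= 0) stop("power form needs center > 0")
  structure(list(param = param, cov = cov, form = form, center = center,
                 theta = theta), class = "covariate_spec")
}

struct_param_names <- function(n_cmt) {
  if (n_cmt == 1L) c("CL", "Vc") else c("CL", "Vc", "Q", "Vp")
}

#' Population pharmacokinetic model
#'
#' Fixed effects, covariate specifications, diagonal inter-individual
#' variability and combined residual error for one analyte.
#' Inter-individual variability is exponential
#' (`theta_i = theta * exp(eta_i)`, `eta ~ N(0, omega^2)`); the residual
#' model is `C_obs = C_pred * (1 + eps_prop) + eps_add`.  Typical values
#' are checked to stay positive over creatinine clearance 10-60 mL/min at
#' construction.
#'
#' @param analyte `"PIPC"` or `"TAZ"`.
#' @param n_cmt 1 or 2 compartments.
#' @param theta Named numeric vector of structural typical values
#'   (`CL`, `Vc` and, for two compartments, `Q`, `Vp`).
#' @param covariates List of [covariate_spec()] objects.
#' @param omega2 Named vector of inter-individual variances; entries may
#'   be 0 (fixed, no random effect), e.g. `Vp` in the final models.
#' @param sigma2 Named vector `c(prop = , add = )` of residual variances.
#' @return An object of class `"pop_model"`.
#' @export
pop_model <- function(analyte, n_cmt, theta, covariates = list(),
                      omega2, sigma2) {
  pn <- struct_param_names(n_cmt)
  stopifnot(all(pn %in% names(theta)), all(pn %in% names(omega2)),
            all(c("prop", "add") %in% names(sigma2)))
  if (any(omega2 < 0) || any(sigma2 < 0))
    stop("variances must be non-negative")
  m <- structure(list(analyte = analyte, n_cmt = as.integer(n_cmt),
                      theta = theta[pn], covariates = covariates,
                      omega2 = omega2[pn], sigma2 = sigma2[c("prop", "add")]),
                 class = "pop_model")
  # positivity of typical values over the supported renal-function range
  for (clcr in c(10, 35, 60)) {
    subj <- data.frame(clcr = clcr, age = 86.5, weight = 45.5, bmi = 19.1,
                       scr = 0.91, albumin = 2.9)
    tp <- typical_params(m, subj)
    if (any(as_param_vector(tp) <= 0))
      stop("typical values non-positive at clcr = ", clcr)
  }
  m
}

apply_covariate <- function(base, spec, x) {
  switch(spec$form,
         linear = base + spec$theta * (x - spec$center),
         exponential = base * exp(spec$theta * (x - spec$center)),
         power = base * (x / spec$center)^spec$theta)
}

#' Typical (population-predicted) parameters for a subject
#'
#' Evaluates the covariate model at the subject's covariates, e.g.
#' `CL = theta1 + theta2 * (CLcr - 37.4)` for the final models.
#'
#' @param model A [pop_model()] object.
#' @param subject A one-row data frame (or list) holding every covariate
#'   the model references.
#' @return A [cmt_params()] object.
#' @examples
#' m <- pipc_model()
#' typical_params(m, data.frame(clcr = 37.4))$CL # 4.58, centering identity
#' @export
typical_params <- function(model, subject) {
  pn <- struct_param_names(model$n_cmt)
  vals <- model$theta[pn]
  for (spec in model$covariates) {
    x <- subject[[spec$cov]]
    if (is.null(x) || is.na(x))
      stop("subject lacks covariate '", spec$cov, "'")
    new <- apply_covariate(vals[[spec$param]], spec, x)
    if (new <= 0)
      stop("typical ", spec$param, " non-positive at ", spec$cov, " = ", x)
    vals[[spec$param]] <- new
  }
  if (model$n_cmt == 1L) cmt_params(vals[["CL"]], vals[["Vc"]])
  else cmt_params(vals[["CL"]], vals[["Vc"]], vals[["Q"]], vals[["Vp"]])
}

#' Individual parameters from random effects
#'
#' Each typical value is multiplied by `exp(eta)`; `eta` must carry one
#' entry per structural parameter (zero where the variance is fixed to 0).
#'
#' @inheritParams typical_params
#' @param eta Named (or positionally ordered) numeric vector of random
#'   effects, one per structural parameter.
#' @return A [cmt_params()] object.
#' @export
individual_params <- function(model, subject, eta) {
  pn <- struct_param_names(model$n_cmt)
  if (length(eta) != length(pn))
    stop("eta must have one entry per structural parameter (",
         length(pn), ")")
  tp <- as_param_vector(typical_params(model, subject))
  vals <- tp * exp(as.numeric(eta))
  if (model$n_cmt == 1L) cmt_params(vals[1], vals[2])
  else cmt_params(vals[1], vals[2], vals[3], vals[4])
}

#' Sample an individual's parameters
#'
#' Draws `eta ~ N(0, omega^2)` independently per structural parameter
#' (deterministic where the variance is fixed to 0) and applies the
#' exponential inter-individual model.
#'
#' @inheritParams typical_params
#' @param n Number of draws.
#' @return For `n = 1` a [cmt_params()] object; otherwise an `n` x P
#'   matrix of parameter values (columns CL, Vc, Q, Vp).
#' @export
sample_individual <- function(model, subject, n = 1) {
  pn <- struct_param_names(model$n_cmt)
  tp <- as_param_vector(typical_params(model, subject))
  eta <- sapply(seq_along(pn), function(k) {
    w2 <- model$omega2[[pn[k]]]
    if (w2 > 0) rnorm(n, 0, sqrt(w2)) else rep(0, n)
  })
  eta <- matrix(eta, nrow = n)
  mat <- sweep(exp(eta), 2, tp, `*`)
  colnames(mat) <- pn
  if (n == 1) {
    if (model$n_cmt == 1L) cmt_params(mat[1, 1], mat[1, 2])
    else cmt_params(mat[1, 1], mat[1, 2], mat[1, 3], mat[1, 4])
  } else mat
}

#' Apply the combined residual-error model
#'
#' `obs = pred * (1 + eps_prop) + eps_add` with independent normal errors.
#' Values may come out negative; censoring against the quantification
#' limit is handled downstream, never by silent clamping.
#'
#' @param pred Predicted concentration(s), ug/mL.
#' @param model A [pop_model()] object (supplies the variances).
#' @return Perturbed concentration(s).
#' @export
apply_residual_error <- function(pred, model) {
  n <- length(pred)
  pred * (1 + rnorm(n, 0, sqrt(model$sigma2[["prop"]]))) +
    rnorm(n, 0, sqrt(model$sigma2[["add"]]))
}

#' Coefficient of variation of a lognormal random effect
#'
#' `CV% = 100 * sqrt(exp(omega2) - 1)`, the transformation under which the
#' reported inter-individual variances translate to percent CVs.
#'
#' @param omega2 Variance(s) of the log-scale random effect, `>= 0`.
#' @return CV in percent.
#' @examples
#' lognormal_cv(0.0705) # 27.0
#' @export
lognormal_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be non-negative")
  100 * sqrt(exp(omega2) - 1)
}

#' Final population models from the packaged estimates
#'
#' Two-compartment models with a linear creatinine-clearance effect on
#' clearance centred at the cohort median (37.4 mL/min), built from the
#' packaged final-estimate fixtures.
#'
#' @return A [pop_model()] object.
#' @examples
#' typical_params(pipc_model(), data.frame(clcr = 38))$CL # 4.6166
#' @export
pipc_model <- function() model_from_fixture("pipc_final", "PIPC")

#' @rdname pipc_model
#' @export
taz_model <- function() model_from_fixture("taz_final", "TAZ")

model_from_fixture <- function(name, analyte) {
  tab <- load_fixture(name)
  est <- setNames(tab$estimate, tab$parameter)
  pop_model(
    analyte = analyte, n_cmt = 2L,
    theta = c(CL = est[["theta1"]], Vc = est[["theta3"]],
              Q = est[["theta4"]], Vp = est[["theta5"]]),
    covariates = list(covariate_spec("CL", "clcr", "linear", 37.4,
                                     est[["theta2"]])),
    omega2 = c(CL = est[["omega2_CL"]], Vc = est[["omega2_Vc"]],
               Q = est[["omega2_Q"]], Vp = est[["omega2_Vp"]]),
    sigma2 = c(prop = est[["sigma2_prop"]], add = est[["sigma2_add"]])
  )
}
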