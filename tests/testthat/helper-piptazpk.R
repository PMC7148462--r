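# Shared builders for the test suite.  Everything is generated in code;
# no stored fixtures beyond the packaged reference tables.

pipc_typical_at <- function(clcr = 60) {
  m <- pipc_model()
  typical_params(m, data.frame(clcr = clcr))
}

study_cohort <- function(seed = 42, n = 18) {
  set.seed(seed)
  sample_covariates(cohort_config(n = n))
}

study_dataset <- function(seed = 42, pipc = pipc_model(), taz = taz_model(),
                          cfg = cohort_config()) {
  set.seed(seed)
  coh <- sample_covariates(cfg)
  generate_dataset(pipc, taz, coh, cfg)
}

cl_covariate <- function(theta = 0) {
  list(covariate_spec("CL", "clcr", "linear", 37.4, theta))
}

# one-compartment single-subject toy with one random effect on CL,
# used for quadrature checks of the marginal likelihood
toy_1eta <- function(seed = 7, eta_true = 0.2, omega2 = 0.1,
                     sigma2 = c(prop = 0.002, add = 4)) {
  m <- pop_model("PIPC", 1, theta = c(CL = 5, Vc = 12),
                 covariates = list(),
                 omega2 = c(CL = omega2, Vc = 0), sigma2 = sigma2)
  subj <- data.frame(id = 1, clcr = 48)
  obst <- 24 + c(0, 1, 1.5, 2, 3, 5)
  ip <- individual_params(m, subj, c(eta_true, 0))
  truec <- conc_infusion(ip, 2000, 1, obst, 8, n_doses = 4)
  set.seed(seed)
  dv <- apply_residual_error(truec, m)
  ds <- rbind(
    data.frame(id = 1, analyte = "PIPC", time = c(0, 8, 16, 24), evid = 1L,
               amt = 2000, dur = 1, dv = NA_real_, blq = FALSE, clcr = 48),
    data.frame(id = 1, analyte = "PIPC", time = obst, evid = 0L,
               amt = NA_real_, dur = NA_real_, dv = dv, blq = FALSE,
               clcr = 48))
  list(model = m, dataset = ds, subj = subj, obst = obst)
}

# 64-node adaptive Gauss-Hermite -2 log marginal likelihood for a 1-eta
# toy: nodes are centred at the joint-density mode and scaled by its
# curvature, then the prior-times-likelihood integrand is summed exactly.
# Entirely independent of the package's Laplace path: mode and curvature
# come from stats::optimize and a finite difference on the log joint.
gh_minus2ll <- function(toy, theta = c(CL = 5, Vc = 12), omega2 = 0.1,
                        sigma2 = c(prop = 0.002, add = 4), nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  obs <- toy$dataset[toy$dataset$evid == 0L, ]
  m <- pop_model("PIPC", 1, theta = theta, covariates = list(),
                 omega2 = c(CL = omega2, Vc = 0), sigma2 = sigma2)
  logjoint <- function(eta) {
    pp <- individual_params(m, toy$subj, c(eta, 0))
    f <- conc_infusion(pp, 2000, 1, toy$obst, 8, n_doses = 4)
    v <- sigma2[["prop"]] * f^2 + sigma2[["add"]]
    sum(dnorm(obs$dv, f, sqrt(v), log = TRUE)) +
      dnorm(eta, 0, sqrt(omega2), log = TRUE)
  }
  mode <- optimize(logjoint, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  h <- 1e-4
  curv <- -(logjoint(mode + h) - 2 * logjoint(mode) + logjoint(mode - h)) /
    h^2
  s <- 1 / sqrt(curv)
  lik <- 0
  for (k in seq_len(nodes)) {
    eta <- mode + sqrt(2) * s * gh$x[k]
    lik <- lik + gh$w[k] * exp(gh$x[k]^2 + logjoint(eta)) * sqrt(2) * s
  }
  -2 * log(lik)
}
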