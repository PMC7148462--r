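test_that("FOCE objective matches adaptive quadrature on 1-eta problems", {
  for (sd_seed in c(7, 17, 27)) {
    toy <- toy_1eta(seed = sd_seed)
    o <- foce_objective(toy$dataset, "PIPC", 1, list(),
                        theta = c(CL = 5, Vc = 12),
                        omega2 = c(CL = 0.1, Vc = 0),
                        sigma2 = c(prop = 0.002, add = 4))
    oracle <- gh_minus2ll(toy)
    expect_lt(abs(o$obj - oracle), 0.5)
  }
  # also away from the generating parameters
  toy <- toy_1eta(seed = 7)
  o <- foce_objective(toy$dataset, "PIPC", 1, list(),
                      theta = c(CL = 6, Vc = 10),
                      omega2 = c(CL = 0.2, Vc = 0),
                      sigma2 = c(prop = 0.005, add = 6))
  oracle <- gh_minus2ll(toy, theta = c(CL = 6, Vc = 10), omega2 = 0.2,
                        sigma2 = c(prop = 0.005, add = 6))
  expect_lt(abs(o$obj - oracle), 0.5)
})

test_that("degenerate prior: with all variances fixed at zero the
           objective is the extended-least-squares deviance", {
  toy <- toy_1eta()
  obs <- toy$dataset[toy$dataset$evid == 0, ]
  o <- foce_objective(toy$dataset, "PIPC", 1, list(),
                      theta = c(CL = 5, Vc = 12),
                      omega2 = c(CL = 0, Vc = 0),
                      sigma2 = c(prop = 0.002, add = 4))
  m <- pop_model("PIPC", 1, theta = c(CL = 5, Vc = 12), covariates = list(),
                 omega2 = c(CL = 0, Vc = 0),
                 sigma2 = c(prop = 0.002, add = 4))
  f <- conc_infusion(typical_params(m, toy$subj), 2000, 1, toy$obst, 8,
                     n_doses = 4)
  v <- 0.002 * f^2 + 4
  els <- sum((obs$dv - f)^2 / v + log(v) + log(2 * pi))
  expect_equal(o$obj, els, tolerance = 1e-8)
  expect_true(all(o$eta == 0))
})

test_that("objective is additive over subjects and invariant to record
           order", {
  ds <- study_dataset(seed = 31)
  clspec <- cl_covariate(0.061)
  th <- c(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96)
  w2 <- c(CL = 0.0705, Vc = 0.389, Q = 0.311, Vp = 0)
  s2 <- c(prop = 0.000927, add = 25.1)
  o1 <- foce_objective(ds, "PIPC", 2, clspec, th, w2, s2)

  # duplicating every subject doubles the objective exactly
  dup <- ds
  dup$id <- dup$id + 100
  o2 <- foce_objective(rbind(ds, dup), "PIPC", 2, clspec, th, w2, s2)
  expect_equal(o2$obj, 2 * o1$obj, tolerance = 1e-9)

  # shuffling record order leaves the objective unchanged
  set.seed(1)
  shuf <- ds[sample(nrow(ds)), ]
  o3 <- foce_objective(shuf, "PIPC", 2, clspec, th, w2, s2)
  expect_equal(o3$obj, o1$obj, tolerance = 1e-9)
})

test_that("noise-free data recover the generating fixed effects", {
  cfg <- cohort_config()
  m0 <- pop_model("PIPC", 2,
                  theta = c(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96),
                  covariates = list(covariate_spec("CL", "clcr", "linear",
                                                   37.4, 0.061)),
                  omega2 = c(CL = 0, Vc = 0, Q = 0, Vp = 0),
                  sigma2 = c(prop = 0, add = 0))
  set.seed(21)
  coh <- sample_covariates(cfg)
  ds0 <- generate_dataset(m0, m0, coh, cfg)
  f0 <- pkfit(ds0, "PIPC", 2, covariates = cl_covariate(),
              init = c("sigma2.prop" = 1e-6, "sigma2.add" = 1,
                       "omega2.CL" = 0, "omega2.Vc" = 0, "omega2.Q" = 0),
              fixed = c("omega2.CL", "omega2.Vc", "omega2.Q", "omega2.Vp",
                        "sigma2.prop", "sigma2.add"),
              control = pkfit_control(iter_max = 500, eval_max = 2000,
                                      se = FALSE))
  expect_lt(max(abs(f0$coef$theta -
                      c(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96)) /
                  c(4.58, 5.39, 20.7, 6.96)), 0.001)
  expect_lt(abs(f0$coef$covariates[[1]]$theta - 0.061) / 0.061, 0.001)
})

test_that("fixed-parameter masks hold and the AIC identity is exact", {
  ds <- study_dataset(seed = 42)
  fit <- pkfit(ds, "PIPC", 2, covariates = cl_covariate(),
               control = pkfit_control(se = FALSE))
  expect_equal(fit$coef$omega2[["Vp"]], 0)
  expect_equal(fit$aic, fit$obj + 2 * fit$n_est)
  expect_equal(AIC(fit), fit$aic)
  expect_equal(as.numeric(logLik(fit)), -fit$obj / 2)

  # a model with additionally fixed variances estimates fewer parameters
  fit2 <- pkfit(ds, "PIPC", 2, covariates = cl_covariate(),
                init = c("omega2.Q" = 0.3),
                fixed = c("omega2.Vp", "omega2.Q"),
                control = pkfit_control(se = FALSE))
  expect_equal(fit2$coef$omega2[["Q"]], 0.3)
  expect_equal(fit2$n_est, fit$n_est - 1)
})

test_that("AIC ranking prefers the generating structural model and
           breaks ties by parameter count", {
  ds <- study_dataset(seed = 42)
  f2 <- pkfit(ds, "PIPC", 2, control = pkfit_control(se = FALSE))
  f1 <- pkfit(ds, "PIPC", 1, control = pkfit_control(se = FALSE))
  tab <- compare_models_aic(list(two_cmt = f2, one_cmt = f1))
  expect_equal(tab$model[1], "two_cmt")
  expect_equal(tab$aic, tab$obj + 2 * tab$n_params)
  # ties: identical fits are ordered by parameter count
  tie <- compare_models_aic(list(a = f1, b = f1))
  expect_equal(tie$n_params, sort(tie$n_params))
})

test_that("CWRES are standardised under a correct model and degenerate
           for zero-residual data", {
  ds <- study_dataset(seed = 42)
  fit <- pkfit(ds, "PIPC", 2, covariates = cl_covariate(),
               control = pkfit_control(se = FALSE))
  r <- residuals(fit, "cwres")
  expect_equal(nrow(r), fit$n_obs)
  expect_lt(abs(mean(r$cwres)), 0.3)
  expect_gt(var(r$cwres), 0.5)
  expect_lt(var(r$cwres), 1.6)

  # zero-residual limit: noise-free data, variances pinned near zero
  cfg <- cohort_config()
  m0 <- pop_model("PIPC", 2,
                  theta = c(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96),
                  covariates = list(covariate_spec("CL", "clcr", "linear",
                                                   37.4, 0.061)),
                  omega2 = c(CL = 0, Vc = 0, Q = 0, Vp = 0),
                  sigma2 = c(prop = 0, add = 0))
  set.seed(22)
  coh <- sample_covariates(cfg)
  ds0 <- generate_dataset(m0, m0, coh, cfg)
  f0 <- pkfit(ds0, "PIPC", 2, covariates = cl_covariate(0.061),
              init = c("theta.CL" = 4.58, "theta.Vc" = 5.39,
                       "theta.Q" = 20.7, "theta.Vp" = 6.96,
                       "sigma2.prop" = 1e-10, "sigma2.add" = 1e-8,
                       "omega2.CL" = 0, "omega2.Vc" = 0, "omega2.Q" = 0),
              fixed = c("theta.CL", "theta.Vc", "theta.Q", "theta.Vp",
                        "theta.CL:clcr", "omega2.CL", "omega2.Vc",
                        "omega2.Q", "omega2.Vp", "sigma2.prop",
                        "sigma2.add"),
              control = pkfit_control(se = FALSE))
  r0 <- residuals(f0, "cwres")
  expect_lt(max(abs(r0$cwres)), 1e-3)
})

test_that("predictions at eta = 0 differ from conditional predictions
           and drive the GOF plot", {
  ds <- study_dataset(seed = 42)
  fit <- pkfit(ds, "PIPC", 2, covariates = cl_covariate(),
               control = pkfit_control(se = FALSE))
  pp <- predict(fit, "population")
  ip <- predict(fit, "individual")
  expect_equal(length(pp), fit$n_obs)
  expect_false(isTRUE(all.equal(pp, ip)))
  # individual predictions track the data more closely
  r <- residuals(fit)
  expect_lt(mean((r$dv - ip)^2), mean((r$dv - pp)^2))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
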