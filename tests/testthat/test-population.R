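test_that("Cockcroft-Gault formula and input validation", {
  expect_equal(cockcroft_gault(40, 72, 1.0, "male"), 100)
  expect_equal(cockcroft_gault(40, 72, 1.0, "female"), 85)
  # a typical study subject lands inside the cohort's reported range
  clcr <- cockcroft_gault(86.5, 45.5, 0.91, "male")
  expect_gt(clcr, 21.5)
  expect_lt(clcr, 59.1)
  expect_error(cockcroft_gault(-1, 72, 1), "positive")
  expect_error(cockcroft_gault(40, 72, 1, "other"), "sex")
})

test_that("typical parameters follow the covariate equations", {
  m <- pipc_model()
  # centering identity: at the covariate median, CL equals theta1
  expect_equal(typical_params(m, data.frame(clcr = 37.4))$CL, 4.58)
  # cohort-mean creatinine clearance reproduces the reported values
  expect_equal(typical_params(m, data.frame(clcr = 38))$CL, 4.6166)
  expect_equal(round(typical_params(m, data.frame(clcr = 38))$CL, 2), 4.62)
  mt <- taz_model()
  expect_equal(typical_params(mt, data.frame(clcr = 38))$CL, 5.03522)
  expect_equal(round(typical_params(mt, data.frame(clcr = 38))$CL, 2), 5.04)
  # parameters without covariates equal their theta
  tp <- typical_params(m, data.frame(clcr = 50))
  expect_equal(c(tp$Vc, tp$Q, tp$Vp), c(5.39, 20.7, 6.96))

  # linear form is affine in the covariate: exact superposition
  cl <- function(x) typical_params(m, data.frame(clcr = x))$CL
  x1 <- 20; x2 <- 55; a <- 0.3
  expect_equal(cl(a * x1 + (1 - a) * x2), a * cl(x1) + (1 - a) * cl(x2),
               tolerance = 1e-12)

  # exponential and power forms
  me <- pop_model("PIPC", 2, theta = c(CL = 4, Vc = 5, Q = 20, Vp = 7),
                  covariates = list(covariate_spec("CL", "clcr",
                                                   "exponential", 37.4, 0.01)),
                  omega2 = c(CL = 0.1, Vc = 0.1, Q = 0.1, Vp = 0),
                  sigma2 = c(prop = 0.001, add = 1))
  expect_equal(typical_params(me, data.frame(clcr = 47.4))$CL,
               4 * exp(0.1))
  mp <- pop_model("PIPC", 2, theta = c(CL = 4, Vc = 5, Q = 20, Vp = 7),
                  covariates = list(covariate_spec("CL", "clcr", "power",
                                                   37.4, 0.75)),
                  omega2 = c(CL = 0.1, Vc = 0.1, Q = 0.1, Vp = 0),
                  sigma2 = c(prop = 0.001, add = 1))
  expect_equal(typical_params(mp, data.frame(clcr = 74.8))$CL,
               4 * 2^0.75)

  expect_error(typical_params(m, data.frame(weight = 50)), "clcr")
})

test_that("individual parameters apply exp(eta) multiplicatively", {
  m <- pipc_model()
  s <- data.frame(clcr = 40)
  tp <- typical_params(m, s)
  expect_equal(individual_params(m, s, c(0, 0, 0, 0)), tp)
  ip <- individual_params(m, s, c(log(2), 0, 0, 0))
  expect_equal(ip$CL, 2 * tp$CL)
  expect_equal(c(ip$Vc, ip$Q, ip$Vp), c(tp$Vc, tp$Q, tp$Vp))
  # +/- one standard deviation moves each parameter by exp(+/-omega)
  w <- sqrt(m$omega2[["CL"]])
  expect_equal(individual_params(m, s, c(w, 0, 0, 0))$CL, tp$CL * exp(w))
  expect_equal(individual_params(m, s, c(-w, 0, 0, 0))$CL, tp$CL * exp(-w))
  expect_error(individual_params(m, s, c(0, 0)), "one entry per")
})

test_that("sampled individuals have lognormal moments and median", {
  m <- pipc_model()
  s <- data.frame(clcr = 37.4)
  # all-zero variances give typical values always
  m0 <- pop_model("PIPC", 2, theta = m$theta, covariates = m$covariates,
                  omega2 = c(CL = 0, Vc = 0, Q = 0, Vp = 0),
                  sigma2 = m$sigma2)
  set.seed(1)
  mat0 <- sample_individual(m0, s, n = 5)
  expect_true(all(mat0[, "CL"] == 4.58))

  set.seed(2)
  n <- 1e5
  mat <- sample_individual(m, s, n = n)
  lcl <- log(mat[, "CL"])
  w2 <- m$omega2[["CL"]]
  expect_lt(abs(mean(lcl) - log(4.58)), 3 * sqrt(w2 / n))
  se_var <- sqrt(2 / (n - 1)) * w2
  expect_lt(abs(var(lcl) - w2), 3 * se_var)
  # empirical CV within 1% of the reported 27.0%
  cv <- 100 * sd(mat[, "CL"]) / mean(mat[, "CL"])
  expect_lt(abs(cv - 27.0) / 27.0, 0.01)
  # lognormal median property
  expect_lt(abs(median(mat[, "CL"]) - 4.58) / 4.58, 0.01)
  # Vp has no variability in the final model
  expect_true(all(mat[, "Vp"] == 6.96))
})

test_that("combined residual error has the variance-sum property", {
  m <- pipc_model()
  expect_equal(apply_residual_error(
    50, pop_model("PIPC", 2, theta = m$theta, covariates = m$covariates,
                  omega2 = m$omega2, sigma2 = c(prop = 0, add = 0))), 50)
  set.seed(3)
  n <- 1e5
  obs <- apply_residual_error(rep(100, n), m)
  v_expected <- 100^2 * m$sigma2[["prop"]] + m$sigma2[["add"]]
  se_v <- sqrt(2 / (n - 1)) * v_expected
  expect_lt(abs(var(obs) - v_expected), 3 * se_v)
  # pred = 0 leaves pure additive noise
  set.seed(4)
  obs0 <- apply_residual_error(rep(0, n), m)
  expect_lt(abs(var(obs0) - m$sigma2[["add"]]),
            3 * sqrt(2 / (n - 1)) * m$sigma2[["add"]])
})

test_that("lognormal CV transformation reproduces all reported CVs", {
  expect_equal(lognormal_cv(0), 0)
  w2 <- c(0.0705, 0.389, 0.311, 0.0715, 0.547, 0.545)
  expect_equal(round(lognormal_cv(w2), 1),
               c(27.0, 69.0, 60.4, 27.2, 85.3, 85.1))
  expect_error(lognormal_cv(-0.1), "non-negative")
})

test_that("model construction validates variances and positivity", {
  expect_error(pop_model("PIPC", 2,
                         theta = c(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96),
                         covariates = list(),
                         omega2 = c(CL = -1, Vc = 0, Q = 0, Vp = 0),
                         sigma2 = c(prop = 0, add = 0)),
               "non-negative")
  # a covariate slope steep enough to cross zero within CLcr 10-60 fails
  expect_error(pop_model("PIPC", 2,
                         theta = c(CL = 4.58, Vc = 5.39, Q = 20.7, Vp = 6.96),
                         covariates = list(covariate_spec("CL", "clcr",
                                                          "linear", 37.4, 0.2)),
                         omega2 = c(CL = 0, Vc = 0, Q = 0, Vp = 0),
                         sigma2 = c(prop = 0, add = 0)),
               "non-positive")
})
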