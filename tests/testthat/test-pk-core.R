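test_that("disposition spectrum satisfies the macro-constant identities", {
  # one compartment: single rate CL/V, coefficient 1/V per mg
  sp1 <- disposition_spectrum(cmt_params(CL = 5, Vc = 10))
  expect_equal(sp1$lambda, 0.5)
  expect_equal(sp1$coef, 0.1)

  # two compartments at the typical parameters (CLcr 60)
  p <- pipc_typical_at(60)
  sp <- disposition_spectrum(p)
  k10 <- p$CL / p$Vc; k12 <- p$Q / p$Vc; k21 <- p$Q / p$Vp
  expect_equal(sum(sp$lambda), k10 + k12 + k21, tolerance = 1e-10)
  expect_equal(prod(sp$lambda), k10 * k21, tolerance = 1e-10)
  # roots of the characteristic polynomial by substitution
  for (lam in sp$lambda)
    expect_lt(abs(lam^2 - (k10 + k12 + k21) * lam + k10 * k21) / lam^2, 1e-10)
  # AUC identity: sum(coef/lambda) = 1/CL per mg
  expect_equal(sum(sp$coef / sp$lambda), 1 / p$CL, tolerance = 1e-12)

  # decoupled-compartments limit Q -> 0
  pq <- cmt_params(CL = 5, Vc = 10, Q = 1e-9, Vp = 7)
  spq <- disposition_spectrum(pq)
  expect_equal(sort(spq$lambda), sort(c(5 / 10, 1e-9 / 7)),
               tolerance = 1e-6)
  expect_equal(spq$coef[which.max(spq$lambda)], 1 / 10, tolerance = 1e-6)

  expect_error(cmt_params(CL = -1, Vc = 5, Q = 1, Vp = 1), "CL")
  expect_error(cmt_params(CL = 1, Vc = 0, Q = 1, Vp = 1), "Vc")
})

test_that("infusion concentrations: zero before start, linear in dose,
           steady state equals long finite superposition", {
  p <- pipc_typical_at(60)
  expect_equal(conc_infusion(p, 4000, 1, 0, 6, n_doses = 1), 0)

  tt <- c(0.25, 0.5, 1, 1.5, 2, 3, 5, 5.99)
  ss <- conc_infusion(p, 4000, 1, tt, 6)
  fin <- conc_infusion(p, 4000, 1, 39 * 6 + tt, 6, n_doses = 40)
  expect_lt(max(abs(ss - fin)), 1e-6)

  # dose linearity is exact
  expect_identical(conc_infusion(p, 2000, 1, tt, 6) * 2,
                   conc_infusion(p, 4000, 1, tt, 6))

  expect_error(conc_infusion(p, 4000, 9, 1, 8), "t_inf")
})

test_that("closed form matches an ODE integration oracle", {
  skip_if_not_installed("deSolve")
  p <- pipc_typical_at(60)
  k10 <- p$CL / p$Vc; k12 <- p$Q / p$Vc; k21 <- p$Q / p$Vp
  # 21 doses q8h reach steady state (terminal half-life ~2 h), then
  # sample within the last interval
  rhs <- function(t, y, parms) {
    tin <- t %% 8
    rate <- if (t <= 20 * 8 + 1 && tin < 1) 4000 else 0
    list(c(rate / p$Vc - (k10 + k12) * y[1] + k21 * y[2] * p$Vp / p$Vc,
           k12 * y[1] * p$Vc / p$Vp - k21 * y[2]))
  }
  times <- sort(unique(c(seq(0, 21 * 8, by = 0.05),
                         20 * 8 + c(1, 1.5, 2, 3, 5))))
  sol <- deSolve::lsoda(c(0, 0), times, rhs, NULL, rtol = 1e-10,
                        atol = 1e-10)
  at <- 20 * 8 + c(1, 1.5, 2, 3, 5)
  ode_c <- sol[match(at, sol[, 1]), 2]
  cf <- conc_infusion(p, 4000, 1, c(1, 1.5, 2, 3, 5), 8)
  expect_equal(cf, unname(ode_c), tolerance = 1e-4)

  # property: random positive parameter sets agree with the oracle
  set.seed(1)
  for (rep in 1:5) {
    pr <- cmt_params(CL = runif(1, 2, 10), Vc = runif(1, 3, 15),
                     Q = runif(1, 5, 30), Vp = runif(1, 3, 15))
    k10 <- pr$CL / pr$Vc; k12 <- pr$Q / pr$Vc; k21 <- pr$Q / pr$Vp
    sol <- deSolve::lsoda(c(0, 0), seq(0, 8, by = 0.01),
      function(t, y, parms)
        list(c((if (t < 1) 3000 else 0) / pr$Vc - (k10 + k12) * y[1] +
                 k21 * y[2] * pr$Vp / pr$Vc,
               k12 * y[1] * pr$Vc / pr$Vp - k21 * y[2])),
      NULL, rtol = 1e-10, atol = 1e-10)
    at <- c(0.5, 1, 2, 5)
    expect_equal(conc_infusion(pr, 3000, 1, at, 8, n_doses = 1),
                 unname(sol[match(at, round(sol[, 1], 10)), 2]),
                 tolerance = 1e-4)
  }
})

test_that("fT>MIC: trivial limits, dense-grid agreement, monotonicity", {
  p <- pipc_typical_at(60)
  reg <- infusion_regimen(4000, 6)
  expect_equal(time_above_threshold(p, reg, 0), 100)
  peak <- conc_infusion(p, 4000, 1, 1, 6)
  expect_equal(time_above_threshold(p, reg, 0.7 * peak * 1.01), 0)

  # exact crossing search vs dense grid, including partial coverage
  for (mic in c(16, 32, 64, 96)) {
    ft <- time_above_threshold(p, reg, mic)
    ftg <- time_above_threshold(p, reg, mic, method = "grid",
                                n_grid = 1e5)
    expect_lt(abs(ft - ftg), 0.05)
  }

  # non-increasing in MIC; non-decreasing in dose at fixed MIC
  mics <- c(1, 4, 16, 48, 96, 200)
  fts <- vapply(mics, function(m) time_above_threshold(p, reg, m), 0)
  expect_true(all(diff(fts) <= 0))
  doses <- c(1000, 2000, 4000, 8000)
  ftd <- vapply(doses, function(d)
    time_above_threshold(p, infusion_regimen(d, 6), 48), 0)
  expect_true(all(diff(ftd) >= 0))
})

test_that("fAUC0-24 satisfies the mass-balance identity and matches
           trapezoid integration", {
  cfg <- pd_config()
  p1 <- cmt_params(CL = 5, Vc = 6.29, Q = 24, Vp = 7.73)
  reg <- infusion_regimen(500, 8, analyte = "TAZ")
  expect_equal(fauc_24(p1, reg), 0.7 * 1500 / 5, tolerance = 1e-9)

  # typical tazobactam patient at the covariate median, 500 mg q6h
  m <- taz_model()
  pt <- typical_params(m, data.frame(clcr = 37.4))
  regt <- infusion_regimen(500, 6, analyte = "TAZ")
  tt <- seq(0, 6, length.out = 1e5 + 1)
  cc <- conc_infusion(pt, 500, 1, tt, 6)
  trap <- 0.7 * sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt)) * 4
  expect_equal(fauc_24(pt, regt), trap, tolerance = 1e-4)
  expect_equal(fauc_24(pt, regt), 0.7 * 2000 / pt$CL, tolerance = 1e-9)

  # AUC conservation across random draws and regimens
  set.seed(2)
  for (rep in 1:10) {
    pr <- cmt_params(CL = runif(1, 1, 10), Vc = runif(1, 3, 15),
                     Q = runif(1, 5, 30), Vp = runif(1, 3, 15))
    tau <- sample(c(6, 8, 12), 1)
    d <- runif(1, 200, 4000)
    expect_equal(fauc_24(pr, infusion_regimen(d, tau)),
                 0.7 * d * (24 / tau) / pr$CL, tolerance = 1e-6)
  }
})
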