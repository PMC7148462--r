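test_that("fT>MIC PTA: trivial MIC limits and seeded reproducibility", {
  m <- pipc_model()
  reg <- infusion_regimen(4000, 6)
  expect_equal(pta_ft_mic(m, reg, 40, mic = 0, n = 50, seed = 1)$pta, 100)
  expect_equal(pta_ft_mic(m, reg, 40, mic = 1e6, n = 50, seed = 1)$pta, 0)
  a <- pta_ft_mic(m, reg, 40, mic = 16, n = 400, seed = 9)
  b <- pta_ft_mic(m, reg, 40, mic = 16, n = 400, seed = 9)
  expect_identical(a$pta, b$pta)
  expect_equal(a$n, 400)
  expect_equal(a$seed, 9)
  expect_error(pta_ft_mic(m, reg, 40, 16, n = 0, seed = 1))
})

test_that("common random numbers make dose-MIC rescaling exact", {
  m <- pipc_model()
  p1 <- pta_ft_mic(m, infusion_regimen(2000, 6), 40, mic = 8,
                   n = 500, seed = 4)
  p2 <- pta_ft_mic(m, infusion_regimen(4000, 6), 40, mic = 16,
                   n = 500, seed = 4)
  expect_identical(p1$pta, p2$pta)
})

test_that("Monte Carlo fAUC PTA converges to the closed form", {
  m <- taz_model()
  cfgs <- list(list(reg = infusion_regimen(500, 8, analyte = "TAZ"),
                    clcr = 60),
               list(reg = infusion_regimen(250, 8, analyte = "TAZ"),
                    clcr = 40),
               list(reg = infusion_regimen(250, 12, analyte = "TAZ"),
                    clcr = 10))
  n <- 2e4
  for (cs in cfgs) {
    mc <- pta_fauc(m, cs$reg, cs$clcr, n = n, seed = 11)$pta
    cf <- pta_fauc_closed_form(m, cs$reg, cs$clcr)
    se <- 100 * sqrt(cf / 100 * (1 - cf / 100) / n)
    expect_lt(abs(mc - cf), 3 * se)
  }
  # degenerate variance: step function around the threshold clearance
  m0 <- pop_model("TAZ", 2, theta = m$theta, covariates = m$covariates,
                  omega2 = c(CL = 0, Vc = 0, Q = 0, Vp = 0),
                  sigma2 = m$sigma2)
  reg <- infusion_regimen(500, 8, analyte = "TAZ")
  # typical CL at clcr 60 is 6.33 L/h; threshold CL = 0.7*1500/96 = 10.9
  expect_equal(pta_fauc_closed_form(m0, reg, 60), 100)
  expect_equal(pta_fauc_closed_form(m0, infusion_regimen(100, 8,
                                                         analyte = "TAZ"),
                                    60), 0)
  # lognormal median: typical fAUC exactly at target gives 50%
  # choose dose so fu*D24/CL_typ = 96 at clcr 40
  cl_typ <- typical_params(m, data.frame(clcr = 40))$CL
  dose <- 96 * cl_typ / (0.7 * 3)
  expect_equal(pta_fauc_closed_form(m, infusion_regimen(dose, 8,
                                                        analyte = "TAZ"),
                                    40), 50, tolerance = 1e-9)
})

test_that("fAUC PTA is effectively determined by the clearance draw", {
  # identity: fAUC = fu * daily dose / CL for every draw
  m <- taz_model()
  set.seed(13)
  reg <- infusion_regimen(500, 8, analyte = "TAZ")
  draws <- piptazpk:::draw_population(m, 40, 200)
  fauc <- vapply(seq_len(200), function(i) {
    p <- cmt_params(draws[i, "CL"], draws[i, "Vc"], draws[i, "Q"],
                    draws[i, "Vp"])
    fauc_24(p, reg)
  }, 0)
  expect_equal(fauc, 0.7 * 1500 / draws[, "CL"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("breakpoint table: threshold-zero fills the grid top, the
           dilution-shift identity is exact, and PTA is monotone", {
  m <- pipc_model()
  regs <- candidate_regimens()
  mic_grid <- 2^seq(-4, 6)
  bp <- breakpoint_table(m, regs, clcr_grid = c(60, 40, 20),
                         mic_grid = mic_grid, n = 300, seed = 21)
  expect_s3_class(bp, "breakpoint_table")
  expect_equal(nrow(bp), 18)

  # threshold 0: every cell is the top of the grid
  bp0 <- breakpoint_table(m, regs["4.5 g q6h"], clcr_grid = 40,
                          mic_grid = mic_grid, n = 50, seed = 3,
                          threshold = 0)
  expect_equal(bp0$breakpoint, 64)

  # dilution-shift identity under common random numbers: the 4.5 g row
  # equals the 2.25 g row shifted exactly one dilution, per interval
  pta <- attr(bp, "pta")
  for (tau in c("q6h", "q8h", "q12h")) {
    hi <- pta[pta$regimen == paste("4.5 g", tau), ]
    lo <- pta[pta$regimen == paste("2.25 g", tau), ]
    for (cl in c(60, 40, 20)) {
      h <- hi[hi$clcr == cl, ]
      l <- lo[lo$clcr == cl, ]
      # PTA at MIC 2m for the doubled dose equals PTA at m for the base
      keep <- (2 * l$mic) %in% h$mic
      expect_identical(h$pta[match(2 * l$mic[keep], h$mic)],
                       l$pta[keep])
    }
  }

  # PTA non-increasing in MIC and in decreasing renal function it rises
  for (rg in unique(pta$regimen)) {
    for (cl in c(60, 40, 20)) {
      p <- pta[pta$regimen == rg & pta$clcr == cl, ]
      expect_true(all(diff(p$pta[order(p$mic)]) <= 0))
    }
    wide <- tapply(pta$pta[pta$regimen == rg],
                   list(pta$mic[pta$regimen == rg],
                        pta$clcr[pta$regimen == rg]), identity)
    # clearance increases with creatinine clearance, so PTA at fixed MIC
    # is non-increasing from clcr 20 to 60 (columns sorted ascending)
    expect_true(all(wide[, "40"] >= wide[, "60"] - 1e-9))
    expect_true(all(wide[, "20"] >= wide[, "40"] - 1e-9))
  }

  expect_error(breakpoint_table(m, regs, mic_grid = c(4, 2, 1), n = 10,
                                seed = 1), "sorted")
})

test_that("fT>MIC breakpoints are ordered by dosing interval at equal
           dose and by dose at equal interval", {
  m <- pipc_model()
  bp <- breakpoint_table(m, candidate_regimens(),
                         clcr_grid = c(60, 40, 20),
                         mic_grid = 2^seq(-4, 6), n = 1000, seed = 31)
  get <- function(r, cl) bp$breakpoint[bp$regimen == r & bp$clcr == cl]
  for (cl in c(60, 40, 20)) {
    for (g in c("4.5 g", "2.25 g")) {
      expect_gte(get(paste(g, "q6h"), cl), get(paste(g, "q8h"), cl))
      expect_gte(get(paste(g, "q8h"), cl), get(paste(g, "q12h"), cl))
    }
    for (tau in c("q6h", "q8h", "q12h"))
      expect_gte(get(paste("4.5 g", tau), cl),
                 get(paste("2.25 g", tau), cl))
  }
  # within a regimen, the breakpoint never decreases as renal function
  # declines (exact under the shared draws)
  for (r in unique(bp$regimen)) {
    b <- bp[bp$regimen == r, ]
    expect_true(all(diff(b$breakpoint[order(b$clcr)]) <= 0))
  }
})
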