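test_that("peak detection finds the earliest maximum", {
  pk <- cmax_tmax(c(1, 2, 4), c(70.6, 40, 20))
  expect_equal(pk$cmax, 70.6)
  expect_equal(pk$tmax, 1)
  expect_equal(cmax_tmax(1, 5), list(cmax = 5, tmax = 1))
  tie <- cmax_tmax(c(1, 2, 3), c(8, 8, 2))
  expect_equal(tie$tmax, 1)
  expect_error(cmax_tmax(c(0, 1), c(NA, NA), blq = c(1, 1)), "no data")
})

test_that("terminal slope is exact on log-linear data", {
  t <- c(24, 36, 48)
  lz <- select_lambda_z(c(1, t), c(50, 100 * exp(-0.1 * t)))
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(lz$adj_r2, 1, tolerance = 1e-9)
  expect_equal(lz$n_points, 3)
})

test_that("terminal slope on a bi-exponential is within 1% of the slow exponent", {
  px <- polyexp(c(50, 10), c(1, 0.1))
  t <- c(0.5, 1, 2, 4, 8, 12, seq(24, 72, by = 4))
  lz <- select_lambda_z(t, px$conc(t))
  expect_equal(lz$lambda_z, 0.1, tolerance = 0.01)
  expect_true(lz$lambda_z > 0)
})

test_that("terminal-slope errors fire on unusable tails", {
  expect_error(select_lambda_z(c(1, 2, 3), c(5, 6, 7)), "no terminal decline")
  expect_error(select_lambda_z(c(1, 2), c(5, 3)), "insufficient terminal data")
})

test_that("trapezoidal AUC matches hand-computed panels", {
  expect_equal(auc_0_t(c(0, 1, 2), c(0, 10, 5)), 12.5)
  expect_equal(auc_0_t(c(0, 1, 2), c(0, 10, 5), method = "lin_up_log_down"),
               5 + 5 / log(2))
  expect_equal(auc_0_t(c(0, 1, 2), c(0, 10, 5), method = "lin_up_log_down"),
               12.213, tolerance = 1e-4)
  # flat panel under log-down falls back to the linear trapezoid
  expect_equal(auc_0_t(c(0, 1, 2), c(4, 4, 4), method = "lin_up_log_down"), 8)
  expect_error(auc_0_t(0, 5), "no data")
})

test_that("AUC converges to the closed form under grid refinement", {
  px <- polyexp(c(50, 10), c(1, 0.1))
  errs <- sapply(c(50, 100, 200, 400), function(n) {
    t <- seq(0, 120, length.out = n)
    abs(auc_0_t(t, px$conc(t)) - px$auc)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4] / px$auc, 5e-3)
})

test_that("AUC is additive over an interior split point", {
  px <- polyexp(c(30, 5), c(0.8, 0.07))
  t <- sort(c(0, runif(30, 0, 48)))
  c_all <- px$conc(t)
  k <- 15
  expect_equal(auc_0_t(t[1:k], c_all[1:k]) + auc_0_t(t[k:31], c_all[k:31]),
               auc_0_t(t, c_all), tolerance = 1e-12)
})

test_that("extrapolation to infinity adds the analytic tail", {
  out <- auc_0_inf(12.213, c_last = 0.823, lambda_z = 0.1)
  expect_equal(out$auc_0_inf, 12.213 + 8.23)
  expect_equal(out$pct_extrapolated, 100 * 8.23 / 20.443)
  expect_lt(out$pct_extrapolated, 100)
  # vanishing last concentration recovers the observed area
  expect_equal(auc_0_inf(12, 1e-12, 0.1)$auc_0_inf, 12, tolerance = 1e-9)
  expect_error(auc_0_inf(12, 0.8, 0), "invalid input")
})

test_that("moment analysis matches bolus bi-exponential closed forms", {
  px <- polyexp(c(50, 10), c(1, 0.1))   # AUC 150, AUMC 1050, MRT 7 h
  t <- dense_times(0.1, 2000)
  cc <- px$conc(t)
  lz <- select_lambda_z(t, cc)
  mom <- aumc_mrt(t, cc, lambda_z = lz$lambda_z, t_inf = 0)
  expect_equal(mom$aumc_0_inf, 1050, tolerance = 2e-3)
  expect_equal(mom$mrt, 7, tolerance = 2e-3)
  # treating the same curve as a 1-h infusion subtracts t_inf/2
  mom_inf <- aumc_mrt(t, cc, lambda_z = lz$lambda_z, t_inf = 1)
  expect_equal(mom_inf$mrt, mom$mrt - 0.5)
  # mono-exponential: bolus MRT = 1/lambda
  mono <- polyexp(20, 0.2)
  tm <- dense_times(0.2, 2000)
  lzm <- select_lambda_z(tm, mono$conc(tm))
  expect_equal(aumc_mrt(tm, mono$conc(tm), lambda_z = lzm$lambda_z,
                        t_inf = 0)$mrt, 5, tolerance = 2e-3)
})

test_that("clearance and Vss unit arithmetic", {
  expect_equal(clearance(10, 500), 20)
  expect_equal(clearance(7.5, 560), 13.39, tolerance = 1e-3)
  expect_equal(clearance(10, 1000), clearance(10, 500) / 2)
  expect_error(clearance(10, 0), "invalid input")
  expect_equal(vss(6.667, 7), 46.669)
  expect_equal(vss(13, 10), 130)
})

test_that("full NCA recovers generating parameters from rich noiseless data", {
  p <- disposition_from_physiology(cl = 17, v1 = 90, q = 50, v2 = 55)
  t <- dense_times(min(p$lambda))
  cc <- simulate_concentrations(p, dose_per_kg = 10, t_inf = 1, times = t)
  res <- run_nca(t, cc, dose_per_kg = 10, t_inf = 1, method = "lin_up_log_down")
  expect_equal(res$cl, 17, tolerance = 0.02)
  expect_equal(res$t_half, log(2) / min(p$lambda), tolerance = 0.02)
  expect_equal(res$vss, 145, tolerance = 0.05)
  expect_equal(res$t_half, log(2) / res$lambda_z)           # definitional
  expect_true(res$auc_0_inf >= res$auc_0_t)
})

test_that("NCA on the study-B schedule recovers clearance within 2%", {
  p <- disposition_from_physiology(cl = 17, v1 = 90, q = 50, v2 = 55)
  t <- sampling_schedule("B")
  cc <- simulate_concentrations(p, 10, 1, t)
  res <- run_nca(t, cc, dose_per_kg = 10, t_inf = 1, method = "lin_up_log_down")
  expect_equal(res$cl, 17, tolerance = 0.02)
})

test_that("dose linearity: scaling concentrations scales areas, not slopes", {
  p <- disposition_from_physiology(cl = 12, v1 = 90, q = 50, v2 = 55)
  t <- sampling_schedule("B")
  cc <- simulate_concentrations(p, 7.5, 1, t)
  r1 <- run_nca(t, cc, dose_per_kg = 7.5, t_inf = 1)
  r3 <- run_nca(t, 3 * cc, dose_per_kg = 7.5, t_inf = 1)
  expect_equal(r3$cmax, 3 * r1$cmax)
  expect_equal(r3$auc_0_inf, 3 * r1$auc_0_inf)
  expect_equal(r3$lambda_z, r1$lambda_z)
  expect_equal(r3$mrt, r1$mrt)
})

test_that("BLQ policy: pre-dose zeroed, embedded and trailing excluded", {
  t <- c(0, 1, 2, 4, 8, 12, 24, 36)
  cc <- c(NA, 40, 30, NA, 12, 6, 1.5, NA)
  blq <- c(1, 0, 0, 1, 0, 0, 0, 1)
  res <- run_nca(t, cc, blq, dose_per_kg = 7.5, t_inf = 1)
  # area uses (0,0), skips t=4 and t=36; last quantifiable point is 24 h
  keep_t <- c(0, 1, 2, 8, 12, 24)
  keep_c <- c(0, 40, 30, 12, 6, 1.5)
  expect_equal(res$auc_0_t, auc_0_t(keep_t, keep_c))
  expect_equal(res$cmax, 40)
  expect_error(run_nca(c(0, 1), c(NA, NA), c(1, 1), dose_per_kg = 7.5),
               "no data")
})

test_that("table-level NCA keys by subject and analyte and reports failures", {
  cfg <- small_config("A", sigma = 0, seed = 5)
  sim <- simulate_study(cfg)
  nca <- run_nca_table(sim$concentrations, sim$truth, method = "lin_up_log_down")
  expect_true(all(c("telavancin", "hydroxypropylbetadex") %in% nca$analyte))
  expect_equal(anyDuplicated(nca[c("subject_id", "analyte")]), 0)
  m <- merge(nca, sim$truth, by = c("subject_id", "analyte"))
  tlv <- m[m$analyte == "telavancin", ]
  expect_true(all(abs(tlv$cl / tlv$cl_ml_h_kg - 1) < 0.03))
})
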