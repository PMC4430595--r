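test_that("macro exponents are the closed-form quadratic roots", {
  # k10 = k12 = k21 = 0.1 -> lambda = (0.3 +/- sqrt(0.05)) / 2
  p <- disposition_from_physiology(cl = 10, v1 = 100, q = 10, v2 = 100)
  expect_equal(p$lambda, c((0.3 + sqrt(0.05)) / 2, (0.3 - sqrt(0.05)) / 2),
               tolerance = 1e-12)
  expect_equal(sum(p$frac), 1)
  expect_equal(p$vss, 200)
  # one-compartment limit
  p1 <- disposition_from_physiology(cl = 10, v1 = 100, q = 0, v2 = 0)
  expect_equal(p1$lambda, 0.1)
  # AUC conservation: unit bolus area sum(frac_i / lambda_i)/v1 = 1/CL
  set.seed(5)
  for (i in 1:10) {
    cl <- runif(1, 5, 30); v1 <- runif(1, 50, 150)
    q <- runif(1, 10, 90); v2 <- runif(1, 30, 120)
    p <- disposition_from_physiology(cl, v1, q, v2)
    expect_equal(sum(p$frac / p$lambda) / p$v1, 1 / cl, tolerance = 1e-12)
    expect_true(p$lambda[1] > p$lambda[2] && p$lambda[2] > 0)
  }
})

test_that("infusion concentrations follow the closed-form solution", {
  # one-compartment, rate 750 ug/kg/h over 1 h, CL 13 mL/h/kg, k 0.1/h
  p <- disposition_from_physiology(cl = 13, v1 = 130, q = 0, v2 = 0)
  c1 <- simulate_concentrations(p, dose_per_kg = 0.75, t_inf = 1, times = 1)
  expect_equal(c1, (750 / 13) * (1 - exp(-0.1)), tolerance = 1e-12)
  expect_equal(c1, 5.49, tolerance = 1e-3)
  expect_equal(simulate_concentrations(p, 0.75, 1, 0), 0)
  expect_error(simulate_concentrations(p, 0.75, 1, -1), "invalid input")
  # peak at end of infusion for monotone disposition
  p2 <- disposition_from_physiology(cl = 14, v1 = 90, q = 50, v2 = 55)
  tt <- seq(0, 48, by = 0.25)
  cc <- simulate_concentrations(p2, 7.5, 1, tt)
  expect_equal(tt[which.max(cc)], 1)
})

test_that("analytic AUC to infinity equals dose/CL and is additive", {
  set.seed(9)
  for (i in 1:8) {
    cl <- runif(1, 5, 25)
    p <- disposition_from_physiology(cl, 90, 50, 55)
    d <- runif(1, 5, 12)
    expect_equal(analytic_auc(p, d, 1, 0, Inf), d * 1000 / cl,
                 tolerance = 1e-10)
    a <- runif(1, 1, 20)
    expect_equal(analytic_auc(p, d, 1, 0, a) + analytic_auc(p, d, 1, a, Inf),
                 analytic_auc(p, d, 1, 0, Inf), tolerance = 1e-10)
  }
  # matches numerical quadrature of the concentration curve
  p <- disposition_from_physiology(14, 90, 50, 55)
  num <- integrate(function(t) simulate_concentrations(p, 7.5, 1, t), 0, 96,
                   subdivisions = 2000L, rel.tol = 1e-10)$value
  expect_equal(analytic_auc(p, 7.5, 1, 0, 96), num, tolerance = 1e-8)
})

test_that("assay error censors below the quantification limit", {
  out <- apply_assay_error(c(5, 0.2, 1), sigma = 0, llq = 0.25)
  expect_equal(out$conc_ug_ml, c(5, NA, 1))
  expect_equal(out$blq, c(0L, 1L, 0L))
  # sigma 0 and all above llq: identity
  x <- c(10, 3, 0.6)
  expect_equal(apply_assay_error(x, 0, 0.25)$conc_ug_ml, x)
  # fixed seed reproduces the realisation
  a <- apply_assay_error(x, 0.2, 0.25, seed = 31)
  b <- apply_assay_error(x, 0.2, 0.25, seed = 31)
  expect_identical(a, b)
})

test_that("cohort generation is in-band, counted and deterministic", {
  cfg <- sim_config("A", n_per_stratum = c(normal = 4L, mild = 4L,
                                           moderate = 4L, severe = 4L,
                                           esrd = 4L), seed = 1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 20)
  expect_equal(unname(table(coh$group)[c("normal", "mild", "moderate",
                                         "severe", "esrd")]),
               rep(4L, 5), ignore_attr = TRUE)
  # every subject's Cockcroft-Gault value lies in its stratum band
  for (i in seq_len(nrow(coh))) {
    s <- coh[i, ]
    clcr <- cockcroft_gault(s$age_y, s$weight_kg, s$scr_mg_dl, s$sex)
    band <- cfg$clcr_bands[[s$group]]
    expect_true(clcr >= band[1] - 1e-9 && clcr <= band[2] + 1e-9)
  }
  expect_identical(generate_cohort(cfg), coh)
  # empty stratum request yields no rows, no error
  cfg0 <- sim_config("A", n_per_stratum = c(normal = 0L), seed = 1)
  expect_equal(nrow(generate_cohort(cfg0)), 0)
})

test_that("urine simulation obeys mass balance analytically", {
  p <- disposition_from_physiology(14, 90, 50, 55, fe = 1)
  iv <- data.frame(start_h = c(0, 6, 12), end_h = c(6, 12, 1e6))
  u <- simulate_urine(p, dose_per_kg = 7.5, weight = 80, iv, volume_cv = 0)
  expect_equal(sum(u$amount_mg), 7.5 * 80, tolerance = 1e-4)
  # fe = 0 -> nothing excreted
  p0 <- disposition_from_physiology(14, 90, 50, 55, fe = 0)
  u0 <- simulate_urine(p0, 7.5, 80, iv, volume_cv = 0)
  expect_equal(u0$conc_ug_ml, rep(0, 3))
  # fe = 0.6, 700 mg dose, full span -> 420 mg
  p6 <- disposition_from_physiology(14, 90, 50, 55, fe = 0.6)
  u6 <- simulate_urine(p6, 10, 70, data.frame(start_h = 0, end_h = 1e7),
                       volume_cv = 0)
  expect_equal(sum(u6$amount_mg), 420, tolerance = 1e-3)
  expect_error(simulate_urine(p, 7.5, 80,
                              data.frame(start_h = c(0, 4), end_h = c(6, 10))),
               "overlapping")
})

test_that("dialysate aliquots integrate the removal rate exactly", {
  p <- disposition_from_physiology(5, 90, 50, 55)
  d <- simulate_dialysis(p, 7.5, 80, session_start = 3, duration = 4,
                         q_d = 800, cl_hd_true = 270)
  expect_equal(unique(d$dialysate$volume_ml), 24000)
  expect_equal(nrow(d$dialysate), 8)
  expect_equal(d$arterial$time_h, 3:7)
  # recovered amount equals the integral of cl_hd * C(t) over the session
  oracle <- integrate(function(t) simulate_concentrations(p, 7.5, 1, t),
                      3, 7, rel.tol = 1e-10)$value * 270 / 1000
  expect_equal(d$removed_mg, oracle, tolerance = 2e-2)
  expect_equal(dialysate_cumulative(d$dialysate$conc_ug_ml,
                                    d$dialysate$volume_ml),
               d$removed_mg)
  # zero dialysis clearance removes nothing
  d0 <- simulate_dialysis(p, 7.5, 80, 3, cl_hd_true = 0)
  expect_equal(d0$dialysate$conc_ug_ml, rep(0, 8))
})

test_that("simulated studies are pure functions of the configuration", {
  cfg <- small_config("B", seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(small_config("B", seed = 78))
  expect_false(identical(s1$concentrations$conc_ug_ml,
                         s3$concentrations$conc_ug_ml))
})

test_that("decreasing renal function strictly increases analytic exposure", {
  cfg <- sim_config("A")
  clcr <- c(100, 65, 40, 20, 10)
  auc <- sapply(clcr, function(x) {
    cl_kg <- (cfg$cl_intercept + cfg$cl_slope * x) / 75
    p <- disposition_from_physiology(cl_kg, cfg$v1, cfg$q, cfg$v2)
    analytic_auc(p, 7.5, 1, 0, Inf)
  })
  expect_true(all(diff(auc) > 0))
})
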