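#' Macro disposition constants from physiological parameters
#'
#' Converts clearance/volume/inter-compartmental flow parameters of a two-
#' compartment mammillary model to the macro (poly-exponential) constants
#' used by the closed-form infusion equations. With micro rate constants
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, the exponents are the roots of
#' \deqn{\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0,}
#' solved in closed form. `Q = 0` gives the one-compartment limit with the
#' single exponent `CL/V1`.
#'
#' All parameters are per kg of body weight; any consistent mass unit works
#' because only ratios enter.
#'
#' @param cl Total clearance, mL/h/kg.
#' @param v1 Central volume, mL/kg.
#' @param q Inter-compartmental clearance, mL/h/kg (0 allowed).
#' @param v2 Peripheral volume, mL/kg (ignored when `q = 0`).
#' @param fe Fraction of total clearance that is renal, in [0, 1].
#' @return An object of class `disposition_params`: list with `lambda`
#'   (exponents 1/h, decreasing), `frac` (unit-bolus central-compartment
#'   weights summing to 1), `v1`, `cl`, `vss` (= V1 + V2), `fe`.
#' @examples
#' p <- disposition_from_physiology(cl = 10, v1 = 100, q = 10, v2 = 100)
#' p$lambda  # 0.2618, 0.0382 /h
#' @export
disposition_from_physiology <- function(cl, v1, q, v2, fe = 0) {
  if (cl <= 0 || v1 <= 0 || q < 0 || (q > 0 && v2 <= 0))
    stop("invalid input: cl, v1 must be positive; q non-negative; v2 positive when q > 0")
  if (fe < 0 || fe > 1) stop("invalid input: fe must lie in [0, 1]")
  k10 <- cl / v1
  if (q == 0) {
    lambda <- k10
    frac <- 1
    vss <- v1
  } else {
    k12 <- q / v1
    k21 <- q / v2
    s <- k10 + k12 + k21
    disc <- sqrt(s^2 - 4 * k10 * k21)
    lambda <- c((s + disc) / 2, (s - disc) / 2)
    frac <- c((lambda[1] - k21) / (lambda[1] - lambda[2]),
              (k21 - lambda[2]) / (lambda[1] - lambda[2]))
    vss <- v1 + v2
  }
  structure(list(lambda = lambda, frac = frac, v1 = v1, cl = cl,
                 vss = vss, fe = fe),
            class = "disposition_params")
}

#' @export
print.disposition_params <- function(x, ...) {
  cat("Disposition parameters (per kg)\n")
  cat("  exponents (1/h):", format(x$lambda, digits = 4), "\n")
  cat("  CL:", format(x$cl, digits = 4), "mL/h/kg   Vss:",
      format(x$vss, digits = 4), "mL/kg   fe:", x$fe, "\n")
  invisible(x)
}

#' Noiseless plasma concentrations after a zero-order infusion
#'
#' Closed-form superposition-of-exponentials solution for a constant-rate
#' infusion of duration `t_inf`. For each exponential term with weight
#' \eqn{w_i} and exponent \eqn{\lambda_i}, during the infusion
#' \deqn{C(t) = \frac{R}{V_1}\sum_i \frac{w_i}{\lambda_i}
#'   (1 - e^{-\lambda_i t}),}
#' and after its end the infusion-end value decays as
#' \eqn{e^{-\lambda_i (t - t_{inf})}}. The analytic area to infinity is
#' exactly dose/CL.
#'
#' @param params A [disposition_from_physiology()] object.
#' @param dose_per_kg Dose in mg/kg.
#' @param t_inf Infusion duration, h (> 0).
#' @param times Non-negative sampling times, h.
#' @return Concentrations in ug/mL at `times`.
#' @export
simulate_concentrations <- function(params, dose_per_kg, t_inf, times) {
  stopifnot(inherits(params, "disposition_params"))
  if (any(times < 0)) stop("invalid input: negative sampling time")
  if (t_inf <= 0) stop("invalid input: infusion duration must be positive")
  rate <- dose_per_kg * 1000 / t_inf              # ug/kg/h
  conc <- numeric(length(times))
  for (i in seq_along(params$lambda)) {
    lam <- params$lambda[i]
    b <- rate * params$frac[i] / (params$v1 * lam) # ug/mL at plateau of term i
    during <- b * (1 - exp(-lam * pmin(times, t_inf)))
    after <- ifelse(times > t_inf, exp(-lam * (times - t_inf)), 1)
    conc <- conc + during * after
  }
  conc
}

#' Analytic plasma AUC of an infusion profile over an interval
#'
#' Exact integral of the [simulate_concentrations()] curve between `t1` and
#' `t2` (`t2 = Inf` allowed). Used by the urine and dialysis simulators so
#' that simulated excreted amounts obey mass balance exactly.
#'
#' @inheritParams simulate_concentrations
#' @param t1,t2 Interval bounds in h, `0 <= t1 < t2 <= Inf`.
#' @return AUC in ug.h/mL.
#' @export
analytic_auc <- function(params, dose_per_kg, t_inf, t1 = 0, t2 = Inf) {
  stopifnot(inherits(params, "disposition_params"))
  if (t1 < 0 || t2 <= t1) stop("invalid input: need 0 <= t1 < t2")
  cum <- function(t) {
    # integral of C from 0 to t
    if (t == 0) return(0)
    rate <- dose_per_kg * 1000 / t_inf
    total <- 0
    for (i in seq_along(params$lambda)) {
      lam <- params$lambda[i]
      b <- rate * params$frac[i] / (params$v1 * lam)
      tin <- min(t, t_inf)
      part <- b * (tin - (1 - exp(-lam * tin)) / lam)
      if (t > t_inf) {
        cend <- b * (1 - exp(-lam * t_inf))
        decay <- if (is.infinite(t)) 1 else 1 - exp(-lam * (t - t_inf))
        part <- part + cend * decay / lam
      }
      total <- total + part
    }
    total
  }
  cum(t2) - cum(t1)
}
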