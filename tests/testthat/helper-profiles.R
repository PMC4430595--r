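# Shared fixtures: analytic poly-exponential profiles and small configs.

# Dense times out to about 10 terminal half-lives for a given terminal slope.
dense_times <- function(lambda_z, n = 400) {
  c(0, seq(0.05, 10 * log(2) / lambda_z, length.out = n))
}

# Bolus poly-exponential C(t) = sum A_i exp(-a_i t) with closed-form moments.
polyexp <- function(A, a) {
  list(conc = function(t) colSums(A * exp(-outer(a, t))),
       auc = sum(A / a),
       aumc = sum(A / a^2))
}

small_config <- function(study = "A", sigma = 0.10, seed = 11, ...) {
  n <- if (study == "A")
    c(normal = 3L, mild = 3L, moderate = 3L, severe = 3L, esrd = 2L)
  else
    c(normal = 4L, mild = 3L, moderate = 3L, severe = 3L)
  sim_config(study, n_per_stratum = n, sigma = sigma, seed = seed, ...)
}
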