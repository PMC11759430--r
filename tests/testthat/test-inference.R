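make_small_leaf <- function(seed = 2, noise_sd = 0.05) {
  leaf_fixture(seed = seed, noise_sd = noise_sd, rate_hz = 5,
               baseline_s = 5, pulse_s = 10, dark_s = 60)
}

test_that("log-posterior: support, noiseless optimum, sigma algebra", {
  fx <- make_small_leaf(noise_sd = 0)
  args <- list(trace = fx$trace, protocol = fx$protocol, env = fx$env,
               optics = fx$optics)
  lp <- function(k, g_bh, g_sw, s) {
    do.call(log_posterior,
            c(list(params = c(k = k, g_bh = g_bh, g_sw = g_sw,
                              sigma_obs = s)), args))
  }
  expect_identical(lp(-5, 0.01, 0.002, 0.05), -Inf)
  expect_identical(lp(900, -1e-3, 0.002, 0.05), -Inf)
  expect_identical(lp(900, 0.01, 0.002, 0), -Inf)

  # noiseless data: truth beats a grid of perturbed parameter sets
  lp_truth <- lp(900, 0.01, 0.002, 0.05)
  for (f in c(0.9, 0.95, 1.05, 1.1)) {
    expect_lt(lp(900 * f, 0.01, 0.002, 0.05), lp_truth)
    expect_lt(lp(900, 0.01 * f, 0.002, 0.05), lp_truth)
    expect_lt(lp(900, 0.01, 0.002 * f, 0.05), lp_truth)
  }

  # zero-residual data: doubling sigma costs n*ln 2 in likelihood
  # (plus the tiny prior shift, removed by differencing the priors)
  n <- length(fx$trace$times)
  pri <- prior_spec()
  prior_term <- function(s) dnorm(s, 0, pri$sigma_sd, log = TRUE) + log(2)
  delta <- (lp(900, 0.01, 0.002, 0.1) - prior_term(0.1)) -
    (lp(900, 0.01, 0.002, 0.05) - prior_term(0.05))
  expect_equal(delta, -n * log(2), tolerance = 1e-8)
})

test_that("fit_rmse matches its definition", {
  expect_equal(fit_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fit_rmse(c(1, 2, 3), c(1.5, 2.5, 3.5)), 0.5)
  set.seed(4)
  x <- rnorm(20000, 0, 0.07)
  expect_equal(fit_rmse(x, rep(0, length(x))), 0.07, tolerance = 0.02)
  expect_error(fit_rmse(1:3, 1:4), "lengths differ")
})

test_that("derive_cp divides draws by mass per area", {
  # aluminum: k = 2968 over 0.001335 * 2484 kg m-2 -> 895.0 J kg-1 K-1
  mpa <- 0.001335 * 2484
  cp <- derive_cp(2968, mpa)
  expect_equal(cp$mean, 895.05, tolerance = 1e-4)
  # identity: derive_cp(C_p * m, m) = C_p
  expect_equal(derive_cp(3851 * 0.25, 0.25)$mean, 3851)
  # tomato: mass per area 0.428 g / 17.348 cm2 = 0.2467 kg m-2
  mpa_tom <- mass_per_area_and_sla(0.428, 17.348)$mass_per_area
  expect_equal(mpa_tom, 0.2467, tolerance = 1e-3)
  expect_equal(derive_cp(950, mpa_tom)$mean, 3851, tolerance = 1e-3)
  # summaries inherit the draws (monotone transform)
  draws <- rnorm(500, 2968, 30)
  cp2 <- derive_cp(draws, mpa)
  expect_equal(unname(cp2$ci),
               unname(quantile(draws, c(0.025, 0.975)) / mpa))
  expect_error(derive_cp(draws, -1), "mass_per_area")
})

test_that("convergence diagnostics behave on iid, split and degenerate draws", {
  set.seed(9)
  iid <- array(rnorm(2000), dim = c(500, 4, 1),
               dimnames = list(NULL, NULL, "x"))
  d <- convergence_diagnostics(iid)
  expect_lt(d$rhat, 1.01)
  expect_equal(d$ess_bulk, 2000, tolerance = 0.2)

  # two chains stuck at different constants: R-hat blows up
  stuck <- cbind(rep(0, 200) + rnorm(200, 0, 1e-3),
                 rep(5, 200) + rnorm(200, 0, 1e-3))
  d2 <- convergence_diagnostics(stuck)
  expect_gt(d2$rhat, 1.1)

  # fully degenerate draws: flagged, not a number
  expect_warning(d3 <- convergence_diagnostics(matrix(1, 200, 4)),
                 "degenerate")
  expect_true(is.na(d3$rhat))
  expect_error(convergence_diagnostics(matrix(rnorm(40), 20, 2)),
               "at least 100")
})

test_that("fit recovers truth on a synthetic leaf and propagates C_p", {
  fx <- make_small_leaf(seed = 21)
  fit <- suppressWarnings(
    fit_transient(fx$trace, fx$protocol, fx$env, fx$optics,
                  sample = fx$sample,
                  control = mcmc_control(chains = 2, iterations = 1500,
                                         warmup = 600, seed = 77)))
  est <- coef(fit)
  expect_equal(est[["k"]], fx$truth$k, tolerance = 0.1)
  expect_equal(est[["g_bh"]], fx$truth$g_bh, tolerance = 0.1)
  expect_equal(est[["g_sw"]], fx$truth$g_sw, tolerance = 0.1)
  expect_lt(fit$rmse, 3 * 0.05)

  # C_p credible interval is the k interval divided by mass per area
  s <- fit$summary
  expect_equal(unname(fit$cp$ci),
               c(s$ci_lower[s$parameter == "k"],
                 s$ci_upper[s$parameter == "k"]) / fx$sample$mass_per_area)

  # methods on the fit object
  expect_s3_class(predict(fit), "thermal_trace")
  expect_equal(length(residuals(fit)), length(fit$trace$times))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "thermal_trace")
  expect_output(print(fit), "Energy-balance transient fit")
})

test_that("halving the noise tightens the posterior on k", {
  fits <- lapply(c(0.1, 0.05), function(ns) {
    fx <- make_small_leaf(seed = 31, noise_sd = ns)
    suppressWarnings(
      fit_transient(fx$trace, fx$protocol, fx$env, fx$optics,
                    control = mcmc_control(chains = 2, iterations = 1200,
                                           warmup = 500, seed = 5)))
  })
  sd_k <- vapply(fits, function(f)
    f$summary$sd[f$summary$parameter == "k"], numeric(1))
  expect_lt(sd_k[2], sd_k[1])
})

test_that("an all-dark trace leaves k unidentified and is flagged", {
  optics <- optical_properties(0.9, 0.98)
  env <- env_state(293.15, 0.5)
  # protocol with a vanishingly weak pulse: no thermal signal
  protocol <- pulse_protocol(baseline_s = 5, pulse_s = 10, dark_s = 45,
                             irradiance = 0)
  truth <- list(k = 900, g_bh = 0.01, g_sw = 0.002)
  dark <- generate_synthetic_transient(truth, protocol, env, optics,
                                       noise_sd = 0.05, seed = 12,
                                       sample_rate_hz = 5)
  fit <- suppressWarnings(
    fit_transient(dark, protocol, env, optics,
                  control = mcmc_control(chains = 2, iterations = 800,
                                         warmup = 400, seed = 3)))
  s <- fit$summary
  ci_width <- s$ci_upper[s$parameter == "k"] - s$ci_lower[s$parameter == "k"]
  # CI spans more than half the prior scale, or the fit is flagged
  expect_true(ci_width > 0.5 * prior_spec()$k_sd || !fit$converged)
})
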