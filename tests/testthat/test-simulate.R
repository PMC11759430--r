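test_that("all-dark protocol from equilibrium gives a constant trace", {
  optics <- optical_properties(0.9, 0.98)
  cond <- conductances(0.01, 0.002)
  env <- env_state(293.15, 0.5)
  Teq <- equilibrium_temperature(env, optics, cond)
  dark <- light_protocol(0, 60, 0)
  tr <- integrate_temperature(Teq, dark, env, optics, cond, 900,
                              sample_rate_hz = 5)
  expect_lt(max(abs(tr$T - Teq)), 1e-7)
})

test_that("adaptive integrator agrees with a 1 ms RK4 oracle", {
  set.seed(11)
  protocol <- pulse_protocol(baseline_s = 2, pulse_s = 5, dark_s = 13)
  out_times <- seq(0, 20, by = 0.5)
  for (i in 1:2) {
    optics <- optical_properties(runif(1, 0.85, 0.98), runif(1, 0.9, 0.99))
    cond <- conductances(runif(1, 0.005, 0.02), runif(1, 0.001, 0.005))
    k <- runif(1, 400, 1500)
    env <- env_state(runif(1, 288, 298), runif(1, 0.3, 0.8))
    T0 <- equilibrium_temperature(env, optics, cond)
    fast <- integrate_temperature(T0, protocol, env, optics, cond, k,
                                  times = out_times)
    slow <- rk4_oracle(T0, protocol, env, optics, cond, k, out_times,
                       dt = 1e-3)
    expect_lt(max(abs(fast$T - slow)), 1e-3)
  }
})

test_that("integrator handles time-varying environment traces", {
  optics <- optical_properties(0.95, 0.96)
  cond <- conductances(0.01, 0)
  # air temperature drifting 0.5 K over the run, sampled every 5 s
  et <- environment_trace(seq(0, 30, by = 5),
                          T_air = 293.15 + seq(0, 0.5, length.out = 7),
                          RH_air = 0.5)
  protocol <- light_protocol(0, 30, 0)
  out_times <- seq(0, 30, by = 1)
  fast <- integrate_temperature(293.15, protocol, et, optics, cond, 2000,
                                times = out_times)
  slow <- rk4_oracle(293.15, protocol, et, optics, cond, 2000, out_times,
                     dt = 1e-3)
  expect_lt(max(abs(fast$T - slow)), 1e-3)
  expect_gt(fast$T[length(fast$T)], 293.15)  # dragged up by warming air
})

test_that("plate transient rises during the pulse then decays monotonically", {
  fx <- aluminum_fixture(seed = 1, noise_sd = 0, rate_hz = 1)
  tr <- fx$trace
  pw <- pulse_window(fx$protocol)
  lit <- tr$times >= pw[1] & tr$times <= pw[2]
  post <- tr$times > pw[2]
  expect_true(all(diff(tr$T[lit]) > 0))
  expect_true(all(diff(tr$T[post]) < 1e-12))
  # decay heads back toward the dark equilibrium (= T_air for the dry plate)
  expect_equal(tr$T[length(tr$T)], fx$env$T_air, tolerance = 1e-3)
})

test_that("larger k gives a strictly smaller pulse temperature rise", {
  optics <- optical_properties(0.93, 0.97)
  cond <- conductances(0.012, 0.002)
  env <- env_state(294.15, 0.55)
  protocol <- pulse_protocol()
  T0 <- equilibrium_temperature(env, optics, cond)
  dmax <- vapply(c(400, 900, 2000, 5000), function(k) {
    tr <- integrate_temperature(T0, protocol, env, optics, cond, k,
                                sample_rate_hz = 5)
    max(tr$T) - T0
  }, numeric(1))
  expect_true(all(diff(dmax) < 0))
})

test_that("synthetic transients are reproducible and calibrated", {
  fx <- list(truth = list(k = 900, g_bh = 0.01, g_sw = 0.002))
  optics <- optical_properties(0.9, 0.98)
  env <- env_state(293.15, 0.5)
  protocol <- pulse_protocol()
  a <- generate_synthetic_transient(fx$truth, protocol, env, optics,
                                    noise_sd = 0.05, seed = 3)
  b <- generate_synthetic_transient(fx$truth, protocol, env, optics,
                                    noise_sd = 0.05, seed = 3)
  expect_identical(a$T, b$T)
  clean <- generate_synthetic_transient(fx$truth, protocol, env, optics,
                                        noise_sd = 0)
  expect_equal(length(clean$T), length(a$T))
  # noiseless equals the plain integration
  cond <- conductances(0.01, 0.002)
  T0 <- equilibrium_temperature(env, optics, cond)
  direct <- integrate_temperature(T0, protocol, env, optics, cond, 900)
  expect_identical(clean$T, direct$T)
  # residual sd close to the requested noise at n = 3251
  expect_equal(sd(a$T - clean$T), 0.05, tolerance = 0.1)
})

test_that("heating slope matches the window definition", {
  t <- seq(0, 30, by = 0.2)
  expect_equal(heating_slope(thermal_trace(t, rep(293.15, length(t))),
                             c(5, 15)), 0)
  ramp <- thermal_trace(t, 293.15 + pmin(pmax(t - 5, 0), 10) * 0.1)
  expect_equal(heating_slope(ramp, c(5, 15)), 0.1, tolerance = 1e-9)
  # a 3.38 K maximum rise over a 10 s pulse -> 0.338 K/s
  bump <- thermal_trace(t, 293.15 + pmin(pmax(t - 5, 0), 10) * 0.338)
  expect_equal(heating_slope(bump, c(5, 15)), 0.338, tolerance = 1e-9)
  expect_error(heating_slope(ramp, c(40, 50)), "no trace samples")
})

test_that("spline derivative recovers slopes and beats raw differencing", {
  t <- seq(0, 20, by = 0.04)
  line <- thermal_trace(t, 290 + 0.17 * t)
  d <- spline_derivative(line)
  interior <- t > 1 & t < 19
  expect_lt(max(abs(d$dT_dt[interior] - 0.17)), 1e-6)

  # noiseless transient: derivative matches the model rhs away from switches
  optics <- optical_properties(0.9, 0.98)
  cond <- conductances(0.01, 0.002)
  env <- env_state(293.15, 0.5)
  protocol <- pulse_protocol()
  fx <- generate_synthetic_transient(list(k = 900, g_bh = 0.01,
                                          g_sw = 0.002),
                                     protocol, env, optics, noise_sd = 0)
  d2 <- spline_derivative(fx)
  rhs <- vapply(seq_along(fx$times), function(i) {
    e <- env_at(env, fx$times[i],
                I_s = protocol_irradiance(protocol, fx$times[i]))
    energy_balance_rhs(fx$T[i], e, optics, cond, 900)
  }, numeric(1))
  away <- abs(fx$times - 10) > 3 & abs(fx$times - 20) > 3 &
    fx$times > 1 & fx$times < 129
  expect_lt(max(abs(d2$dT_dt[away] - rhs[away])), 5e-3)

  # with noise, the smoothing spline beats finite differences
  set.seed(5)
  noisy <- thermal_trace(fx$times, fx$T + rnorm(length(fx$T), 0, 0.05))
  d3 <- spline_derivative(noisy)
  fd <- diff(noisy$T) / diff(noisy$times)
  mid <- (rhs[-1] + rhs[-length(rhs)]) / 2
  rmse_spline <- sqrt(mean((d3$dT_dt - rhs)^2))
  rmse_fd <- sqrt(mean((fd - mid)^2))
  expect_lt(rmse_spline, rmse_fd)
  expect_error(spline_derivative(thermal_trace(1:5, rep(293, 5))),
               "at least 10")
})

test_that("light-onset detection finds the switch on a black-tape trace", {
  # fast thin tape: k = 150 -> onset slope alpha*I/k ~ 1.7 K/s
  optics <- optical_properties(0.95, 0.97)
  env <- env_state(293.15, 0.5)
  protocol <- pulse_protocol(baseline_s = 5, pulse_s = 10, dark_s = 20)
  tape <- generate_synthetic_transient(list(k = 150, g_bh = 0.01, g_sw = 0),
                                       protocol, env, optics,
                                       noise_sd = 0.02, seed = 8,
                                       sample_rate_hz = 25)
  t_on <- detect_light_onset(tape, threshold = 0.8)
  expect_lt(abs(t_on - 5), 1 / 25 + 1e-9)
  # constant trace: never exceeds
  flat <- thermal_trace(tape$times, rep(293.15, length(tape$times)))
  expect_error(detect_light_onset(flat, threshold = 0.8), "never exceeds")
  # threshold 0 on a strictly rising trace -> first sample
  rise <- thermal_trace(seq(0, 2, 0.04), 293.15 + seq(0, 2, 0.04))
  expect_equal(detect_light_onset(rise, threshold = 0), 0)
})

test_that("trace containers validate and decimate correctly", {
  expect_error(thermal_trace(c(0, 1, 1, 2), rep(293, 4)), "increasing")
  tr <- thermal_trace(seq(0, 10, by = 0.04), rep(293.15, 251))
  expect_equal(tr$sample_rate_hz, 25)
  d <- decimate_trace(tr, 5)
  expect_equal(d$sample_rate_hz, 5)
  expect_equal(length(d$times), 51)
  expect_error(environment_trace(c(0, 0), 293, 0.5), "increasing")
  pr <- pulse_protocol(10, 10, 110, 270)
  expect_equal(unname(pulse_window(pr)), c(10, 20))
  expect_equal(protocol_irradiance(pr, c(5, 15, 25)), c(0, 270, 0))
})
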