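test_that("saturation vapour pressure matches hand-evaluated Tetens values", {
  # Tetens by hand: 610.78 at 0 degC; 610.78*exp(17.27*20/257.3) = 2338.2
  expect_equal(saturation_vapour_pressure(273.15), 610.78, tolerance = 1e-6)
  expect_equal(saturation_vapour_pressure(293.15), 2338.2, tolerance = 1e-4)
  # strictly increasing and positive
  Ts <- seq(260, 320, by = 5)
  es <- saturation_vapour_pressure(Ts)
  expect_true(all(es > 0))
  expect_true(all(diff(es) > 0))
  # Buck agrees with Tetens to ~0.3% at room temperature
  expect_equal(saturation_vapour_pressure(293.15, "buck"),
               saturation_vapour_pressure(293.15, "tetens"),
               tolerance = 3e-3)
  expect_error(saturation_vapour_pressure(150), "200")
})

test_that("psychrometric state reproduces VPD and air density", {
  env <- env_state(T_air = 293.15, RH_air = 1.0)
  expect_equal(psychrometric_state(293.15, env)$VPD, 0)
  env <- env_state(T_air = 293.15, RH_air = 0.7)
  ps <- psychrometric_state(293.15, env)
  expect_equal(ps$VPD, 0.3 * 2338.2, tolerance = 1e-4)
  # ideal-gas air density at 20 degC, 1 atm: 101325/(287.05*293.15) = 1.2041
  expect_equal(ps$rho_air, 1.2041, tolerance = 1e-4)
  expect_true(ps$es > 0 && ps$ea > 0 && ps$C_s > 0 && ps$lambda > 0)
  expect_equal(ps$ea, env$RH_air * saturation_vapour_pressure(env$T_air))
})

test_that("series conductance handles limits and hand value", {
  expect_identical(series_conductance(0, 0.01), 0)
  expect_identical(series_conductance(0.01, 0), 0)
  g <- 0.004
  expect_equal(series_conductance(g, g), g / 2)
  # 1/(1/0.003 + 1/0.010870) = 0.0023512
  expect_equal(series_conductance(0.003, 0.010870), 0.0023512,
               tolerance = 1e-4)
  expect_true(series_conductance(0.003, 0.01) <= 0.003)
  expect_error(series_conductance(-1e-3, 0.01), ">= 0")
})

test_that("molar conversion matches P/(RT) and round-trips", {
  # P/(RT) = 101325/(8.3145*293.15) = 41.570 mol m-3
  expect_equal(conductance_to_molar(0.01, 293.15, 101325), 0.41570,
               tolerance = 1e-4)
  expect_identical(conductance_to_molar(0, 293.15, 101325), 0)
  g <- 0.0123
  for (flag in c(TRUE, FALSE)) {
    gm <- conductance_to_molar(g, 300, 98000, include_092 = flag)
    expect_equal(molar_to_conductance(gm, 300, 98000, include_092 = flag), g)
  }
  # the 0.92 stomatal variant differs by exactly that factor
  expect_equal(conductance_to_molar(0.01, 293.15, 101325, TRUE) * 0.92,
               conductance_to_molar(0.01, 293.15, 101325, FALSE))
})

test_that("flux components: zero state, absorbed pulse, long-wave sign", {
  optics <- optical_properties(0.98, 0.96)
  cond <- conductances(0.01, 0)
  env0 <- env_state(293.15, 0.5, I_s = 0)
  f0 <- flux_components(293.15, env0, optics, cond)
  expect_equal(unname(f0), c(0, 0, 0, 0))
  # absorbed short-wave under the pulse: 0.98 * 270 = 264.6 W m-2
  env1 <- env_state(293.15, 0.5, I_s = 270)
  expect_equal(flux_components(293.15, env1, optics, cond)[["SW_abs"]],
               264.6)
  # warmer object than surroundings -> net long-wave loss
  f <- flux_components(295.15, env0, optics, cond)
  expect_lt(f[["LW_net"]], 0)
  expect_gt(f[["H_sensible"]], 0)
})

test_that("energy-balance rhs: onset slope and k-proportionality", {
  optics <- optical_properties(0.98, 0.96)
  cond <- conductances(0.01, 0)
  env <- env_state(293.15, 0.5, I_s = 270)
  # plate at dark equilibrium when the pulse starts: slope = alpha*I/k
  k <- 0.001335 * 2484 * 896  # 2971.3 J m-2 K-1
  expect_equal(energy_balance_rhs(293.15, env, optics, cond, k),
               264.6 / k, tolerance = 1e-12)
  expect_equal(264.6 / k, 0.0892, tolerance = 2e-3)  # printed rounding
  # doubling k halves the tendency at any fixed state
  r1 <- energy_balance_rhs(296, env, optics, cond, 1000)
  r2 <- energy_balance_rhs(296, env, optics, cond, 2000)
  expect_equal(r1, 2 * r2)
  expect_error(energy_balance_rhs(296, env, optics, cond, -5), "k")
})

test_that("equilibrium temperature: identity, cooling sign, conservation", {
  optics <- optical_properties(0.95, 0.97)
  env <- env_state(293.15, 0.6, I_s = 0)
  # dry object, T_reflect = T_air -> equilibrates at T_air
  Teq_dry <- equilibrium_temperature(env, optics, conductances(0.01, 0))
  expect_equal(Teq_dry, 293.15, tolerance = 1e-8)
  # transpiring leaf in unsaturated air -> below air temperature
  cond <- conductances(0.01, 0.003)
  Teq <- equilibrium_temperature(env, optics, cond)
  expect_lt(Teq, 293.15)
  # energy conservation at the root
  f <- flux_components(Teq, env, optics, cond)
  expect_lt(abs(sum(f * c(1, 1, -1, -1))), 1e-8)
  # local stability: rhs strictly decreasing in T_leaf near equilibrium
  r <- function(T) energy_balance_rhs(T, env, optics, cond, 1000)
  expect_lt((r(Teq + 0.01) - r(Teq - 0.01)) / 0.02, 0)
})

test_that("conductances container keeps the 0.92 boundary-layer relation", {
  for (g in c(1e-4, 0.005, 0.02)) {
    cd <- conductances(g_bh = g, g_sw = g / 3)
    expect_equal(cd$g_bw, g / 0.92)
  }
  expect_error(conductances(-0.01), "g_bh")
})

test_that("input validation rejects unphysical states", {
  expect_error(env_state(500, 0.5), "kelvin")
  expect_error(env_state(293, 1.5), "RH_air")
  expect_error(env_state(293, 0.5, I_s = -10), "I_s")
  expect_error(optical_properties(1.2, 0.9), "alpha")
  expect_silent(optical_properties(1.078, 0.96, strict = FALSE))
})
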