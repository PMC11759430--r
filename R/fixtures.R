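#' Synthetic aluminum-plate validation fixture
#'
#' Emulates the method-validation experiment: a black-painted aluminum plate
#' (thickness 0.001335 m, density 2484 kg m-3, C_p 896 J kg-1 K-1, emissivity
#' 0.96, absorptance 0.98, so k = lt * rho * C_p = 2971.3 J m-2 K-1) exposed
#' to a 60 s pulse of 270 W m-2 followed by 9 min of darkness, recorded with
#' additive sensor noise. A dry plate has no latent flux (`g_sw = 0`). The
#' unreported lab conditions are fixed at the stated setpoints: air at
#' 20 degC, RH 50\%, `T_reflect = T_air`, boundary-layer conductance
#' 0.01 m s-1 (fan-stirred enclosure, ~0.2 m s-1 wind).
#'
#' @param seed integer seed for the noise.
#' @param noise_sd sensor noise sd (K); default 0.05.
#' @param rate_hz sampling rate (Hz); default 5 (the rate used for fitting).
#' @param baseline_s dark baseline before the pulse (s).
#' @param pulse_s,dark_s pulse and dark durations (s).
#' @param irradiance pulse irradiance (W m-2).
#' @param T_air_C,RH lab air temperature (degC) and relative humidity.
#' @param g_bh true boundary-layer conductance (m s-1).
#' @return A list with `trace`, `protocol`, `env`, `optics`, `sample`, and
#'   `truth` (list `k`, `g_bh`, `g_sw`, `C_p`).
#' @examples
#' fx <- aluminum_fixture(seed = 1)
#' fx$truth$C_p
#' @export
aluminum_fixture <- function(seed = 1, noise_sd = 0.05, rate_hz = 5,
                             baseline_s = 10, pulse_s = 60, dark_s = 540,
                             irradiance = 270, T_air_C = 20, RH = 0.5,
                             g_bh = 0.01) {
  lt <- 0.001335; rho <- 2484; C_p <- 896
  optics <- optical_properties(alpha = 0.98, epsilon = 0.96)
  sample <- sample_properties(lt_m = lt, rho = rho,
                              alpha = 0.98, epsilon = 0.96)
  truth <- list(k = lt * rho * C_p, g_bh = g_bh, g_sw = 0, C_p = C_p)
  protocol <- pulse_protocol(baseline_s, pulse_s, dark_s, irradiance)
  env <- env_state(T_air = T_air_C + 273.15, RH_air = RH)
  trace <- generate_synthetic_transient(truth, protocol, env, optics,
                                        noise_sd = noise_sd, seed = seed,
                                        sample_rate_hz = rate_hz)
  list(trace = trace, protocol = protocol, env = env, optics = optics,
       sample = sample, truth = truth)
}

#' Synthetic leaf fixture
#'
#' A tomato-like leaf under the standard protocol (10 s pulse at 270 W m-2,
#' 110 s dark): areal heat capacity k = 900 J m-2 K-1, boundary-layer
#' conductance 0.01 m s-1, stomatal conductance 0.002 m s-1, absorptance
#' 0.901, emissivity 0.986, fresh mass per area 0.2467 kg m-2 (0.428 g over
#' 17.348 cm2). Sampled at the camera's 25 Hz by default with 0.05 K noise.
#'
#' @param seed integer seed for the noise.
#' @param k,g_bh,g_sw true parameters (J m-2 K-1, m s-1, m s-1).
#' @param noise_sd sensor noise sd (K).
#' @param rate_hz sampling rate (Hz).
#' @param baseline_s,pulse_s,dark_s protocol durations (s).
#' @param irradiance pulse irradiance (W m-2).
#' @param T_air_C,RH lab air temperature (degC) and relative humidity.
#' @param alpha,epsilon leaf optics.
#' @param FW_g,area_cm2,DW_g leaf mass and area (set the mass per area).
#' @return A list with `trace`, `protocol`, `env`, `optics`, `sample`, and
#'   `truth` (including the implied `C_p = k / mass_per_area`).
#' @examples
#' fx <- leaf_fixture(seed = 1, rate_hz = 5)
#' fx$truth$C_p
#' @export
leaf_fixture <- function(seed = 1, k = 900, g_bh = 0.01, g_sw = 0.002,
                         noise_sd = 0.05, rate_hz = 25, baseline_s = 10,
                         pulse_s = 10, dark_s = 110, irradiance = 270,
                         T_air_C = 20, RH = 0.5, alpha = 0.901,
                         epsilon = 0.986, FW_g = 0.428, area_cm2 = 17.348,
                         DW_g = 0.049) {
  optics <- optical_properties(alpha = alpha, epsilon = epsilon)
  sample <- sample_properties(FW_g = FW_g, area_cm2 = area_cm2, DW_g = DW_g,
                              alpha = alpha, epsilon = epsilon)
  truth <- list(k = k, g_bh = g_bh, g_sw = g_sw,
                C_p = k / sample$mass_per_area)
  protocol <- pulse_protocol(baseline_s, pulse_s, dark_s, irradiance)
  env <- env_state(T_air = T_air_C + 273.15, RH_air = RH)
  trace <- generate_synthetic_transient(truth, protocol, env, optics,
                                        noise_sd = noise_sd, seed = seed,
                                        sample_rate_hz = rate_hz)
  list(trace = trace, protocol = protocol, env = env, optics = optics,
       sample = sample, truth = truth)
}
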