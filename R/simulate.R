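#' Simulate a temperature transient under a light protocol
#'
#' Integrates the dynamic energy balance dT/dt = `energy_balance_rhs` with the
#' irradiance switching between the protocol's piecewise-constant segments.
#' The integrator is an adaptive embedded Runge-Kutta (Cash-Karp 4/5) whose
#' steps never cross a segment boundary, so the discontinuous forcing is
#' handled exactly; environmental drivers are interpolated piecewise-linearly
#' in time.
#'
#' @param T0 initial object temperature (K) at the first output time.
#' @param protocol a [light_protocol()].
#' @param env an [environment_trace()] or [env_state()].
#' @param optics an [optical_properties()].
#' @param cond a [conductances()].
#' @param k areal heat capacity (J m-2 K-1).
#' @param times output times (s); defaults to a regular grid over the protocol
#'   at `sample_rate_hz`.
#' @param sample_rate_hz output rate when `times` is not given (default 25 Hz,
#'   the thermal camera's frame rate).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param const a [physics_constants()].
#' @return A [thermal_trace()].
#' @examples
#' env <- env_state(293.15, 0.5)
#' tr <- integrate_temperature(293.15, pulse_protocol(), env,
#'                             optical_properties(0.9, 0.98),
#'                             conductances(0.01, 0.002), k = 900,
#'                             sample_rate_hz = 5)
#' @export
integrate_temperature <- function(T0, protocol, env, optics, cond, k,
                                  times = NULL, sample_rate_hz = 25,
                                  rtol = 1e-8, atol = 1e-8,
                                  const = physics_constants()) {
  check_temperature(T0, "T0")
  check_scalar(k, "k", lower = 1e-12)
  stopifnot(inherits(protocol, "light_protocol"),
            inherits(optics, "optical_properties"),
            inherits(cond, "conductances"))
  env <- as_environment_trace(env)
  if (is.null(times)) {
    times <- seq(min(protocol$t_start), max(protocol$t_end),
                 by = 1 / sample_rate_hz)
  } else {
    sample_rate_hz <- 1 / stats::median(diff(times))
  }
  Tout <- integrate_eb_cpp(T0, times, protocol_matrix(protocol),
                           env_matrix(env), env$P_atm, optics$alpha,
                           optics$epsilon, cond$g_bh, cond$g_sw, k,
                           const$C_s, const$lambda, es_formula_code(const),
                           rtol, atol)
  thermal_trace(times, Tout, sample_rate_hz = sample_rate_hz)
}

#' Generate a synthetic noisy temperature transient
#'
#' Forward-simulates the energy balance at known ("true") parameters and adds
#' independent zero-mean Gaussian sensor noise, emulating a thermal-camera
#' recording. The default noise (0.05 K) sits between the camera noise floor
#' (NETD < 30 mK) and typical thermocouple noise (~0.2 K).
#'
#' @param truth list with elements `k` (J m-2 K-1), `g_bh`, `g_sw` (m s-1).
#' @param protocol a [light_protocol()].
#' @param env an [environment_trace()] or [env_state()].
#' @param optics an [optical_properties()].
#' @param noise_sd additive noise standard deviation (K).
#' @param seed optional integer seed for reproducibility.
#' @param sample_rate_hz sampling rate (Hz).
#' @param T0 initial temperature (K); defaults to the dark equilibrium of the
#'   environment at the protocol start.
#' @param const a [physics_constants()].
#' @return A [thermal_trace()].
#' @examples
#' env <- env_state(293.15, 0.5)
#' tr <- generate_synthetic_transient(list(k = 900, g_bh = 0.01,
#'                                         g_sw = 0.002),
#'                                    pulse_protocol(), env,
#'                                    optical_properties(0.9, 0.98),
#'                                    noise_sd = 0.05, seed = 1,
#'                                    sample_rate_hz = 5)
#' @export
generate_synthetic_transient <- function(truth, protocol, env, optics,
                                         noise_sd = 0.05, seed = NULL,
                                         sample_rate_hz = 25, T0 = NULL,
                                         const = physics_constants()) {
  check_scalar(noise_sd, "noise_sd", lower = 0)
  cond <- conductances(truth$g_bh, truth$g_sw)
  env <- as_environment_trace(env)
  if (is.null(T0)) {
    e0 <- env_at(env, min(protocol$t_start), I_s = 0)
    T0 <- equilibrium_temperature(e0, optics, cond, const)
  }
  clean <- integrate_temperature(T0, protocol, env, optics, cond, truth$k,
                                 sample_rate_hz = sample_rate_hz,
                                 const = const)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      })
    }
    clean$T <- clean$T + stats::rnorm(length(clean$T), 0, noise_sd)
  }
  clean
}

#' Heating slope during the light pulse
#'
#' The maximum temperature rise during the pulse divided by the pulse
#' duration: `(max T in window - T at t_on) / (t_off - t_on)`, in K s-1. This
#' is the temperature response rate reported per species.
#'
#' @param trace a [thermal_trace()].
#' @param pulse numeric `c(t_on, t_off)` (s), e.g. from [pulse_window()].
#' @return Heating slope (K s-1).
#' @examples
#' tr <- thermal_trace(0:20, 293.15 + pmin(0:20, 10) * 0.1)
#' heating_slope(tr, c(0, 10))  # 0.1
#' @export
heating_slope <- function(trace, pulse) {
  stopifnot(inherits(trace, "thermal_trace"), length(pulse) == 2L)
  t_on <- pulse[1]; t_off <- pulse[2]
  if (t_off <= t_on) stop("pulse window must have t_on < t_off", call. = FALSE)
  inside <- trace$times >= t_on - 1e-9 & trace$times <= t_off + 1e-9
  if (!any(inside))
    stop("pulse window contains no trace samples", call. = FALSE)
  T_on <- trace$T[which(inside)[1]]
  (max(trace$T[inside]) - T_on) / (t_off - t_on)
}

#' Smoothed derivative of a temperature trace
#'
#' Fits a smoothing spline to the trace (the standard way to estimate
#' dT_leaf/dt from noisy thermograms) and evaluates the derivative of the
#' fitted function at the trace times. Smoothness is chosen by generalized
#' cross-validation unless `spar` or `df` is given.
#'
#' @param trace a [thermal_trace()].
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @param df optional equivalent degrees of freedom.
#' @return A list with `times`, `dT_dt` (K s-1) and the fitted `spline`.
#' @examples
#' tr <- thermal_trace(seq(0, 10, 0.1), 293.15 + 0.2 * seq(0, 10, 0.1))
#' d <- spline_derivative(tr)
#' @export
spline_derivative <- function(trace, spar = NULL, df = NULL) {
  stopifnot(inherits(trace, "thermal_trace"))
  if (length(trace$times) < 10L)
    stop("need at least 10 samples for a spline derivative", call. = FALSE)
  args <- list(x = trace$times, y = trace$T)
  if (!is.null(spar)) args$spar <- spar
  if (!is.null(df)) args$df <- df
  fit <- do.call(stats::smooth.spline, args)
  dT <- stats::predict(fit, x = trace$times, deriv = 1)$y
  list(times = trace$times, dT_dt = dT, spline = fit)
}

local_slopes <- function(times, T, window = 5L) {
  n <- length(times)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    tt <- times[idx] - times[i]
    sum(tt * (T[idx] - mean(T[idx]))) / sum(tt * (tt - mean(tt)))
  }, numeric(1))
}

#' Detect the light-onset time from a reference trace
#'
#' The temperature response of a fast, strongly absorbing reference (black
#' tape) marks when the lamp switched on. The detector computes a locally
#' smoothed derivative (local linear slope over a short window) and returns
#' the earliest trace time at which it exceeds `threshold`; used to align the
#' protocol clock with the camera clock.
#'
#' @param trace a [thermal_trace()] of the reference object.
#' @param threshold slope threshold (K s-1); choose well above the
#'   noise-induced slope and below the onset slope `alpha I / k`.
#' @param window odd number of samples for the local slope (default 5).
#' @return Onset time (s).
#' @examples
#' t <- seq(0, 10, 0.04)
#' tape <- thermal_trace(t, 293.15 + pmax(0, t - 5) * 2)
#' detect_light_onset(tape, threshold = 1)
#' @export
detect_light_onset <- function(trace, threshold, window = 5L) {
  stopifnot(inherits(trace, "thermal_trace"))
  check_scalar(threshold, "threshold")
  sl <- local_slopes(trace$times, trace$T, window = window)
  hit <- which(sl > threshold)
  if (length(hit) == 0L)
    stop("smoothed derivative never exceeds threshold = ", format(threshold),
         "; no light onset detected", call. = FALSE)
  trace$times[hit[1]]
}
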