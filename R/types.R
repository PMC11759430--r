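check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number", call. = FALSE)
  if (x < lower || x > upper)
    stop("`", name, "` = ", format(x), " is outside [", lower, ", ", upper, "]",
         call. = FALSE)
  invisible(x)
}

check_temperature <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`", name, "` must be finite", call. = FALSE)
  if (any(x <= 200) || any(x >= 400))
    stop("`", name, "` must be in kelvin, strictly between 200 and 400 K ",
         "(got ", format(x[which(x <= 200 | x >= 400)[1]]), ")", call. = FALSE)
  invisible(x)
}

#' Instantaneous environmental state
#'
#' The drivers of the leaf energy balance at one instant: air temperature,
#' relative humidity, radiative temperature of the surroundings (measured in
#' practice from a crumpled aluminum foil imaged at emissivity 1), atmospheric
#' pressure, and incident short-wave irradiance.
#'
#' @param T_air air temperature (K).
#' @param RH_air relative humidity as a fraction in \[0, 1\].
#' @param T_reflect radiative temperature of the surroundings (K); defaults to
#'   `T_air`.
#' @param P_atm atmospheric pressure (Pa).
#' @param I_s incident short-wave irradiance (W m-2).
#' @return An object of class `env_state`.
#' @examples
#' env_state(T_air = 293.15, RH_air = 0.5)
#' @export
env_state <- function(T_air, RH_air, T_reflect = T_air, P_atm = 101325,
                      I_s = 0) {
  check_temperature(T_air, "T_air")
  check_temperature(T_reflect, "T_reflect")
  check_scalar(RH_air, "RH_air", 0, 1)
  check_scalar(P_atm, "P_atm", lower = 1e-12)
  check_scalar(I_s, "I_s", lower = 0)
  structure(list(T_air = T_air, RH_air = RH_air, T_reflect = T_reflect,
                 P_atm = P_atm, I_s = I_s),
            class = "env_state")
}

#' Optical properties of a sample surface
#'
#' @param alpha short-wave absorptance (fraction of incident short-wave
#'   radiation absorbed).
#' @param epsilon long-wave emissivity.
#' @param strict enforce the physical range \[0, 1\]. Sensitivity analyses
#'   perturb measured values by +/-10\% which can push absorptance slightly
#'   above 1; `perturb_inputs()` constructs such states with `strict = FALSE`.
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(alpha = 0.98, epsilon = 0.96)
#' @export
optical_properties <- function(alpha, epsilon, strict = TRUE) {
  if (strict) {
    check_scalar(alpha, "alpha", 0, 1)
    check_scalar(epsilon, "epsilon", 0, 1)
  } else {
    check_scalar(alpha, "alpha", 0, 1.5)
    check_scalar(epsilon, "epsilon", 0, 1.5)
  }
  structure(list(alpha = alpha, epsilon = epsilon),
            class = "optical_properties")
}

#' Boundary-layer and stomatal conductances
#'
#' Stores the boundary-layer conductance to heat `g_bh` and the stomatal
#' conductance to water vapour `g_sw` (both in m s-1) and derives the
#' boundary-layer conductance to water vapour from the laminar-flow relation
#' g_bh = 0.92 g_bw, i.e. `g_bw = g_bh / 0.92`.
#'
#' @param g_bh boundary-layer conductance to heat (m s-1).
#' @param g_sw stomatal conductance to water vapour (m s-1); 0 for a
#'   non-transpiring sample such as an aluminum plate.
#' @return An object of class `conductances` with fields `g_bh`, `g_sw`,
#'   `g_bw`.
#' @examples
#' conductances(g_bh = 0.01, g_sw = 0.002)
#' @export
conductances <- function(g_bh, g_sw = 0) {
  check_scalar(g_bh, "g_bh", lower = 0)
  check_scalar(g_sw, "g_sw", lower = 0)
  structure(list(g_bh = g_bh, g_sw = g_sw, g_bw = g_bh / 0.92),
            class = "conductances")
}

#' Light protocol: piecewise-constant irradiance segments
#'
#' @param t_start,t_end segment boundaries (s); segments must be contiguous
#'   and non-overlapping.
#' @param I_s irradiance per segment (W m-2).
#' @return An object of class `light_protocol` (a data frame with columns
#'   `t_start`, `t_end`, `I_s`).
#' @seealso [pulse_protocol()] for the standard baseline/pulse/dark layout.
#' @examples
#' light_protocol(c(0, 10, 20), c(10, 20, 130), c(0, 270, 0))
#' @export
light_protocol <- function(t_start, t_end, I_s) {
  if (!(length(t_start) == length(t_end) &&
        length(t_end) == length(I_s)) || length(t_start) < 1L)
    stop("t_start, t_end, I_s must have equal positive length", call. = FALSE)
  if (any(!is.finite(t_start)) || any(!is.finite(t_end)) ||
      any(!is.finite(I_s)))
    stop("protocol values must be finite", call. = FALSE)
  if (any(t_end <= t_start))
    stop("each segment needs t_start < t_end", call. = FALSE)
  if (any(I_s < 0)) stop("I_s must be >= 0", call. = FALSE)
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; I_s <- I_s[o]
  if (length(t_start) > 1L &&
      any(abs(t_start[-1] - t_end[-length(t_end)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping", call. = FALSE)
  structure(data.frame(t_start = t_start, t_end = t_end, I_s = I_s),
            class = c("light_protocol", "data.frame"))
}

#' Baseline / pulse / dark light protocol
#'
#' Convenience constructor for the standard measurement protocol: a dark
#' baseline, a light pulse, and a dark recovery period. The default pulse is
#' 10 s at 270 W m-2 followed by 110 s darkness, the protocol used on leaves;
#' the aluminum validation protocol used a 60 s pulse and 540 s darkness.
#'
#' @param baseline_s dark baseline duration before the pulse (s).
#' @param pulse_s pulse duration (s).
#' @param dark_s dark period after the pulse (s).
#' @param irradiance pulse irradiance (W m-2).
#' @return A [light_protocol()].
#' @examples
#' pulse_protocol()                      # leaf protocol
#' pulse_protocol(pulse_s = 60, dark_s = 540)  # aluminum-plate protocol
#' @export
pulse_protocol <- function(baseline_s = 10, pulse_s = 10, dark_s = 110,
                           irradiance = 270) {
  check_scalar(baseline_s, "baseline_s", lower = 0)
  check_scalar(pulse_s, "pulse_s", lower = 1e-9)
  check_scalar(dark_s, "dark_s", lower = 1e-9)
  check_scalar(irradiance, "irradiance", lower = 0)
  if (baseline_s > 0) {
    light_protocol(c(0, baseline_s, baseline_s + pulse_s),
                   c(baseline_s, baseline_s + pulse_s,
                     baseline_s + pulse_s + dark_s),
                   c(0, irradiance, 0))
  } else {
    light_protocol(c(0, pulse_s), c(pulse_s, pulse_s + dark_s),
                   c(irradiance, 0))
  }
}

#' Pulse on/off times of a protocol
#'
#' @param protocol a [light_protocol()].
#' @return Numeric vector `c(t_on, t_off)` of the first lit segment.
#' @export
pulse_window <- function(protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  lit <- which(protocol$I_s > 0)
  if (length(lit) == 0L) stop("protocol has no lit segment", call. = FALSE)
  c(t_on = protocol$t_start[lit[1]], t_off = protocol$t_end[lit[1]])
}

#' Time-resolved environment trace
#'
#' Environmental drivers sampled over time (in practice every ~5 s). Values
#' are interpolated piecewise-linearly between samples and held constant
#' beyond the recorded range. Scalars are recycled, so a constant environment
#' is `environment_trace(0, T_air, RH_air, T_reflect)`.
#'
#' @param times sample times (s), strictly increasing.
#' @param T_air,RH_air,T_reflect drivers at those times (K, fraction, K);
#'   scalars are recycled.
#' @param P_atm atmospheric pressure (Pa), a single value.
#' @return An object of class `environment_trace`.
#' @examples
#' environment_trace(0, T_air = 293.15, RH_air = 0.5)
#' @export
environment_trace <- function(times, T_air, RH_air, T_reflect = T_air,
                              P_atm = 101325) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("`times` must be finite numeric", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  n <- length(times)
  rec <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n)
      stop("`", name, "` must have length 1 or length(times)", call. = FALSE)
    x
  }
  T_air <- rec(T_air, "T_air"); RH_air <- rec(RH_air, "RH_air")
  T_reflect <- rec(T_reflect, "T_reflect")
  check_temperature(T_air, "T_air"); check_temperature(T_reflect, "T_reflect")
  if (any(RH_air < 0 | RH_air > 1))
    stop("`RH_air` must be a fraction in [0, 1]", call. = FALSE)
  check_scalar(P_atm, "P_atm", lower = 1e-12)
  structure(list(times = times, T_air = T_air, RH_air = RH_air,
                 T_reflect = T_reflect, P_atm = P_atm),
            class = "environment_trace")
}

#' Coerce to an environment trace
#'
#' @param x an `environment_trace` (returned unchanged) or an [env_state()]
#'   (interpreted as constant in time).
#' @return An `environment_trace`.
#' @export
as_environment_trace <- function(x) {
  if (inherits(x, "environment_trace")) return(x)
  if (inherits(x, "env_state"))
    return(environment_trace(0, x$T_air, x$RH_air, x$T_reflect, x$P_atm))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to an environment_trace", call. = FALSE)
}

#' Environment state at a given time
#'
#' Piecewise-linear interpolation inside the recorded range, constant
#' extrapolation outside. Irradiance comes from the light protocol, not the
#' environment trace, so `I_s` must be supplied separately (default 0).
#'
#' @param env an `environment_trace` (or `env_state`).
#' @param t time (s).
#' @param I_s irradiance at `t` (W m-2).
#' @return An [env_state()].
#' @export
env_at <- function(env, t, I_s = 0) {
  env <- as_environment_trace(env)
  ip <- function(y) {
    if (length(env$times) == 1L) return(y[1])
    stats::approx(env$times, y, xout = t, rule = 2)$y
  }
  env_state(T_air = ip(env$T_air), RH_air = ip(env$RH_air),
            T_reflect = ip(env$T_reflect), P_atm = env$P_atm, I_s = I_s)
}

#' Irradiance prescribed by a protocol at a given time
#'
#' @param protocol a [light_protocol()].
#' @param t time (s); vectorized.
#' @return Irradiance (W m-2); 0 outside all segments.
#' @export
protocol_irradiance <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"))
  vapply(t, function(ti) {
    hit <- which(ti >= protocol$t_start & ti < protocol$t_end)
    if (length(hit)) protocol$I_s[hit[1]] else 0
  }, numeric(1))
}

#' Sampled object-temperature trace
#'
#' @param times times (s), strictly increasing.
#' @param T object temperature (K).
#' @param sample_rate_hz nominal sampling rate; inferred from `times` when
#'   omitted.
#' @return An object of class `thermal_trace`.
#' @examples
#' thermal_trace(seq(0, 1, by = 0.04), rep(293.15, 26))
#' @export
thermal_trace <- function(times, T, sample_rate_hz = NULL) {
  if (!is.numeric(times) || !is.numeric(T) || length(times) != length(T))
    stop("`times` and `T` must be numeric vectors of equal length",
         call. = FALSE)
  if (length(times) < 2L)
    stop("a thermal trace needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(T)))
    stop("trace values must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  check_temperature(T, "T")
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1 / stats::median(diff(times))
  structure(list(times = times, T = T, sample_rate_hz = sample_rate_hz),
            class = "thermal_trace")
}

#' @export
print.thermal_trace <- function(x, ...) {
  cat("<thermal_trace> ", length(x$times), " samples, ",
      format(round(x$sample_rate_hz, 2)), " Hz, t = [",
      format(min(x$times)), ", ", format(max(x$times)), "] s, T = [",
      format(round(min(x$T), 3)), ", ", format(round(max(x$T), 3)), "] K\n",
      sep = "")
  invisible(x)
}

#' @export
plot.thermal_trace <- function(x, ..., celsius = TRUE) {
  y <- if (celsius) x$T - 273.15 else x$T
  graphics::plot(x$times, y, type = "l", xlab = "time (s)",
                 ylab = if (celsius) "temperature (°C)"
                        else "temperature (K)", ...)
  invisible(x)
}

#' Decimate a thermal trace to a lower sampling rate
#'
#' Keeps every n-th sample so that the nominal rate does not exceed
#' `target_hz`. Fitting at 5 Hz instead of the camera's 25 Hz changes the
#' posterior very little but cuts the likelihood cost five-fold.
#'
#' @param trace a [thermal_trace()].
#' @param target_hz desired maximum rate (Hz).
#' @return A [thermal_trace()].
#' @export
decimate_trace <- function(trace, target_hz) {
  stopifnot(inherits(trace, "thermal_trace"))
  check_scalar(target_hz, "target_hz", lower = 1e-9)
  by <- max(1L, as.integer(round(trace$sample_rate_hz / target_hz)))
  if (by == 1L) return(trace)
  idx <- seq(1L, length(trace$times), by = by)
  thermal_trace(trace$times[idx], trace$T[idx],
                sample_rate_hz = trace$sample_rate_hz / by)
}

#' Physical and optical properties of a measured sample
#'
#' Geometry and optics of a leaf (or reference plate). Mass per unit area --
#' the product leaf density x thickness -- is taken as fresh weight divided by
#' one-sided leaf area, or as `lt * rho` when thickness and density are known
#' (e.g. the aluminum plate). Inputs use the bench units of a trait table:
#' grams and cm2; stored values are SI.
#'
#' @param FW_g fresh weight (g).
#' @param area_cm2 one-sided area (cm2).
#' @param DW_g dry weight (g), optional.
#' @param lt_m thickness (m), optional.
#' @param rho density (kg m-3), optional.
#' @param alpha,epsilon optional short-wave absorptance and long-wave
#'   emissivity; when given, an `optical_properties` object is attached.
#' @return An object of class `sample_properties` with SI fields `FW_kg`,
#'   `DW_kg`, `area_m2`, `lt_m`, `rho`, `mass_per_area` (kg m-2) and `optics`.
#' @examples
#' sample_properties(FW_g = 0.428, area_cm2 = 17.348, DW_g = 0.049,
#'                   alpha = 0.901, epsilon = 0.986)
#' @export
sample_properties <- function(FW_g = NA, area_cm2 = NA, DW_g = NA, lt_m = NA,
                              rho = NA, alpha = NA, epsilon = NA) {
  check_scalar(FW_g, "FW_g", lower = 1e-12, allow_na = TRUE)
  check_scalar(area_cm2, "area_cm2", lower = 1e-12, allow_na = TRUE)
  check_scalar(DW_g, "DW_g", lower = 0, allow_na = TRUE)
  check_scalar(lt_m, "lt_m", lower = 1e-12, allow_na = TRUE)
  check_scalar(rho, "rho", lower = 1e-12, allow_na = TRUE)
  if (!is.na(DW_g) && !is.na(FW_g) && DW_g > FW_g)
    stop("dry weight cannot exceed fresh weight", call. = FALSE)
  mpa_fw <- if (!is.na(FW_g) && !is.na(area_cm2))
    (FW_g / 1000) / (area_cm2 / 1e4) else NA_real_
  mpa_lt <- if (!is.na(lt_m) && !is.na(rho)) lt_m * rho else NA_real_
  if (!is.na(mpa_fw) && !is.na(mpa_lt) &&
      abs(mpa_fw - mpa_lt) > 0.05 * max(mpa_fw, mpa_lt))
    warning("FW/area and lt*rho disagree by more than 5%; using FW/area")
  mass_per_area <- if (!is.na(mpa_fw)) mpa_fw else mpa_lt
  optics <- if (!is.na(alpha) && !is.na(epsilon))
    optical_properties(alpha, epsilon) else NULL
  structure(list(FW_kg = FW_g / 1000, DW_kg = DW_g / 1000,
                 area_m2 = area_cm2 / 1e4, lt_m = lt_m, rho = rho,
                 mass_per_area = mass_per_area, optics = optics),
            class = "sample_properties")
}

protocol_matrix <- function(protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  cbind(protocol$t_start, protocol$t_end, protocol$I_s)
}

env_matrix <- function(env) {
  env <- as_environment_trace(env)
  cbind(env$times, env$T_air, env$RH_air, env$T_reflect)
}
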