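# Trace CSV conventions: long files have columns (time_s, value); wide files
# have time_s plus any of T_leaf_C, T_air_C, RH_pct, T_reflect_C.
# Temperatures on disk are degC and humidities percent; in memory everything
# is K and fractional.

read_numeric_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df))
    stop(path, ": missing required column `time_s`", call. = FALSE)
  for (nm in names(df)) {
    suppressWarnings(v <- as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]) & df[[nm]] != "")
    if (length(bad))
      stop(path, ": non-numeric value in column `", nm, "` at data line ",
           bad[1], call. = FALSE)
    df[[nm]] <- v
  }
  if (anyNA(df$time_s))
    stop(path, ": missing time at data line ", which(is.na(df$time_s))[1],
         call. = FALSE)
  d <- diff(df$time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop(path, ": time not strictly increasing at data line ", i + 1L,
         if (d[i] == 0) " (duplicated timestamp)" else "", call. = FALSE)
  }
  df
}

#' Read a trace CSV
#'
#' Reads either a long file (`time_s`, `value`) holding a single channel, or a
#' wide file (`time_s` plus any of `T_leaf_C`, `T_air_C`, `RH_pct`,
#' `T_reflect_C`). Disk units (degC, \%) are converted to internal units (K,
#' fraction) on read. Malformed rows, missing columns and non-monotone
#' timestamps raise errors naming the offending line.
#'
#' @param path CSV file path.
#' @param channel for long files: one of `"T_leaf"`, `"T_air"`, `"RH"`,
#'   `"T_reflect"`; the value column is interpreted as degC (or \% for RH).
#' @param P_atm atmospheric pressure (Pa) attached to environment traces.
#' @return For a wide file: a list with a [thermal_trace()] in `$trace` (when
#'   `T_leaf_C` is present) and an [environment_trace()] in `$env` (when the
#'   environment channels are present). For a long file: a [thermal_trace()]
#'   (temperature channels) or a data frame (`RH`).
#' @export
read_trace_csv <- function(path, channel = NULL, P_atm = 101325) {
  df <- read_numeric_csv(path)
  if ("value" %in% names(df)) {
    if (is.null(channel))
      stop("long-format file: supply `channel` (T_leaf, T_air, RH, ",
           "T_reflect)", call. = FALSE)
    channel <- match.arg(channel, c("T_leaf", "T_air", "RH", "T_reflect"))
    if (channel == "RH")
      return(data.frame(time_s = df$time_s, RH = df$value / 100))
    return(thermal_trace(df$time_s, df$value + 273.15))
  }
  out <- list()
  if ("T_leaf_C" %in% names(df))
    out$trace <- thermal_trace(df$time_s, df$T_leaf_C + 273.15)
  env_cols <- c("T_air_C", "RH_pct", "T_reflect_C")
  if (any(env_cols %in% names(df))) {
    miss <- setdiff(c("T_air_C", "RH_pct"), names(df))
    if (length(miss))
      stop(path, ": environment channels present but missing ",
           paste(miss, collapse = ", "), call. = FALSE)
    tr <- if ("T_reflect_C" %in% names(df)) df$T_reflect_C else df$T_air_C
    out$env <- environment_trace(df$time_s, df$T_air_C + 273.15,
                                 df$RH_pct / 100, tr + 273.15, P_atm)
  }
  if (length(out) == 0L)
    stop(path, ": no recognized channels (expected `value` or any of ",
         "T_leaf_C, T_air_C, RH_pct, T_reflect_C)", call. = FALSE)
  if (length(out) == 1L) out[[1]] else out
}

#' Write traces to CSV
#'
#' Inverse of [read_trace_csv()]: internal units (K, fraction) are converted
#' to disk units (degC, \%). When both a thermal trace and an environment
#' trace are given they must share time stamps and are written as one wide
#' file.
#'
#' @param path output CSV path.
#' @param trace optional [thermal_trace()].
#' @param env optional [environment_trace()].
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(path, trace = NULL, env = NULL) {
  if (is.null(trace) && is.null(env))
    stop("nothing to write", call. = FALSE)
  if (!is.null(env)) env <- as_environment_trace(env)
  times <- if (!is.null(trace)) trace$times else env$times
  df <- data.frame(time_s = times)
  if (!is.null(trace)) df$T_leaf_C <- trace$T - 273.15
  if (!is.null(env)) {
    ip <- function(y) if (length(env$times) == 1L) rep(y, length(times))
      else stats::approx(env$times, y, xout = times, rule = 2)$y
    df$T_air_C <- ip(env$T_air) - 273.15
    df$RH_pct <- ip(env$RH_air) * 100
    df$T_reflect_C <- ip(env$T_reflect) - 273.15
  }
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(format(df, digits = 15, scientific = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1,
    trace_csv = NULL,
    sample = list(FW_g = NA, DW_g = NA, area_cm2 = NA, lt_m = NA, rho = NA,
                  alpha = NA, epsilon = NA),
    environment = list(T_air_C = 20, RH_pct = 50, T_reflect_C = NA,
                       P_atm = 101325),
    protocol = list(baseline_s = 10, pulse_s = 10, dark_s = 110,
                    irradiance = 270),
    priors = list(k_sd = 5000, g_bh_sd = 0.005, g_sw_sd = 0.005,
                  sigma_sd = 0.5),
    mcmc = list(chains = 4, iterations = 1000, warmup = 500),
    physics = list(C_s = 1010, lambda = 2.45e6, es_formula = "tetens"),
    truth = list(k = 900, g_bh = 0.01, g_sw = 0.002),
    noise_sd = 0.05,
    decimate_hz = 5,
    fix_g_sw = FALSE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a run configuration
#'
#' Configurations are JSON. Every omitted field falls back to a documented
#' default and the *effective* configuration (defaults included) is echoed
#' into every output report, so no assumed constant stays silent. Unknown
#' top-level fields are rejected.
#'
#' @param path JSON file path, or `NULL` for the defaults.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg$protocol, {
    stopifnot(pulse_s > 0, dark_s > 0, baseline_s >= 0, irradiance >= 0)
  })
  stopifnot(cfg$mcmc$chains >= 1,
            cfg$mcmc$iterations > cfg$mcmc$warmup,
            cfg$noise_sd >= 0, cfg$decimate_hz > 0)
  if (!is.na(cfg$environment$RH_pct))
    stopifnot(cfg$environment$RH_pct >= 0, cfg$environment$RH_pct <= 100)
  structure(cfg, class = c("run_config", "list"))
}

config_objects <- function(cfg) {
  env <- env_state(
    T_air = cfg$environment$T_air_C + 273.15,
    RH_air = cfg$environment$RH_pct / 100,
    T_reflect = if (is.na(cfg$environment$T_reflect_C))
      cfg$environment$T_air_C + 273.15
      else cfg$environment$T_reflect_C + 273.15,
    P_atm = cfg$environment$P_atm)
  protocol <- pulse_protocol(cfg$protocol$baseline_s, cfg$protocol$pulse_s,
                             cfg$protocol$dark_s, cfg$protocol$irradiance)
  s <- cfg$sample
  sample <- sample_properties(FW_g = s$FW_g, area_cm2 = s$area_cm2,
                              DW_g = s$DW_g, lt_m = s$lt_m, rho = s$rho,
                              alpha = s$alpha, epsilon = s$epsilon)
  optics <- sample$optics
  priors <- do.call(prior_spec, cfg$priors)
  control <- mcmc_control(cfg$mcmc$chains, cfg$mcmc$iterations,
                          cfg$mcmc$warmup, seed = cfg$seed)
  const <- do.call(physics_constants, cfg$physics)
  list(env = env, protocol = protocol, sample = sample, optics = optics,
       priors = priors, control = control, const = const)
}

#' Serialize a fit as a JSON report
#'
#' Writes parameter summaries, convergence diagnostics, RMSE, the C_p
#' summary (when available) and the full effective configuration/seed echo.
#'
#' @param fit a `cp_fit`.
#' @param path output JSON path.
#' @param config optional `run_config` to echo.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, config = NULL) {
  stopifnot(inherits(fit, "cp_fit"))
  report <- list(
    posterior = fit$summary,
    rmse_K = fit$rmse,
    converged = fit$converged,
    accept_rate = fit$accept_rate,
    n_obs = length(fit$trace$times),
    T0_K = fit$T0,
    fix_g_sw = fit$fix_g_sw,
    mcmc = unclass(fit$control),
    priors = unclass(fit$priors),
    physics = unclass(fit$const),
    cp = if (!is.null(fit$cp))
      list(mean = fit$cp$mean, sd = fit$cp$sd, ci = fit$cp$ci,
           mass_per_area = fit$cp$mass_per_area) else NULL,
    config = if (!is.null(config)) unclass(config) else NULL
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a sensitivity table to CSV and JSON
#'
#' @param x a `cp_sensitivity` table.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return The table, invisibly.
#' @export
write_sensitivity <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "cp_sensitivity"))
  df <- as.data.frame(x)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(baseline_cp = attr(x, "baseline_cp"),
                              rel_change = attr(x, "rel_change"),
                              table = df),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(x)
}
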