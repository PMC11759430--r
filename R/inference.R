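#' Prior specification for the transient fit
#'
#' All parameters carry half-normal priors (mean 0, truncated to positive
#' values, as physics requires). The conductance scales (sd 0.005 m s-1 for
#' both `g_sw` and `g_bh`) are the broadly chosen priors of the method; the
#' areal-heat-capacity and noise scales are weakly informative defaults wide
#' enough to cover reference plates (~3000 J m-2 K-1) and leaves
#' (~200-25000 J m-2 K-1).
#'
#' @param k_sd prior sd of k (J m-2 K-1).
#' @param g_bh_sd prior sd of g_bh (m s-1).
#' @param g_sw_sd prior sd of g_sw (m s-1).
#' @param sigma_sd prior sd of the residual noise sigma_obs (K).
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(k_sd = 5000, g_bh_sd = 0.005, g_sw_sd = 0.005,
                       sigma_sd = 0.5) {
  for (nm in c("k_sd", "g_bh_sd", "g_sw_sd", "sigma_sd"))
    check_scalar(get(nm), nm, lower = 1e-12)
  structure(list(k_sd = k_sd, g_bh_sd = g_bh_sd, g_sw_sd = g_sw_sd,
                 sigma_sd = sigma_sd),
            class = "prior_spec")
}

#' MCMC sampler settings
#'
#' Defaults follow the reference procedure: four chains of 1000 iterations
#' with 500 warmup. The sampler is an adaptive random-walk Metropolis on
#' log-parameters (proposal covariance and scale adapted during warmup only);
#' being less efficient per iteration than Hamiltonian samplers, it may need
#' more iterations to clear the ESS > 200 bar — increase `iterations` rather
#' than loosening the diagnostics.
#'
#' @param chains number of independent chains.
#' @param iterations total iterations per chain (including warmup).
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param seed optional integer seed.
#' @param target_accept target acceptance rate of the scale adaptation.
#' @return An object of class `mcmc_control`.
#' @examples
#' mcmc_control(seed = 1)
#' @export
mcmc_control <- function(chains = 4, iterations = 1000, warmup = 500,
                         seed = NULL, target_accept = 0.3) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 50,
            target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = seed,
                 target_accept = target_accept),
            class = "mcmc_control")
}

half_normal_lpdf <- function(x, sd) {
  if (x < 0) return(-Inf)
  stats::dnorm(x, 0, sd, log = TRUE) + log(2)
}

# Model prediction at the observation times; NULL on integration failure.
predict_trace <- function(params, trace, protocol, env, optics, T0,
                          const = physics_constants(), rtol = 1e-8,
                          atol = 1e-8) {
  env <- as_environment_trace(env)
  tryCatch(
    integrate_eb_cpp(T0, trace$times, protocol_matrix(protocol),
                     env_matrix(env), env$P_atm, optics$alpha,
                     optics$epsilon, params[["g_bh"]], params[["g_sw"]],
                     params[["k"]], const$C_s, const$lambda,
                     es_formula_code(const), rtol, atol),
    error = function(e) NULL)
}

default_T0 <- function(trace, protocol) {
  t_on <- tryCatch(pulse_window(protocol)[["t_on"]], error = function(e) Inf)
  pre <- trace$times < t_on - 1e-9
  if (sum(pre) >= 3L) mean(trace$T[pre]) else trace$T[1]
}

#' Log-posterior density of the transient model
#'
#' Gaussian likelihood of the observed temperatures around the integrated
#' model trajectory (`sigma_obs` residual sd) plus independent half-normal
#' log-priors on `k`, `g_bh`, `g_sw` and `sigma_obs`. Returns `-Inf` outside
#' the support (any non-positive `k` or `sigma_obs`, negative conductance) and
#' on integration failure.
#'
#' @param params named numeric vector with elements `k`, `g_bh`, `g_sw`,
#'   `sigma_obs`.
#' @param trace observed [thermal_trace()].
#' @param protocol a [light_protocol()].
#' @param env an [environment_trace()] or [env_state()].
#' @param optics an [optical_properties()].
#' @param priors a [prior_spec()].
#' @param T0 initial model temperature (K); default: mean of the pre-pulse
#'   observations.
#' @param fix_g_sw if `TRUE`, `g_sw` is pinned to 0 (dry reference plate) and
#'   excluded from the prior.
#' @param const a [physics_constants()].
#' @return Log-posterior density (scalar).
#' @export
log_posterior <- function(params, trace, protocol, env, optics,
                          priors = prior_spec(), T0 = NULL,
                          fix_g_sw = FALSE, const = physics_constants()) {
  stopifnot(inherits(trace, "thermal_trace"))
  p <- as.list(params)
  if (fix_g_sw) p$g_sw <- 0
  for (nm in c("k", "g_bh", "g_sw", "sigma_obs"))
    if (is.null(p[[nm]]) || !is.finite(p[[nm]]))
      stop("`params` must contain finite ", nm, call. = FALSE)
  if (p$k <= 0 || p$sigma_obs <= 0 || p$g_bh < 0 || p$g_sw < 0)
    return(-Inf)
  lp <- half_normal_lpdf(p$k, priors$k_sd) +
    half_normal_lpdf(p$g_bh, priors$g_bh_sd) +
    half_normal_lpdf(p$sigma_obs, priors$sigma_sd)
  if (!fix_g_sw) lp <- lp + half_normal_lpdf(p$g_sw, priors$g_sw_sd)
  if (!is.finite(lp)) return(-Inf)
  if (is.null(T0)) T0 <- default_T0(trace, protocol)
  pred <- predict_trace(list(k = p$k, g_bh = p$g_bh, g_sw = p$g_sw),
                        trace, protocol, env, optics, T0, const)
  if (is.null(pred)) {
    warning("energy-balance integration failed; log-posterior set to -Inf")
    return(-Inf)
  }
  lp + sum(stats::dnorm(trace$T - pred, 0, p$sigma_obs, log = TRUE))
}

#' Root mean squared error between observed and predicted traces
#'
#' @param observed a [thermal_trace()] or numeric vector.
#' @param predicted a [thermal_trace()] or numeric vector on the same times.
#' @return RMSE (K).
#' @examples
#' fit_rmse(c(1, 2, 3), c(1.1, 2.1, 3.1))  # 0.1
#' @export
fit_rmse <- function(observed, predicted) {
  obs <- if (inherits(observed, "thermal_trace")) observed$T else observed
  pre <- if (inherits(predicted, "thermal_trace")) predicted$T else predicted
  if (length(obs) != length(pre))
    stop("observed and predicted lengths differ (", length(obs), " vs ",
         length(pre), ")", call. = FALSE)
  if (inherits(observed, "thermal_trace") &&
      inherits(predicted, "thermal_trace") &&
      max(abs(observed$times - predicted$times)) > 1e-6)
    stop("observed and predicted traces are not aligned in time",
         call. = FALSE)
  sqrt(mean((obs - pre)^2))
}

#' Specific heat capacity from posterior draws of k
#'
#' Divides each posterior draw of the areal heat capacity k by the fresh mass
#' per unit area (= thickness x density = fresh weight / leaf area), so the
#' C_p summary inherits the full posterior uncertainty of k.
#'
#' @param k_draws numeric vector of posterior draws of k (J m-2 K-1).
#' @param mass_per_area fresh mass per unit area (kg m-2).
#' @return A list of class `cp_summary`: `draws`, `mean`, `sd`, `ci` (95\%
#'   equal-tailed).
#' @examples
#' derive_cp(rnorm(100, 2968, 20), mass_per_area = 0.001335 * 2484)
#' @export
derive_cp <- function(k_draws, mass_per_area) {
  check_scalar(mass_per_area, "mass_per_area", lower = 1e-12)
  if (!is.numeric(k_draws) || length(k_draws) < 1L)
    stop("`k_draws` must be a non-empty numeric vector", call. = FALSE)
  draws <- k_draws / mass_per_area
  structure(list(draws = draws, mean = mean(draws), sd = stats::sd(draws),
                 ci = unname(stats::quantile(draws, c(0.025, 0.975))),
                 mass_per_area = mass_per_area),
            class = "cp_summary")
}

#' @export
print.cp_summary <- function(x, ...) {
  cat("C_p = ", format(round(x$mean, 1)), " J kg-1 K-1 (95% CI ",
      format(round(x$ci[1], 1)), " - ", format(round(x$ci[2], 1)),
      "), mass per area = ", format(x$mass_per_area), " kg m-2\n", sep = "")
  invisible(x)
}

# Heuristic starting point: k from the onset slope alpha*I/slope, g_bh from
# the post-pulse decay time constant, g_sw from the dark equilibrium offset,
# sigma from the high-frequency noise.
init_from_trace <- function(trace, protocol, env, optics, fix_g_sw,
                            const = physics_constants()) {
  pw <- tryCatch(pulse_window(protocol), error = function(e) NULL)
  if (is.null(pw))  # dark protocol: nothing to initialize from
    pw <- c(t_on = trace$times[1],
            t_off = trace$times[1] + diff(range(trace$times)) / 2)
  e0 <- env_at(env, pw[["t_on"]], I_s = 0)
  I_pulse <- max(protocol$I_s)
  slope <- tryCatch(heating_slope(trace, pw), error = function(e) NA_real_)
  k0 <- if (is.finite(slope) && slope > 1e-4)
    optics$alpha * I_pulse / slope else 1000
  k0 <- min(max(k0, 10), 5e4)

  # decay time constant from the post-pulse relaxation
  post <- trace$times > pw[["t_off"]]
  tau <- NA_real_
  if (sum(post) > 10L) {
    tt <- trace$times[post]; TT <- trace$T[post]
    T_inf <- mean(TT[tt >= stats::quantile(tt, 0.9)])
    amp <- TT - T_inf
    use <- amp > max(0.1, 0.05 * max(amp))
    if (sum(use) > 5L) {
      cf <- stats::coef(stats::lm(log(amp[use]) ~ tt[use]))
      if (is.finite(cf[2]) && cf[2] < 0) tau <- -1 / cf[2]
    }
  }
  rho_air <- e0$P_atm / (const$R_dry_air * e0$T_air)
  rad <- 8 * optics$epsilon * physics_constants()$sigma_sb * e0$T_air^3
  g_bh0 <- if (is.finite(tau) && tau > 0)
    max((k0 / tau - rad) / (2 * rho_air * const$C_s), 5e-4) else 0.01
  g_bh0 <- min(g_bh0, 0.05)

  g_sw0 <- 1e-4
  if (!fix_g_sw) {
    # dark equilibrium offset below air temperature -> latent flux estimate
    pre <- trace$times < pw[["t_on"]]
    T_dark <- if (sum(pre) >= 3L) mean(trace$T[pre]) else trace$T[1]
    dT <- e0$T_air - T_dark
    if (dT > 0.05) {
      psy <- psychrometric_state(T_dark, e0, const)
      LW <- 2 * optics$epsilon * physics_constants()$sigma_sb *
        (e0$T_reflect^4 - T_dark^4)
      H <- 2 * rho_air * const$C_s * g_bh0 * (T_dark - e0$T_air)
      gtw <- (LW - H) * e0$P_atm /
        (2 * const$lambda * 0.622 * rho_air * max(psy$VPD, 1))
      if (is.finite(gtw) && gtw > 0 && gtw < g_bh0 / 0.92) {
        g_sw0 <- 1 / (1 / gtw - 0.92 / g_bh0)
      } else if (is.finite(gtw) && gtw > 0) {
        g_sw0 <- 0.005
      }
    }
    g_sw0 <- min(max(g_sw0, 1e-5), 0.02)
  }
  sigma0 <- max(stats::sd(diff(trace$T)) / sqrt(2), 1e-3)
  list(k = k0, g_bh = g_bh0, g_sw = g_sw0, sigma_obs = sigma0)
}

# Adaptive random-walk Metropolis on the log scale. Returns kept draws
# (natural scale) as a matrix and the acceptance rate.
run_chain <- function(lp_log, theta0, iterations, warmup, target_accept) {
  d <- length(theta0)
  draws <- matrix(NA_real_, iterations, d)
  theta <- theta0
  lp_cur <- lp_log(theta)
  if (!is.finite(lp_cur))
    stop("non-finite log-posterior at the initial point", call. = FALSE)
  log_lambda <- log(2.38^2 / d)
  C <- diag(0.01, d)
  L <- chol(C)
  n_acc <- 0L
  for (i in seq_len(iterations)) {
    prop <- theta + sqrt(exp(log_lambda)) * drop(crossprod(L, stats::rnorm(d)))
    lp_prop <- lp_log(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
      theta <- prop; lp_cur <- lp_prop; acc <- 1
    } else acc <- 0
    n_acc <- n_acc + acc
    draws[i, ] <- theta
    if (i <= warmup) {
      log_lambda <- log_lambda + (acc - target_accept) / max(i^0.6, 1)
      if (i >= 100L && i %% 25L == 0L) {
        Cnew <- stats::cov(draws[max(1L, i - 400L):i, , drop = FALSE]) +
          diag(1e-8, d)
        Lnew <- tryCatch(chol(Cnew), error = function(e) NULL)
        if (!is.null(Lnew)) { C <- Cnew; L <- Lnew }
      }
    }
  }
  list(draws = draws[(warmup + 1L):iterations, , drop = FALSE],
       accept_rate = n_acc / iterations)
}

#' Fit the energy-balance model to an observed temperature transient
#'
#' Bayesian inversion of a temperature transient recorded during and after a
#' light pulse. The sampler explores (k, g_bh, g_sw, sigma_obs) — or
#' (k, g_bh, sigma_obs) for a dry reference plate with `fix_g_sw = TRUE` —
#' under half-normal priors, with a Gaussian likelihood comparing the
#' integrated model temperature to the observations. Chains are initialized
#' from heuristics (onset slope, decay time constant, dark equilibrium
#' offset) with per-chain jitter. The fit is flagged non-converged unless all
#' free parameters reach R-hat < 1.01 and bulk ESS > 200.
#'
#' @param trace observed [thermal_trace()] spanning the pulse and the
#'   post-pulse decay.
#' @param protocol a [light_protocol()] aligned with the trace clock.
#' @param env an [environment_trace()] or [env_state()].
#' @param optics an [optical_properties()]; taken from `sample` when omitted.
#' @param sample optional [sample_properties()]; when it carries a mass per
#'   area, the posterior of C_p = k / mass_per_area is reported.
#' @param priors a [prior_spec()].
#' @param control an [mcmc_control()].
#' @param fix_g_sw pin g_sw to 0 (aluminum-plate mode).
#' @param decimate_hz decimate the trace to at most this rate before fitting
#'   (default 5 Hz); `Inf` fits the full-rate trace.
#' @param T0 initial model temperature (K); default: mean of pre-pulse
#'   observations.
#' @param const a [physics_constants()].
#' @return An object of class `cp_fit`; see [summary.cp_fit()].
#' @examples
#' \donttest{
#' fx <- leaf_fixture(seed = 1, rate_hz = 5)
#' fit <- fit_transient(fx$trace, fx$protocol, fx$env, fx$optics,
#'                      sample = fx$sample,
#'                      control = mcmc_control(chains = 2, iterations = 400,
#'                                             warmup = 200, seed = 1))
#' }
#' @export
fit_transient <- function(trace, protocol, env, optics = NULL, sample = NULL,
                          priors = prior_spec(), control = mcmc_control(),
                          fix_g_sw = FALSE, decimate_hz = 5, T0 = NULL,
                          const = physics_constants()) {
  stopifnot(inherits(trace, "thermal_trace"),
            inherits(protocol, "light_protocol"),
            inherits(priors, "prior_spec"),
            inherits(control, "mcmc_control"))
  if (is.null(optics)) {
    if (!is.null(sample) && !is.null(sample$optics)) optics <- sample$optics
    else stop("supply `optics` or a `sample` carrying optical properties",
              call. = FALSE)
  }
  env <- as_environment_trace(env)
  pw <- tryCatch(pulse_window(protocol), error = function(e) NULL)
  if (is.null(pw))
    warning("protocol has no lit segment: k is not identifiable from a ",
            "dark trace")
  else if (max(trace$times) < pw[["t_off"]] + 30)
    warning("trace ends less than 30 s after the pulse; ",
            "conductances may be poorly identified")
  fit_trace <- if (is.finite(decimate_hz)) decimate_trace(trace, decimate_hz)
               else trace
  if (is.null(T0)) T0 <- default_T0(fit_trace, protocol)

  if (!is.null(control$seed)) set.seed(control$seed)
  init <- init_from_trace(fit_trace, protocol, env, optics, fix_g_sw, const)

  free <- if (fix_g_sw) c("k", "g_bh", "sigma_obs")
          else c("k", "g_bh", "g_sw", "sigma_obs")
  lp_log <- function(theta) {
    p <- as.list(exp(theta))
    names(p) <- free
    if (fix_g_sw) p$g_sw <- 0
    lp <- log_posterior(unlist(p), fit_trace, protocol, env, optics, priors,
                        T0 = T0, fix_g_sw = fix_g_sw, const = const)
    lp + sum(theta)  # Jacobian of the log transform
  }

  kept <- control$iterations - control$warmup
  draws <- array(NA_real_, dim = c(kept, control$chains, length(free)),
                 dimnames = list(NULL, NULL, free))
  accept <- numeric(control$chains)
  theta_init <- log(unlist(init)[free])
  for (ch in seq_len(control$chains)) {
    th0 <- theta_init + stats::rnorm(length(free), 0, 0.05)
    res <- run_chain(lp_log, th0, control$iterations, control$warmup,
                     control$target_accept)
    draws[, ch, ] <- exp(res$draws)
    accept[ch] <- res$accept_rate
  }

  diag_df <- convergence_diagnostics(draws)
  converged <- all(is.finite(diag_df$rhat)) &&
    all(diag_df$rhat < 1.01) && all(diag_df$ess_bulk > 200)
  if (!converged)
    warning("fit flagged non-converged (need R-hat < 1.01 and ESS > 200 ",
            "for all free parameters); consider more iterations")

  flat <- apply(draws, 3, as.vector)
  post_mean <- colMeans(flat)
  summ <- data.frame(
    parameter = free,
    mean = post_mean,
    sd = apply(flat, 2, stats::sd),
    ci_lower = apply(flat, 2, stats::quantile, probs = 0.025),
    ci_upper = apply(flat, 2, stats::quantile, probs = 0.975),
    rhat = diag_df$rhat,
    ess_bulk = diag_df$ess_bulk,
    row.names = NULL, stringsAsFactors = FALSE)

  pm <- as.list(post_mean)
  if (fix_g_sw) pm$g_sw <- 0
  fitted_T <- predict_trace(pm, fit_trace, protocol, env, optics, T0, const)
  rmse <- if (is.null(fitted_T)) NA_real_ else fit_rmse(fit_trace$T, fitted_T)
  fitted_trace <- if (is.null(fitted_T)) NULL
                  else thermal_trace(fit_trace$times, fitted_T)

  cp <- NULL
  if (!is.null(sample) && is.finite(sample$mass_per_area))
    cp <- derive_cp(as.vector(flat[, "k"]), sample$mass_per_area)

  structure(list(draws = draws, summary = summ, rmse = rmse,
                 converged = converged, accept_rate = accept,
                 fitted = fitted_trace,
                 trace = fit_trace, protocol = protocol, env = env,
                 optics = optics, sample = sample, priors = priors,
                 control = control, fix_g_sw = fix_g_sw, T0 = T0,
                 init = init, cp = cp, const = const),
            class = "cp_fit")
}
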