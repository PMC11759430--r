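#' @export
print.cp_fit <- function(x, ...) {
  cat("Energy-balance transient fit (", x$control$chains, " chains x ",
      x$control$iterations, " iterations, ", x$control$warmup, " warmup)\n",
      sep = "")
  cat(if (x$converged) "Converged" else "NOT CONVERGED",
      sprintf("; RMSE = %.4f K\n", x$rmse))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %12.5g  [%.5g, %.5g]\n", s$parameter[i], s$mean[i],
                s$ci_lower[i], s$ci_upper[i]))
  if (!is.null(x$cp)) print(x$cp)
  invisible(x)
}

#' Summarize a transient fit
#'
#' @param object a `cp_fit` from [fit_transient()].
#' @param ... unused.
#' @return A list of class `summary.cp_fit` with the posterior table
#'   (mean, sd, 95\% credible interval, R-hat, bulk ESS per parameter), RMSE
#'   of the posterior-mean prediction, convergence flag, and the C_p summary
#'   when a sample with known mass per area was supplied.
#' @export
summary.cp_fit <- function(object, ...) {
  structure(list(posterior = object$summary, rmse = object$rmse,
                 converged = object$converged, cp = object$cp,
                 accept_rate = object$accept_rate,
                 n_obs = length(object$trace$times),
                 control = object$control),
            class = "summary.cp_fit")
}

#' @export
print.summary.cp_fit <- function(x, ...) {
  cat("Posterior summary (", x$n_obs, " observations):\n", sep = "")
  print(x$posterior, row.names = FALSE, digits = 5)
  cat(sprintf("RMSE = %.4f K; mean acceptance rate = %.2f; %s\n", x$rmse,
              mean(x$accept_rate),
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$cp)) print(x$cp)
  invisible(x)
}

#' @export
coef.cp_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Posterior-mean model prediction
#'
#' @param object a `cp_fit`.
#' @param times output times (s); defaults to the fitted trace times.
#' @param ... unused.
#' @return A [thermal_trace()] of the posterior-mean trajectory.
#' @export
predict.cp_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  pm <- as.list(coef(object))
  if (object$fix_g_sw) pm$g_sw <- 0
  cond <- conductances(pm$g_bh, pm$g_sw)
  integrate_temperature(object$T0, object$protocol, object$env,
                        object$optics, cond, pm$k, times = times,
                        const = object$const)
}

#' @export
residuals.cp_fit <- function(object, ...) {
  if (is.null(object$fitted)) return(rep(NA_real_, length(object$trace$T)))
  object$trace$T - object$fitted$T
}

#' Posterior-predictive transients
#'
#' Draws parameter vectors from the posterior, integrates the model for each,
#' and adds Gaussian observation noise at the drawn `sigma_obs`.
#'
#' @param object a `cp_fit`.
#' @param nsim number of simulated traces.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of [thermal_trace()] objects of length `nsim`.
#' @export
simulate.cp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$draws
  n_draw <- dim(d)[1] * dim(d)[2]
  flat <- apply(d, 3, as.vector)
  idx <- sample.int(n_draw, nsim, replace = nsim > n_draw)
  lapply(idx, function(i) {
    p <- as.list(flat[i, ])
    if (object$fix_g_sw) p$g_sw <- 0
    cond <- conductances(p$g_bh, p$g_sw)
    tr <- integrate_temperature(object$T0, object$protocol, object$env,
                                object$optics, cond, p$k,
                                times = object$trace$times,
                                const = object$const)
    tr$T <- tr$T + stats::rnorm(length(tr$T), 0, p$sigma_obs)
    tr
  })
}

#' Plot observed vs fitted transient
#'
#' Observed temperatures as a solid line, the posterior-mean model as a dashed
#' red line, with the lit period shaded.
#'
#' @param x a `cp_fit`.
#' @param celsius plot in degrees Celsius (default) rather than kelvin.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cp_fit <- function(x, celsius = TRUE, ...) {
  off <- if (celsius) 273.15 else 0
  graphics::plot(x$trace$times, x$trace$T - off, type = "l",
                 xlab = "time (s)",
                 ylab = if (celsius) "temperature (°C)" else "temperature (K)",
                 ...)
  pw <- pulse_window(x$protocol)
  graphics::rect(pw[1], graphics::par("usr")[3], pw[2],
                 graphics::par("usr")[4],
                 col = grDevices::adjustcolor("gold", 0.2), border = NA)
  if (!is.null(x$fitted))
    graphics::lines(x$fitted$times, x$fitted$T - off, col = "red", lty = 2,
                    lwd = 2)
  graphics::legend("topright", legend = c("observed", "modelled"),
                   col = c("black", "red"), lty = c(1, 2), bty = "n")
  invisible(x)
}
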