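# Rank-normalized split R-hat and bulk effective sample size, following the
# definitions of Vehtari, Gelman, Simpson, Carpenter & Buerkner (2021).

split_chains <- function(sims) {
  n <- nrow(sims)
  half <- n %/% 2L
  cbind(sims[seq_len(half), , drop = FALSE],
        sims[(n - half + 1L):n, , drop = FALSE])
}

rank_normalize <- function(sims) {
  S <- length(sims)
  z <- stats::qnorm((rank(as.vector(sims), ties.method = "average") - 0.375) /
                      (S + 0.25))
  matrix(z, nrow = nrow(sims), ncol = ncol(sims))
}

rhat_basic <- function(sims) {
  n <- nrow(sims); m <- ncol(sims)
  if (n < 2L || m < 2L) return(NA_real_)
  means <- colMeans(sims)
  vars <- apply(sims, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(sims) {
  n <- nrow(sims); m <- ncol(sims)
  if (n < 3L) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(sims[, j], lag.max = n - 1L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  # acf() divides by n, i.e. already the biased estimator used by Stan
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(colMeans(sims))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus  # rho[1] = lag 0
  # Geyer initial positive + monotone sequence on pair sums
  max_pairs <- (n - 1L) %/% 2L
  tau <- 0
  prev <- Inf
  for (kpair in seq_len(max_pairs)) {
    p <- rho[2L * kpair] + rho[2L * kpair + 1L]
    if (!is.finite(p) || p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- rho[1] + 2 * tau  # lag-0 term plus twice the paired positive sums
  ess <- n * m / max(tau, 1e-12)
  min(ess, n * m * log10(max(n * m, 10)))
}

rhat_rank <- function(sims) {
  s <- split_chains(sims)
  if (stats::sd(as.vector(s)) == 0) return(NA_real_)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - stats::median(s))))
  max(bulk, folded)
}

ess_bulk_rank <- function(sims) {
  s <- split_chains(sims)
  if (stats::sd(as.vector(s)) == 0) return(NA_real_)
  ess_basic(rank_normalize(s))
}

#' MCMC convergence diagnostics
#'
#' Computes the rank-normalized split R-hat and bulk effective sample size
#' (ESS) per parameter from per-chain posterior draws. R-hat compares within-
#' and between-chain variance on rank-normalized (and folded) draws; values
#' below 1.01 together with ESS above 200 are the acceptance thresholds used
#' by [fit_transient()]. Degenerate inputs (all draws identical) yield `NA`
#' with a warning rather than a number.
#'
#' @param draws a matrix (iterations x chains) for one parameter, or a 3-d
#'   array (iterations x chains x parameters).
#' @return A data frame with columns `parameter`, `rhat`, `ess_bulk`.
#' @examples
#' draws <- array(rnorm(4000), dim = c(500, 4, 2),
#'                dimnames = list(NULL, NULL, c("a", "b")))
#' convergence_diagnostics(draws)
#' @export
convergence_diagnostics <- function(draws) {
  if (is.matrix(draws)) {
    dn <- "parameter"
    draws <- array(draws, dim = c(dim(draws), 1L),
                   dimnames = list(NULL, NULL, dn))
  }
  if (!(is.array(draws) && length(dim(draws)) == 3L))
    stop("`draws` must be an iterations x chains (x parameters) array",
         call. = FALSE)
  n <- dim(draws)[1]; m <- dim(draws)[2]
  if (m < 2L) stop("need at least 2 chains", call. = FALSE)
  if (n < 100L)
    stop("need at least 100 post-warmup draws per chain", call. = FALSE)
  pn <- dimnames(draws)[[3]]
  if (is.null(pn)) pn <- paste0("par", seq_len(dim(draws)[3]))
  out <- data.frame(parameter = pn,
                    rhat = NA_real_, ess_bulk = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(dim(draws)[3])) {
    sims <- draws[, , p]
    out$rhat[p] <- rhat_rank(sims)
    out$ess_bulk[p] <- ess_bulk_rank(sims)
  }
  if (anyNA(out$rhat))
    warning("degenerate draws (zero variance) for: ",
            paste(out$parameter[is.na(out$rhat)], collapse = ", "),
            "; R-hat undefined")
  out
}
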