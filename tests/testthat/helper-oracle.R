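# Brute-force fixed-step RK4 integrator written against the pure-R
# energy_balance_rhs(); independent of the compiled adaptive integrator.
rk4_oracle <- function(T0, protocol, env, optics, cond, k, out_times,
                       dt = 1e-3, const = physics_constants()) {
  env <- as_environment_trace(env)
  f <- function(t, T) {
    e <- env_at(env, t, I_s = protocol_irradiance(protocol, t))
    energy_balance_rhs(T, e, optics, cond, k, const)
  }
  out <- numeric(length(out_times))
  out[1] <- T0
  T <- T0
  t <- out_times[1]
  # step boundaries: protocol switch points plus output times
  for (i in 2:length(out_times)) {
    target <- out_times[i]
    while (t < target - 1e-12) {
      nb <- protocol$t_start[protocol$t_start > t + 1e-12]
      nb <- c(nb, protocol$t_end[protocol$t_end > t + 1e-12])
      h <- min(dt, target - t, if (length(nb)) min(nb) - t else Inf)
      k1 <- f(t, T)
      k2 <- f(t + h / 2, T + h / 2 * k1)
      k3 <- f(t + h / 2, T + h / 2 * k2)
      k4 <- f(t + h, T + h * k3)
      T <- T + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    t <- target
    out[i] <- T
  }
  out
}

# Small shared fixtures / controls for fast unit-level fits
fast_control <- function(seed = 42, chains = 2, iterations = 800,
                         warmup = 400) {
  mcmc_control(chains = chains, iterations = iterations, warmup = warmup,
               seed = seed)
}

plate_inputs <- function() {
  fx <- aluminum_fixture(seed = 1, noise_sd = 0)
  fx
}
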