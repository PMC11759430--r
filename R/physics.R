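#' Saturation vapour pressure of water
#'
#' Magnus-type formulas over liquid water. Tetens:
#' es(T) = 610.78 exp(17.27 Tc / (Tc + 237.3)) with Tc in degC; Buck (1996):
#' es(T) = 611.21 exp((18.678 - Tc/234.5) Tc / (257.14 + Tc)). Both agree to
#' ~0.1\% over 0-45 degC.
#'
#' @param T temperature (K); vectorized. Must lie strictly inside (200, 400) K.
#' @param formula `"tetens"` (default) or `"buck"`.
#' @return Saturation vapour pressure (Pa).
#' @examples
#' saturation_vapour_pressure(293.15)  # ~2339 Pa at 20 degC
#' @export
saturation_vapour_pressure <- function(T, formula = c("tetens", "buck")) {
  formula <- match.arg(formula)
  check_temperature(T, "T")
  tc <- T - 273.15
  if (formula == "buck")
    611.21 * exp((18.678 - tc / 234.5) * (tc / (257.14 + tc)))
  else
    610.78 * exp(17.27 * tc / (tc + 237.3))
}

#' Psychrometric state of a leaf/air pair
#'
#' Evaluates the humidity-related quantities entering the energy balance: the
#' saturation vapour pressure at leaf temperature (`es`, the vapour pressure
#' of the saturated leaf interior), the air vapour pressure
#' `ea = RH_air * es(T_air)`, their difference `VPD = es - ea`, the air
#' density by the ideal-gas law at (`T_air`, `P_atm`), and the fixed air heat
#' capacity `C_s` and latent heat `lambda` from [physics_constants()].
#'
#' @param T_leaf leaf (object) temperature (K).
#' @param env an [env_state()].
#' @param const a [physics_constants()].
#' @return A list of class `psychrometric_state` with fields `es`, `ea`,
#'   `VPD` (Pa), `rho_air` (kg m-3), `C_s` (J kg-1 K-1), `lambda` (J kg-1).
#' @examples
#' psychrometric_state(294.15, env_state(293.15, 0.7))
#' @export
psychrometric_state <- function(T_leaf, env, const = physics_constants()) {
  stopifnot(inherits(env, "env_state"), inherits(const, "physics_constants"))
  check_temperature(T_leaf, "T_leaf")
  es <- saturation_vapour_pressure(T_leaf, const$es_formula)
  ea <- env$RH_air * saturation_vapour_pressure(env$T_air, const$es_formula)
  structure(list(es = es, ea = ea, VPD = es - ea,
                 rho_air = env$P_atm / (const$R_dry_air * env$T_air),
                 C_s = const$C_s, lambda = const$lambda),
            class = "psychrometric_state")
}

#' Series combination of stomatal and boundary-layer conductance
#'
#' Total conductance to water vapour of the stomatal and boundary-layer
#' pathways in series, `1 / (1/g_sw + 1/g_bw)`. The limit when either
#' conductance is 0 is defined as 0 (closed stomata or a dry reference plate
#' shut off the latent flux; no division error is raised).
#'
#' @param g_sw stomatal conductance to water vapour (m s-1); vectorized.
#' @param g_bw boundary-layer conductance to water vapour (m s-1); vectorized.
#' @return Series conductance (m s-1).
#' @examples
#' series_conductance(0.003, 0.01087)
#' series_conductance(0, 0.01)  # 0, defined limit
#' @export
series_conductance <- function(g_sw, g_bw) {
  if (any(g_sw < 0) || any(g_bw < 0))
    stop("conductances must be >= 0", call. = FALSE)
  out <- numeric(length(g_sw <- rep_len(g_sw, max(length(g_sw),
                                                  length(g_bw)))))
  g_bw <- rep_len(g_bw, length(g_sw))
  pos <- g_sw > 0 & g_bw > 0
  out[pos] <- 1 / (1 / g_sw[pos] + 1 / g_bw[pos])
  out
}

#' Convert a conductance from velocity to molar units
#'
#' Converts m s-1 to mol m-2 s-1 by the molar density of air,
#' `g * P_atm / (R * T_leaf)`. For stomatal conductance the field convention
#' stated alongside the model uses an extra factor 0.92 in the conversion
#' factor (0.92 R T / P as the divisor); set `include_092 = TRUE` to apply it,
#' which divides the plain molar value by 0.92.
#'
#' @param g conductance (m s-1); vectorized.
#' @param T_leaf leaf temperature (K).
#' @param P_atm atmospheric pressure (Pa).
#' @param include_092 apply the stomatal-conductance 0.92 variant.
#' @return Conductance in mol m-2 s-1.
#' @seealso [molar_to_conductance()] for the inverse.
#' @examples
#' conductance_to_molar(0.01, 293.15, 101325)  # ~0.416 mol m-2 s-1
#' @export
conductance_to_molar <- function(g, T_leaf, P_atm, include_092 = FALSE) {
  if (any(g < 0)) stop("`g` must be >= 0", call. = FALSE)
  check_temperature(T_leaf, "T_leaf")
  check_scalar(P_atm, "P_atm", lower = 1e-12)
  R <- physics_constants()$R_gas
  out <- g * P_atm / (R * T_leaf)
  if (include_092) out <- out / 0.92
  out
}

#' @rdname conductance_to_molar
#' @param g_mol conductance (mol m-2 s-1).
#' @export
molar_to_conductance <- function(g_mol, T_leaf, P_atm, include_092 = FALSE) {
  if (any(g_mol < 0)) stop("`g_mol` must be >= 0", call. = FALSE)
  check_temperature(T_leaf, "T_leaf")
  check_scalar(P_atm, "P_atm", lower = 1e-12)
  R <- physics_constants()$R_gas
  out <- g_mol * R * T_leaf / P_atm
  if (include_092) out <- out * 0.92
  out
}

#' Energy flux components at an instant
#'
#' The four terms of the energy-balance numerator, each in W m-2 of one-sided
#' leaf area: absorbed short-wave radiation `alpha * I_s` (one face), net
#' long-wave exchange `2 eps theta (T_reflect^4 - T_leaf^4)`, sensible heat
#' loss `2 rho_air C_s g_bh (T_leaf - T_air)`, and latent heat loss
#' `2 lambda (0.622 rho_air / P_atm) g_tw VPD` with `g_tw` the series
#' conductance of stomata and boundary layer. Long-wave, sensible and latent
#' exchange act on both faces (factor 2); the short-wave pulse is absorbed on
#' the lit face only.
#'
#' @param T_leaf leaf (object) temperature (K).
#' @param env an [env_state()].
#' @param optics an [optical_properties()].
#' @param cond a [conductances()].
#' @param const a [physics_constants()].
#' @return Named numeric vector `c(SW_abs, LW_net, H_sensible, LE_latent)`;
#'   `SW_abs + LW_net - H_sensible - LE_latent` is the stored heat flux.
#' @examples
#' flux_components(295.15, env_state(293.15, 0.5, I_s = 270),
#'                 optical_properties(0.98, 0.96), conductances(0.01, 0))
#' @export
flux_components <- function(T_leaf, env, optics, cond,
                            const = physics_constants()) {
  stopifnot(inherits(env, "env_state"),
            inherits(optics, "optical_properties"),
            inherits(cond, "conductances"))
  check_temperature(T_leaf, "T_leaf")
  psy <- psychrometric_state(T_leaf, env, const)
  SW <- optics$alpha * env$I_s
  LW <- 2 * optics$epsilon * const$sigma_sb *
    (env$T_reflect^4 - T_leaf^4)
  H <- 2 * psy$rho_air * const$C_s * cond$g_bh * (T_leaf - env$T_air)
  g_tw <- series_conductance(cond$g_sw, cond$g_bw)
  LE <- 2 * const$lambda * (0.622 * psy$rho_air / env$P_atm) * g_tw * psy$VPD
  c(SW_abs = SW, LW_net = LW, H_sensible = H, LE_latent = LE)
}

#' Rate of change of leaf temperature
#'
#' The right-hand side of the dynamic energy balance:
#' dT_leaf/dt = (SW_abs + LW_net - H_sensible - LE_latent) / k, in K s-1.
#' `k` is the areal heat capacity (thickness x density x specific heat
#' capacity, J m-2 K-1); doubling `k` halves the rate at a fixed state.
#'
#' @inheritParams flux_components
#' @param k areal heat capacity (J m-2 K-1), > 0.
#' @return Temperature tendency (K s-1).
#' @examples
#' energy_balance_rhs(293.15, env_state(293.15, 0.5, I_s = 270),
#'                    optical_properties(0.98, 0.96),
#'                    conductances(0.01, 0), k = 2971.3)
#' @export
energy_balance_rhs <- function(T_leaf, env, optics, cond, k,
                               const = physics_constants()) {
  check_scalar(k, "k", lower = 1e-12)
  f <- flux_components(T_leaf, env, optics, cond, const)
  unname((f[["SW_abs"]] + f[["LW_net"]] - f[["H_sensible"]] -
            f[["LE_latent"]]) / k)
}

#' Steady-state (equilibrium) temperature
#'
#' Solves `energy_balance_rhs = 0` for the leaf temperature, bracketed in
#' `[T_air - 30, T_air + 50]` K. In darkness with open stomata and
#' unsaturated air the equilibrium sits below air temperature (evaporative
#' cooling); a dry plate with `T_reflect = T_air` equilibrates exactly at air
#' temperature. The root is polished so that `|rhs| < 1e-10` K s-1.
#'
#' @inheritParams flux_components
#' @return Equilibrium temperature (K).
#' @examples
#' equilibrium_temperature(env_state(293.15, 0.5),
#'                         optical_properties(0.95, 0.98),
#'                         conductances(0.01, 0.002))
#' @export
equilibrium_temperature <- function(env, optics, cond,
                                    const = physics_constants()) {
  stopifnot(inherits(env, "env_state"))
  if (cond$g_bh <= 0)
    stop("equilibrium requires g_bh > 0", call. = FALSE)
  f <- function(T) energy_balance_rhs(T, env, optics, cond, k = 1,
                                      const = const)
  lo <- env$T_air - 30; hi <- env$T_air + 50
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("no sign change of the energy balance in [T_air - 30, T_air + 50]; ",
         "rhs(", format(lo), ") = ", format(flo), ", rhs(", format(hi),
         ") = ", format(fhi), call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # Newton polish to drive the residual below 1e-10 K s-1 (k = 1 scale)
  for (i in 1:3) {
    fr <- f(root)
    if (abs(fr) < 1e-12) break
    df <- (f(root + 1e-6) - f(root - 1e-6)) / 2e-6
    if (!is.finite(df) || df == 0) break
    root <- root - fr / df
  }
  if (abs(f(root)) > 1e-10)
    stop("equilibrium solve did not converge: |rhs| = ",
         format(abs(f(root))), call. = FALSE)
  root
}
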