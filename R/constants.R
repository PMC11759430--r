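#' Physical constants and psychrometric conventions
#'
#' Bundles the fixed physical constants and the overridable psychrometric
#' coefficients used throughout the energy-balance model. The Stefan-Boltzmann
#' constant and the molar gas constant are fixed; the specific heat capacity of
#' humid air `C_s` and the latent heat of vaporization `lambda` are treated as
#' constants at their ~20 degC values (the model's sensitivity to them is
#' second order) but can be overridden here. Air density is always computed by
#' the ideal-gas law at (`T_air`, `P_atm`) using the specific gas constant of
#' dry air.
#'
#' @param C_s specific heat capacity of (humid) air, J kg-1 K-1.
#' @param lambda latent heat of vaporization of water, J kg-1.
#' @param es_formula saturation vapour pressure formula, `"tetens"` (default)
#'   or `"buck"`.
#' @return An object of class `physics_constants` (a named list that also
#'   carries `sigma_sb`, the Stefan-Boltzmann constant in W m-2 K-4; `R_gas`,
#'   the molar gas constant in J mol-1 K-1; and `R_dry_air`, the specific gas
#'   constant of dry air in J kg-1 K-1).
#' @examples
#' physics_constants()
#' physics_constants(es_formula = "buck")
#' @export
physics_constants <- function(C_s = 1010, lambda = 2.45e6,
                              es_formula = c("tetens", "buck")) {
  es_formula <- match.arg(es_formula)
  stopifnot(is.numeric(C_s), length(C_s) == 1L, C_s > 0,
            is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  structure(
    list(sigma_sb = 5.670374419e-8,
         R_gas = 8.3145,
         R_dry_air = 287.05,
         C_s = C_s,
         lambda = lambda,
         es_formula = es_formula),
    class = "physics_constants"
  )
}

es_formula_code <- function(const) {
  if (identical(const$es_formula, "buck")) 1L else 0L
}
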