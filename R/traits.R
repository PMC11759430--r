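#' Leaf water content
#'
#' `LWC (\%) = (FW - DW) / FW * 100`. Any consistent mass unit may be used.
#' A missing dry weight propagates to `NA` (never a silent zero).
#'
#' @param FW fresh weight; vectorized.
#' @param DW dry weight; vectorized, `NA` allowed.
#' @return Water content in percent, in \[0, 100\].
#' @examples
#' leaf_water_content(0.428, 0.049)  # 88.6 %
#' @export
leaf_water_content <- function(FW, DW) {
  if (any(FW <= 0, na.rm = TRUE))
    stop("`FW` must be > 0", call. = FALSE)
  if (any(DW < 0, na.rm = TRUE) || any(DW > FW, na.rm = TRUE))
    stop("`DW` must satisfy 0 <= DW <= FW", call. = FALSE)
  (FW - DW) / FW * 100
}

#' Fresh mass per unit area and fresh-weight specific leaf area
#'
#' Fresh mass per area (the lumped density x thickness term of the energy
#' balance) is fresh weight divided by one-sided leaf area; fresh-weight
#' specific leaf area is its reciprocal. Inputs use trait-table bench units
#' (g, cm2); outputs are SI.
#'
#' @param FW_g fresh weight (g); vectorized.
#' @param area_cm2 one-sided leaf area (cm2); vectorized.
#' @return A data frame with `mass_per_area` (kg m-2) and `sla_fw`
#'   (m2 kg-1), satisfying `mass_per_area * sla_fw = 1`.
#' @examples
#' mass_per_area_and_sla(0.428, 17.348)  # 0.2467 kg m-2, 4.054 m2 kg-1
#' @export
mass_per_area_and_sla <- function(FW_g, area_cm2) {
  if (any(FW_g <= 0, na.rm = TRUE) || any(area_cm2 <= 0, na.rm = TRUE))
    stop("fresh weight and area must be > 0", call. = FALSE)
  mpa <- (FW_g / 1000) / (area_cm2 / 1e4)
  data.frame(mass_per_area = mpa, sla_fw = 1 / mpa)
}

#' Leaf mass per area (dry-weight basis)
#'
#' @param DW_g dry weight (g); `NA` (e.g. lost sample) propagates to `NA`.
#' @param area_cm2 one-sided leaf area (cm2).
#' @return LMA in g m-2.
#' @examples
#' lma(0.049, 17.348)  # 28.2 g m-2
#' lma(NA, 17.348)     # NA, explicit missing
#' @export
lma <- function(DW_g, area_cm2) {
  if (any(DW_g <= 0, na.rm = TRUE))
    stop("`DW_g` must be > 0 (use NA for missing)", call. = FALSE)
  if (any(area_cm2 <= 0, na.rm = TRUE))
    stop("`area_cm2` must be > 0", call. = FALSE)
  DW_g / (area_cm2 / 1e4)
}

#' Water loss during the imaging protocol
#'
#' `100 (FW_before - FW_after) / FW_before`. Runs losing more than 4\% of
#' fresh weight are flagged with a warning: beyond that, the water (and hence
#' heat-capacity) state of the leaf changed materially during the measurement.
#'
#' @param FW_before,FW_after fresh weight before/after imaging (same unit).
#' @return Water loss in percent.
#' @examples
#' water_loss_percent(1.000, 0.990)  # 1 %
#' @export
water_loss_percent <- function(FW_before, FW_after) {
  if (any(FW_before <= 0, na.rm = TRUE) || any(FW_after <= 0, na.rm = TRUE))
    stop("fresh weights must be > 0", call. = FALSE)
  if (any(FW_after > FW_before, na.rm = TRUE))
    stop("`FW_after` cannot exceed `FW_before`", call. = FALSE)
  wl <- 100 * (FW_before - FW_after) / FW_before
  if (any(wl > 4, na.rm = TRUE))
    warning("water loss above 4%: the sample dried noticeably during ",
            "imaging; treat the fit with caution")
  wl
}

#' Long-wave emissivity by the reference-emittance technique
#'
#' A freshly cut leaf floats on warm water next to a crumpled aluminum foil;
#' assuming the leaf takes the water temperature, its emissivity follows from
#' the apparent (camera) temperatures:
#' `eps_leaf = eps_reference * (T_l_app^4 - T_reflect^4) /
#' (T_water^4 - T_reflect^4)`, with the water reference emissivity 0.98.
#'
#' @param T_water water-surface temperature (K).
#' @param T_l_app apparent leaf temperature imaged at the reference
#'   emissivity (K).
#' @param T_reflect foil (reflected background) temperature (K).
#' @param eps_reference emissivity of water (default 0.98).
#' @return Estimated emissivity; values outside \[0, 1\] are clipped with a
#'   warning.
#' @examples
#' leaf_emissivity(313.15, 312.00, 293.15)  # ~0.918
#' @export
leaf_emissivity <- function(T_water, T_l_app, T_reflect,
                            eps_reference = 0.98) {
  check_temperature(T_water, "T_water")
  check_temperature(T_l_app, "T_l_app")
  check_temperature(T_reflect, "T_reflect")
  check_scalar(eps_reference, "eps_reference", 0, 1)
  den <- T_water^4 - T_reflect^4
  if (any(abs(den) < 1e-9))
    stop("T_water and T_reflect coincide: emissivity undefined",
         call. = FALSE)
  eps <- eps_reference * (T_l_app^4 - T_reflect^4) / den
  if (any(eps < 0) || any(eps > 1)) {
    warning("estimated emissivity outside [0, 1]; clipped")
    eps <- pmin(pmax(eps, 0), 1)
  }
  eps
}

#' Compute derived traits for a trait table
#'
#' Appends leaf water content, fresh mass per area, fresh-weight specific
#' leaf area and LMA to a table with columns `FW_g`, `DW_g` and `area_cm2`
#' (further columns such as `species`, `water_loss_pct`, `emissivity`,
#' `absorptance` pass through untouched). Missing dry weights propagate as
#' `NA`.
#'
#' @param df a data frame with at least `FW_g` and `area_cm2`.
#' @return The data frame with columns `LWC_pct`, `mass_per_area_kg_m2`,
#'   `SLA_FW_m2_kg`, `LMA_g_m2` appended.
#' @examples
#' tab <- read.csv(system.file("extdata", "species_traits.csv",
#'                             package = "leafcp"))
#' head(compute_leaf_traits(tab))
#' @export
compute_leaf_traits <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("FW_g", "area_cm2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  DW <- if ("DW_g" %in% names(df)) df$DW_g else rep(NA_real_, nrow(df))
  ms <- mass_per_area_and_sla(df$FW_g, df$area_cm2)
  df$LWC_pct <- leaf_water_content(df$FW_g, DW)
  df$mass_per_area_kg_m2 <- ms$mass_per_area
  df$SLA_FW_m2_kg <- ms$sla_fw
  df$LMA_g_m2 <- ifelse(is.na(DW), NA_real_, DW / (df$area_cm2 / 1e4))
  df
}
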