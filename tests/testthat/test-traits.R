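test_that("leaf water content follows (FW - DW)/FW * 100", {
  expect_equal(leaf_water_content(0.428, 0.049), 88.551, tolerance = 1e-4)
  expect_equal(leaf_water_content(1, 1), 0)
  expect_equal(leaf_water_content(1, 0), 100)
  expect_true(is.na(leaf_water_content(1, NA)))
  expect_error(leaf_water_content(0.4, 0.5), "DW")
  expect_error(leaf_water_content(0, 0), "FW")
})

test_that("mass per area / SLA are a reciprocal pair in SI units", {
  m <- mass_per_area_and_sla(0.428, 17.348)
  expect_equal(m$mass_per_area, 0.24671, tolerance = 1e-4)
  expect_equal(m$sla_fw, 4.0533, tolerance = 1e-4)
  expect_equal(m$mass_per_area * m$sla_fw, 1)
  expect_equal(mass_per_area_and_sla(1000, 1e4)$mass_per_area, 1)
  expect_equal(mass_per_area_and_sla(1, 2)$mass_per_area,
               mass_per_area_and_sla(1, 1)$mass_per_area / 2)
  expect_error(mass_per_area_and_sla(-1, 2), "> 0")
})

test_that("LMA computes g m-2 and propagates missing dry weight", {
  expect_equal(lma(0.049, 17.348), 28.245, tolerance = 1e-3)
  expect_equal(lma(1, 1e4), 1)
  expect_true(is.na(lma(NA, 17.3)))
  expect_error(lma(0.05, -1), "area")
})

test_that("water loss percent validates and warns above 4%", {
  expect_equal(water_loss_percent(1, 1), 0)
  expect_equal(water_loss_percent(1.000, 0.990), 1.0)
  expect_error(water_loss_percent(0.9, 1.0), "exceed")
  expect_warning(water_loss_percent(1.0, 0.9), "above 4%")
})

test_that("reference-emittance emissivity identities and hand value", {
  # leaf apparent temperature equal to water -> reference emissivity
  expect_equal(leaf_emissivity(313.15, 313.15, 293.15), 0.98)
  # apparent temperature equal to background -> 0
  expect_equal(leaf_emissivity(313.15, 293.15, 293.15), 0)
  # quartic arithmetic by hand: 0.98*(312^4-293.15^4)/(313.15^4-293.15^4)
  expect_equal(leaf_emissivity(313.15, 312.00, 293.15), 0.91830,
               tolerance = 1e-4)
  # monotone increasing in apparent temperature between the anchors
  Ts <- seq(294, 313, by = 1)
  eps <- vapply(Ts, function(x) leaf_emissivity(313.15, x, 293.15),
                numeric(1))
  expect_true(all(diff(eps) > 0))
  expect_error(leaf_emissivity(293.15, 300, 293.15), "coincide")
  expect_warning(leaf_emissivity(313.15, 314.15, 293.15), "clipped")
})

test_that("trait table round-trip stays in physical range", {
  tab <- read.csv(system.file("extdata", "species_traits.csv",
                              package = "leafcp"),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 13)
  out <- compute_leaf_traits(tab)
  expect_true(all(out$mass_per_area_kg_m2 > 0.02 &
                    out$mass_per_area_kg_m2 < 2))
  lwc <- out$LWC_pct[!is.na(out$LWC_pct)]
  expect_true(all(lwc > 40 & lwc < 98))
  # pumpkin's missing dry weight propagates, never a silent zero
  expect_true(is.na(out$LWC_pct[out$species == "pumpkin"]))
  expect_true(is.na(out$LMA_g_m2[out$species == "pumpkin"]))
  expect_equal(out$SLA_FW_m2_kg * out$mass_per_area_kg_m2,
               rep(1, nrow(out)))
  expect_error(compute_leaf_traits(data.frame(FW_g = 1)), "lacks columns")
})
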