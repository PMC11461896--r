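test_that("excess concentration is the signed departure from equilibrium", {
  expect_identical(excess_concentration(0.5, 0.5), 0)
  # river mean 8.6 ug/L against the cold-water equilibrium, ~0.53 uM excess
  cw <- convert_concentration(8.6, "ug_L", "uM")
  ceq <- equilibrium_concentration(gas_conditions(1, 1, 1900))
  expect_equal(round(excess_concentration(cw, ceq), 2), 0.53)
  # undersaturated water has a negative excess
  expect_equal(excess_concentration(0, 0.004), -0.004)
  expect_error(excess_concentration(-1, 0), ">= 0")
})

test_that("diffusive flux is bilinear in kx and excess, on both unit scales", {
  expect_identical(diffusive_flux(10, 0)$flux_mmol_m2_d, 0)
  f <- diffusive_flux(118.8, 0.53)
  expect_equal(f$flux_mmol_m2_d, 118.8 * 0.53)
  expect_equal(f$flux_umol_m2_d, 1000 * f$flux_mmol_m2_d)
  # bilinearity
  expect_equal(diffusive_flux(2 * 118.8, 0.53)$flux_mmol_m2_d,
               2 * f$flux_mmol_m2_d)
  expect_equal(diffusive_flux(118.8, 2 * 0.53)$flux_mmol_m2_d,
               2 * f$flux_mmol_m2_d)
  expect_error(diffusive_flux(0, 0.5), "positive")
})

test_that("river and lake fluxes reproduce the published digits", {
  sc1 <- schmidt_number_ch4(1)
  kx_river <- schmidt_scale(k600_river(energy_dissipation(0.01, 4)), sc1)
  expect_equal(signif(diffusive_flux(kx_river, 0.53)$flux_mmol_m2_d, 2), 63)
  kx_lake <- schmidt_scale(k600_lake_wind(3.7), sc1)
  expect_equal(signif(diffusive_flux(kx_lake, 0.34)$flux_mmol_m2_d, 1), 0.05)
})

test_that("residence time follows hydraulic continuity", {
  summer <- reach_scenario(4000, 20, 1, 50)
  winter <- reach_scenario(4000, 20, 1, 10)
  expect_equal(round(residence_time(summer)), 27)
  expect_equal(round(residence_time(winter)), 133)
  expect_equal(residence_time(summer), 4000 / 2.5 / 60)
  # doubling discharge halves the residence time
  expect_equal(residence_time(reach_scenario(4000, 20, 1, 100)),
               residence_time(summer) / 2)
  expect_error(reach_scenario(4000, 20, 0, 50), "positive")
})

test_that("zero-order attenuation conserves mass and clamps at the load", {
  expect_identical(attenuate(0.53, 2.97, 0)$removed_um, 0)
  expect_identical(attenuate(0.53, 0, 133)$fraction_removed_pct, 0)
  # removed + remaining = c0 exactly; fraction within [0, 100]
  set.seed(11)
  for (i in 1:25) {
    c0 <- stats::runif(1, 0.05, 2)
    a <- attenuate(c0, stats::runif(1, 0, 5), stats::runif(1, 0, 3000))
    expect_identical(a$removed_um + a$remaining_um, c0)
    expect_gte(a$fraction_removed_pct, 0)
    expect_lte(a$fraction_removed_pct, 100)
  }
  # long transit cannot remove more methane than is present
  full <- attenuate(0.53, 2.97, 1e6)
  expect_identical(full$removed_um, 0.53)
  expect_identical(full$fraction_removed_pct, 100)
  # nondecreasing in residence time and in rate
  taus <- seq(0, 300, by = 30)
  fr <- vapply(taus, function(t) attenuate(0.53, 2.97, t)$fraction_removed_pct,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("summer and winter attenuation match the published rounding chain", {
  summer <- attenuate(0.53, 2.97, residence_time(reach_scenario(4000, 20, 1, 50)))
  winter <- attenuate(0.53, 2.97, residence_time(reach_scenario(4000, 20, 1, 10)))
  expect_equal(summer$removed_um, 0.055)
  expect_equal(winter$removed_um, 0.275)
  # raw fractions
  expect_equal(summer$fraction_removed_pct, 100 * 0.055 / 0.53)
  expect_equal(round(winter$fraction_removed_pct, 1), 51.9)
  # rounding the removed mass to 2 d.p. before the ratio gives 11 and 53
  expect_equal(round(summer$fraction_removed_pct_rounded), 11)
  expect_equal(round(winter$fraction_removed_pct_rounded), 53)
})

test_that("oxidation/emission comparison demands an explicit unit scale", {
  expect_error(oxidation_vs_emission(157.5, 63), "scale")
  expect_equal(oxidation_vs_emission(157.5, 63, scale = "umol_m2_d"), 2.5)
  expect_equal(oxidation_vs_emission(63, 63, scale = "umol_m2_d"), 1)
  expect_identical(oxidation_vs_emission(0, 63, scale = "mmol_m2_d"), 0)
  expect_error(oxidation_vs_emission(1, 0, scale = "umol_m2_d"), "positive")
})
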