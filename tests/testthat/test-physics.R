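# Closed-form physics: psychrometrics, latent heat, transfer correlations.

test_that("saturation vapor pressure matches steam tables and is monotone", {
  expect_equal(saturation_vapor_pressure(0), 611, tolerance = 0.01)
  expect_equal(saturation_vapor_pressure(16), 1820, tolerance = 0.01)
  # independent steam-table oracle, within 1% over the precooling range
  rel <- abs(saturation_vapor_pressure(steam_table$t_c) - steam_table$psat_pa) /
    steam_table$psat_pa
  expect_lt(max(rel), 0.01)
  tt <- seq(-5, 35, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(tt)) > 0))
  expect_error(saturation_vapor_pressure(-240), "degC")
})

test_that("latent heat takes kelvin: steam-table agreement disambiguates the unit", {
  expect_equal(latent_heat(273.15), 2.50e6, tolerance = 1e-3)
  expect_equal(latent_heat(289.15), 2.46e6, tolerance = 2e-3)
  t_k <- steam_table$t_c + 273.15
  rel_kelvin <- abs(latent_heat(t_k) - steam_table$hfg_j_kg) / steam_table$hfg_j_kg
  expect_lt(max(rel_kelvin), 0.01)
  # evaluating the same polynomial at Celsius temperatures misses by > 50%
  rel_celsius <- abs(suppressWarnings(latent_heat(steam_table$t_c)) -
                       steam_table$hfg_j_kg) / steam_table$hfg_j_kg
  expect_gt(min(rel_celsius), 0.5)
  # decreasing on the operating range
  expect_lt(latent_heat(289.15), latent_heat(273.15))
  expect_warning(latent_heat(400), "range")
})

test_that("surface and ambient vapor pressures follow VPL and RH", {
  fruit <- fruit_properties(vpl = 1)
  env_sat <- environment_conditions(rh = 1)
  vp <- vapor_pressures(10, 10, fruit, env_sat)
  expect_equal(vp$ps, vp$pa)
  vp2 <- vapor_pressures(16, 1, fruit_properties(vpl = 0.99),
                         environment_conditions(rh = 0.8))
  expect_equal(vp2$ps, 1.80e3, tolerance = 0.01)
  expect_equal(vp2$pa, 0.8 * saturation_vapor_pressure(1))
  env_dry <- environment_conditions(rh = 0)
  expect_identical(vapor_pressures(16, 1, fruit, env_dry)$pa, 0)
  # bounded by saturation
  expect_lte(vp2$ps, saturation_vapor_pressure(16))
})

test_that("Sherwood correlation has the stagnant-film limit and power-law scaling", {
  air <- air_properties()
  still <- boundary_layer_transfer(air, u = 0, d = 0.03)
  expect_identical(still$Re, 0)
  expect_equal(still$Sh, 2)
  expect_equal(still$km, 2 * air$D_wv / 0.03)

  u54 <- 54 * air$mu_a / (air$rho_a * 0.03)   # velocity giving Re = 54
  b <- boundary_layer_transfer(air, u54, 0.03)
  expect_equal(b$Re, 54, tolerance = 1e-12)
  expect_equal(b$Sc, 0.605, tolerance = 0.01)
  expect_equal(b$Sh, 2 + 0.522 * 54^0.53 * b$Sc^0.33, tolerance = 1e-12)
  expect_equal(b$Sh, 5.7, tolerance = 0.01)

  b2 <- boundary_layer_transfer(air, 2 * u54, 0.03)
  expect_equal((b2$Sh - 2) / (b$Sh - 2), 2^0.53, tolerance = 1e-10)
  # kg_conv is proportional to km
  expect_equal(b2$kg_conv / b$kg_conv, b2$km / b$km, tolerance = 1e-12)
  expect_error(boundary_layer_transfer(air, 1, d = 0), "d must be")
})

test_that("series mass-transfer resistance is harmonic and bounded", {
  expect_equal(total_mass_transfer_coeff(3.3e-8, Inf), 3.3e-8)
  expect_equal(total_mass_transfer_coeff(4e-8, 4e-8), 2e-8)
  expect_equal(total_mass_transfer_coeff(3.3e-8, 5.5e-8), 2.0625e-8,
               tolerance = 1e-3)
  # property sweep: kg <= min of the two resistances for any positive inputs
  set.seed(11)
  a <- 10^stats::runif(200, -9, -6)
  b <- 10^stats::runif(200, -9, -6)
  expect_true(all(total_mass_transfer_coeff(a, b) <= pmin(a, b)))
  expect_error(total_mass_transfer_coeff(-1e-8, 1e-8), "positive")
})

test_that("transpiration flux follows the driving force and clamps by default", {
  expect_identical(transpiration_flux(2e-8, 500, 500), 0)
  expect_equal(transpiration_flux(2e-8, 800, 500), 6e-6)
  expect_identical(transpiration_flux(0, 800, 500), 0)
  expect_identical(transpiration_flux(2e-8, 400, 500), 0)           # clamped
  expect_equal(transpiration_flux(2e-8, 400, 500, signed = TRUE), -2e-6)
  expect_equal(evaporative_heat_flux(6e-6, 2.5e6), 15)
  expect_equal(evaporative_heat_flux(0, 2.5e6), 0)
  expect_equal(evaporative_heat_flux(2 * 6e-6, 2.5e6),
               2 * evaporative_heat_flux(6e-6, 2.5e6))
})

test_that("heat-mass analogy htc has the conduction limit and grows with u", {
  air <- air_properties()
  expect_equal(convective_htc(air, 0, 0.03), 2 * air$k_a / 0.03)
  u54 <- 54 * air$mu_a / (air$rho_a * 0.03)
  expect_equal(convective_htc(air, u54, 0.03), 4.7, tolerance = 0.02)
  uu <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(convective_htc(air, uu, 0.03)) > 0))
})

test_that("moisture_transfer_state chains consistently", {
  st <- moisture_transfer_state(air_properties(), fruit_properties(),
                                environment_conditions(), u = 0.024,
                                t_surface_c = 16, t_air_c = 1)
  expect_gte(st$Sh, 2)
  expect_lte(st$kg, min(st$kg_conv, fruit_properties()$kg_skin))
  expect_equal(st$mdot, st$kg * (st$ps - st$pa))
  expect_equal(st$ps, 0.99 * st$pw)
  expect_gt(st$L, 2.4e6)
})
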