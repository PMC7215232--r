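# Cooling simulator: conduction oracles, zone balances, conservation and
# qualitative cooling invariants.

test_that("sphere solver matches the analytic prescribed-surface series", {
  fruit <- fruit_properties()
  alpha <- fruit$k_p / (fruit$rho_p * fruit$cp_p)
  times <- seq(0, 10800, by = 120)
  sol <- simulate_sphere_cooling(fruit, h = 1e6, t_air_c = 1, t0_c = 16,
                                 times = times, n_shells = 60)
  fo <- alpha * times / (fruit$d / 2)^2
  keep <- times >= 300                       # let the series converge
  exact_center <- 1 + 15 * sphere_center_theta(fo[keep])
  expect_lt(max(abs(sol$center[keep] - exact_center)), 0.2)
  exact_mean <- 1 + 15 * sphere_mean_theta(fo[keep])
  expect_lt(max(abs(sol$mass_avg[keep] - exact_mean)), 0.2)
})

test_that("low-Biot cooling matches the lumped-capacitance limit within 2%", {
  fruit <- fruit_properties()
  h <- 1                                     # Bi = h R / k ~ 0.026
  times <- seq(0, 40000, by = 400)
  sol <- simulate_sphere_cooling(fruit, h = h, t_air_c = 1, t0_c = 16,
                                 times = times, n_shells = 20)
  area <- pi * fruit$d^2
  mass <- fruit$rho_p * pi / 6 * fruit$d^3
  theta_lumped <- exp(-h * area * times / (mass * fruit$cp_p))
  theta_sim <- (sol$mass_avg - 1) / 15
  keep <- theta_lumped > 0.05
  expect_lt(max(abs(theta_sim[keep] - theta_lumped[keep]) / theta_lumped[keep]),
            0.02)
})

test_that("long runs equilibrate to the air temperature", {
  fruit <- fruit_properties()
  times <- seq(0, 2e5, by = 2000)
  sol <- simulate_sphere_cooling(fruit, h = 10, t_air_c = 1, t0_c = 16,
                                 times = times, n_shells = 10)
  expect_lt(abs(utils::tail(sol$center, 1) - 1), 0.01)
  expect_lt(abs(utils::tail(sol$mass_avg, 1) - 1), 0.01)
})

test_that("surface flux splits into convective and latent parts", {
  off <- fruit_surface_flux(289.15, 274.15, h = 4.7, moisture = "off")
  expect_equal(off$convective, 4.7 * 15)
  expect_identical(off$latent, 0)
  expect_identical(off$mdot, 0)

  # isothermal transpiration: no convection, pure evaporative cooling
  iso <- fruit_surface_flux(280.15, 280.15, h = 4.7, moisture = "on", u = 0.02)
  expect_equal(iso$convective, 0)
  expect_gt(iso$latent, 0)

  on <- fruit_surface_flux(289.15, 274.15, h = 4.7, moisture = "on", u = 0.024)
  st <- moisture_transfer_state(air_properties(), fruit_properties(),
                                environment_conditions(), u = 0.024,
                                t_surface_c = 16, t_air_c = 1)
  expect_equal(on$convective, 70.5)
  expect_equal(on$latent, st$mdot * st$L)
  expect_equal(on$mdot, st$mdot)
})

test_that("air zone balance is zero at equilibrium and convex in between", {
  # no fruit heat, inflow at zone temperature: nothing changes
  expect_equal(air_zone_balance(5, 5, 1e-4, 0), 0)
  # steady state with one fruit lies strictly between inlet and surface temps
  h <- 4.7; area <- 2.83e-3; ts <- 14; tin <- 1; flow <- 2e-4
  air <- air_properties()
  f <- function(ta) air_zone_balance(ta, tin, flow, h * area * (ts - ta), air)
  ta_star <- stats::uniroot(f, c(tin, ts))$root
  expect_gt(ta_star, tin)
  expect_lt(ta_star, ts)
  # warmer inflow raises the derivative
  expect_gt(air_zone_balance(5, 8, 1e-4, 0), 0)
  expect_error(air_zone_balance(5, 5, 1e-4, 0, volume = 0), "volume")
})

test_that("zonal runs conserve energy and cool monotonically", {
  for (nm in c("IPAS", "MPAS")) {
    res <- run_design(nm, duration = 10800, out_interval = 60)
    expect_lt(energy_residual(res), 0.005)
    after <- res$times > 60
    for (z in seq_len(ncol(res$mass_avg))) {
      expect_true(all(diff(res$mass_avg[after, z]) <= 1e-9), label = nm)
    }
    # air temperatures bounded by inlet and the warmest upstream fruit
    expect_true(all(res$air >= std_env$t_air_in - 1e-6))
    expect_true(all(res$air <= std_env$t_product_0 + 1e-6))
  }
})

test_that("moisture-on cooling is pointwise faster and shortens the 7/8 time", {
  off <- run_design("IPAS", duration = 36000, out_interval = 120)
  on <- run_design("IPAS", duration = 36000, out_interval = 120,
                   moisture = "on")
  expect_true(all(on$mass_avg <= off$mass_avg + 1e-9))
  for (p in c("p1", "p2")) {
    expect_lt(t78_of(on, p), t78_of(off, p))
  }
  expect_lt(energy_residual(on), 0.005)
  # latent term contributes nothing to a moisture-off budget
  expect_identical(max(abs(off$energy$e_latent)), 0)
})

test_that("a package granted more flow at equal inlet temperature cools no slower", {
  d <- load_design("PAS")
  d$splits$package <- c(p1 = 0.42, p2 = 0.58)
  d$splits$first_half <- c(p1 = 0.5, p2 = 0.5)
  res <- simulate_cooling(d, config = simulation_config(duration = 36000,
                                                        out_interval = 120))
  expect_lte(t78_of(res, "p2"), t78_of(res, "p1"))
})

test_that("doubling the radial resolution moves the 7/8 time by < 1%", {
  t78 <- sapply(c(10, 20), function(n) {
    res <- simulate_cooling(load_design("ARP-M1"),
                            config = simulation_config(duration = 36000,
                                                       out_interval = 120,
                                                       n_shells = n))
    t78_of(res, "p1")
  })
  expect_lt(abs(t78[2] - t78[1]) / t78[1], 0.01)
})

test_that("transported-humidity mode conserves energy and tempers evaporation", {
  fixed <- run_design("IPAS", duration = 10800, out_interval = 120,
                      moisture = "on")
  transported <- run_design("IPAS", duration = 10800, out_interval = 120,
                            moisture = "on", humidity_mode = "transported")
  expect_lt(energy_residual(transported), 0.005)
  # downstream air humidifies, so less moisture leaves the fruit overall
  expect_lt(cumulative_moisture_loss(transported)$grams,
            cumulative_moisture_loss(fixed)$grams)
})

test_that("configuration and environment inputs are validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(duration = -1), "duration")
  expect_error(simulation_config(n_shells = 0), "n_shells")
  expect_error(environment_conditions(rh = 1.2), "rh")
  expect_error(environment_conditions(t_air_in = 20), "cooling")
  expect_error(fruit_properties(vpl = 1.5), "vpl")
  expect_error(air_properties(rho_a = -1), "positive")
})
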