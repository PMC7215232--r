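# Zonal cooling simulator: 1-D radial-conduction fruit spheres coupled to
# well-mixed air zones chained along the flow path. The surface boundary
# condition carries convection plus, when the moisture flag is on, the
# evaporative sink mdot*L of the transpiration submodel.

#' Simulation configuration
#'
#' @param duration Run length (s). Default 10800 s (3 h).
#' @param out_interval Output sampling interval (s).
#' @param n_shells Radial shells per fruit sphere, >= 1.
#' @param rtol,atol Integrator tolerances (deSolve lsoda).
#' @param moisture `"on"` or `"off"`: include the transpiration term in the
#'   fruit surface boundary condition.
#' @param humidity_mode `"fixed-rh"` evaluates the ambient vapor pressure as
#'   `RH * pw(T_zone)`; `"transported"` adds a vapor mass balance per zone.
#' @param seed Reserved; the simulation itself is deterministic.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(duration = 10800, out_interval = 30,
                              n_shells = 10, rtol = 1e-7, atol = 1e-7,
                              moisture = c("off", "on"),
                              humidity_mode = c("fixed-rh", "transported"),
                              seed = NULL) {
  moisture <- match.arg(moisture)
  humidity_mode <- match.arg(humidity_mode)
  if (duration <= 0) stop("duration must be > 0")
  if (n_shells < 1) stop("n_shells must be >= 1")
  structure(list(duration = duration, out_interval = out_interval,
                 n_shells = as.integer(n_shells), rtol = rtol, atol = atol,
                 moisture = moisture, humidity_mode = humidity_mode,
                 seed = seed),
            class = "simulation_config")
}

# finite-volume radial grid of a sphere of diameter d with N equal shells
.sphere_grid <- function(d, n) {
  r_edge <- seq(0, d / 2, length.out = n + 1)
  list(dr = (d / 2) / n,
       a_edge = 4 * pi * r_edge[-1]^2,                      # outward face areas
       vol = 4 / 3 * pi * diff(r_edge^3))
}

# Solve the surface temperature from flux continuity at the outer face:
#   2 k / dr (T_N - Ts) = h (Ts - Ta) + mdot(Ts) L(Ts)
# Newton in Ts; with moisture off the problem is linear.
.surface_temp <- function(tN, ta, h, fruit, kg, pa, moisture) {
  cond <- 2 * fruit$k_p / attr(kg, "dr")
  if (!moisture) {
    return((cond * tN + h * ta) / (cond + h))
  }
  ts <- (cond * tN + h * ta) / (cond + h)
  for (i in 1:6) {
    pw <- saturation_vapor_pressure(ts)
    drive <- fruit$vpl * pw - pa
    active <- drive > 0
    mdot <- ifelse(active, c(kg) * drive, 0)
    L <- latent_heat(ts + 273.15)
    g <- cond * (tN - ts) - h * (ts - ta) - mdot * L
    dpw <- pw * 3990.5 / (ts + 233.833)^2
    dmdot <- ifelse(active, c(kg) * fruit$vpl * dpw, 0)
    dL <- 18.2 * (ts + 273.15) - 7512.9
    gp <- -cond - h - (dmdot * L + mdot * dL)
    ts <- ts - g / gp
  }
  ts
}

#' Simulate the cooling of a packaged tray
#'
#' Integrates the coupled product/air energy balances: each zone holds
#' identical fruit spheres solved by 1-D radial conduction, exchanging heat
#' with one well-mixed air volume; zones are chained along the design's flow
#' path (fresh cold-room air plus, for IPAS, a warm stream from package 1).
#' With `config$moisture = "on"` the fruit surface condition includes the
#' evaporative sink `mdot * L` fed by the transpiration chain.
#'
#' @param design A `tray_design`.
#' @param flow A `flow_solution`; default solves prescribed mode at the
#'   environment's specific airflow rate.
#' @param fruit,air,env Property objects; see [fruit_properties()],
#'   [air_properties()], [environment_conditions()].
#' @param config A [simulation_config()].
#' @return A `cooling_simulation` object: `times` (s), per-zone matrices
#'   `center`, `surface`, `mass_avg`, `air`, `mdot` (kg s-1 m-2),
#'   `moisture_cum` (kg per fruit), an `energy` audit data frame, and the
#'   echoed inputs.
#' @export
#' @examples
#' \donttest{
#' res <- simulate_cooling(load_design("IPAS"),
#'                         config = simulation_config(duration = 3600))
#' tail(res$energy$residual, 1)    # conservation audit
#' }
simulate_cooling <- function(design, flow = NULL,
                             fruit = fruit_properties(),
                             air = air_properties(),
                             env = environment_conditions(),
                             config = simulation_config()) {
  stopifnot(inherits(design, "tray_design"))

  # per-fruit geometry and zone loading
  m_f <- fruit$rho_p * pi / 6 * fruit$d^3
  zone_mass_nominal <- design$geometry$package_mass / 2
  n_fruit <- max(1L, round(zone_mass_nominal / m_f))
  a_f <- pi * fruit$d^2

  if (is.null(flow)) {
    total_mass <- 4 * n_fruit * m_f
    flow <- solve_flow_network(design, total_airflow(env$specific_airflow, total_mass))
  }
  zones <- flow$zones
  nz <- nrow(zones)
  nsh <- config$n_shells
  moisture_on <- config$moisture == "on"
  transported <- config$humidity_mode == "transported"

  grid <- .sphere_grid(fruit$d, nsh)
  h_z <- vapply(zones$u, function(u) convective_htc(air, u, fruit$d), numeric(1))
  kg_z <- vapply(zones$u, function(u) {
    blt <- boundary_layer_transfer(air, u, fruit$d)
    total_mass_transfer_coeff(blt$kg_conv, fruit$kg_skin)
  }, numeric(1))
  attr(kg_z, "dr") <- grid$dr
  vol_z <- design$geometry$zone_air_volume
  rho_cp_flow <- air$rho_a * air$cp_a
  W <- flow$warm_matrix                    # [receiver, source] inter-zone flows
  if (is.null(W)) W <- matrix(0, nz, nz)
  pa_cold <- env$rh * saturation_vapor_pressure(env$t_air_in)
  rv_const <- 8.314462 / air$M_h2o                      # specific gas constant of vapor

  idxT <- matrix(seq_len(nz * nsh), nrow = nz, byrow = TRUE)
  iAir <- nz * nsh + seq_len(nz)
  iML <- nz * nsh + nz + seq_len(nz)
  iEa <- nz * nsh + 2 * nz + 1
  iEl <- iEa + 1
  iPa <- if (transported) iEl + seq_len(nz) else integer(0)

  y0 <- c(rep(env$t_product_0, nz * nsh), rep(env$t_air_in, nz), rep(0, nz), 0, 0,
          if (transported) rep(pa_cold, nz))

  rhs <- function(t, y, parms) {
    Tm <- matrix(y[1:(nz * nsh)], nrow = nz, byrow = TRUE)
    ta <- y[iAir]
    pa <- if (transported) y[iPa] else env$rh * saturation_vapor_pressure(ta)
    tN <- Tm[, nsh]
    ts <- .surface_temp(tN, ta, h_z, fruit, kg_z, pa, moisture_on)
    mdot <- if (moisture_on) {
      transpiration_flux(kg_z, fruit$vpl * saturation_vapor_pressure(ts), pa)
    } else rep(0, nz)
    L <- latent_heat(ts + 273.15)
    q_surf <- h_z * (ts - ta) + mdot * L                  # W m-2 leaving the fruit

    dT <- matrix(0, nz, nsh)
    if (nsh > 1) {
      cond <- fruit$k_p * (Tm[, -nsh, drop = FALSE] - Tm[, -1, drop = FALSE]) / grid$dr
      qface <- sweep(cond, 2, grid$a_edge[-nsh], `*`)     # W across internal faces
      dT[, 1] <- -qface[, 1]
      if (nsh > 2) {
        dT[, 2:(nsh - 1)] <- qface[, 1:(nsh - 2), drop = FALSE] -
          qface[, 2:(nsh - 1), drop = FALSE]
      }
      dT[, nsh] <- qface[, nsh - 1] - q_surf * grid$a_edge[nsh]
    } else {
      dT[, 1] <- -q_surf * grid$a_edge[nsh]
    }
    dT <- sweep(dT, 2, fruit$rho_p * fruit$cp_p * grid$vol, `/`)

    adv <- rho_cp_flow * (zones$fresh_flow * (env$t_air_in - ta) +
                            as.numeric(W %*% ta) - zones$warm_flow * ta)
    conv <- n_fruit * h_z * a_f * (ts - ta)
    dTa <- (adv + conv) / (air$rho_a * vol_z * air$cp_a)

    dML <- mdot * a_f
    dEa <- sum(rho_cp_flow * zones$to_fan_flow * (ta - env$t_air_in))
    dEl <- sum(n_fruit * mdot * L * a_f)

    dy <- numeric(length(y))
    dy[1:(nz * nsh)] <- as.numeric(t(dT))
    dy[iAir] <- dTa
    dy[iML] <- dML
    dy[iEa] <- dEa
    dy[iEl] <- dEl
    if (transported) {
      dy[iPa] <- (zones$fresh_flow * (pa_cold - pa) +
                    as.numeric(W %*% pa) - zones$warm_flow * pa) / vol_z +
        n_fruit * mdot * a_f * rv_const * (ta + 273.15) / vol_z
    }
    list(dy)
  }

  times <- seq(0, config$duration, by = config$out_interval)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = config$rtol, atol = config$atol)
  if (attr(sol, "istate")[1] < 0) stop("integrator failed to converge")
  sol <- as.matrix(sol)

  Tarr <- sol[, 1 + 1:(nz * nsh), drop = FALSE]
  air_T <- sol[, 1 + iAir, drop = FALSE]
  ml <- sol[, 1 + iML, drop = FALSE]
  colnames(air_T) <- colnames(ml) <- zones$zone

  w <- grid$vol / sum(grid$vol)
  center <- mass_avg <- surface <- mdot_m <- matrix(0, length(times), nz,
                                                    dimnames = list(NULL, zones$zone))
  for (z in seq_len(nz)) {
    Tz <- Tarr[, (z - 1) * nsh + seq_len(nsh), drop = FALSE]
    center[, z] <- Tz[, 1]
    mass_avg[, z] <- as.numeric(Tz %*% w)
    pa_t <- if (transported) sol[, 1 + iPa[z]] else
      env$rh * saturation_vapor_pressure(air_T[, z])
    kgz <- kg_z[z]
    attr(kgz, "dr") <- grid$dr
    ts <- .surface_temp(Tz[, nsh], air_T[, z], h_z[z], fruit, kgz, pa_t, moisture_on)
    surface[, z] <- ts
    mdot_m[, z] <- if (moisture_on) {
      transpiration_flux(kg_z[z], fruit$vpl * saturation_vapor_pressure(ts), pa_t)
    } else 0
  }

  # moisture on: evaporative cooling at sub-saturated RH can undercool the
  # fruit below the dry-bulb inlet temperature (toward the wet-bulb floor),
  # so the lower sanity bound is widened accordingly
  band <- c(env$t_air_in - if (moisture_on) 5 else 0.5, env$t_product_0 + 0.5)
  if (min(Tarr) < band[1] || max(Tarr) > band[2]) {
    stop(sprintf(
      "fruit temperature left the physical band [%.2f, %.2f] degC (range %.2f..%.2f)",
      band[1], band[2], min(Tarr), max(Tarr)))
  }

  e_fruit <- rowSums(sweep(env$t_product_0 - mass_avg, 2,
                           n_fruit * m_f * fruit$cp_p, `*`))
  e_air_store <- rowSums(sweep(air_T - env$t_air_in, 2,
                               air$rho_a * vol_z * air$cp_a, `*`))
  energy <- data.frame(
    time = times,
    e_fruit = e_fruit,
    e_air_out = sol[, 1 + iEa],
    e_air_storage = e_air_store,
    e_latent = sol[, 1 + iEl]
  )
  energy$residual <- abs(energy$e_fruit - energy$e_air_out -
                           energy$e_air_storage - energy$e_latent) /
    pmax(energy$e_fruit, 1e-9)

  structure(list(
    times = times,
    zones = cbind(zones, n_fruit = n_fruit, h = h_z, kg = as.numeric(kg_z)),
    center = center, surface = surface, mass_avg = mass_avg,
    air = air_T, mdot = mdot_m, moisture_cum = ml,
    energy = energy,
    fruit_mass = m_f, fruit_area = a_f, n_fruit = n_fruit,
    design = design, flow = flow, config = config,
    fruit = fruit, air_props = air, env = env
  ), class = "cooling_simulation")
}

#' Surface heat fluxes of a fruit sphere
#'
#' Splits the fruit-surface boundary condition into its convective part
#' `h (Ts - Ta)` and, with moisture on, the evaporative part `mdot L` from
#' the transpiration chain at superficial velocity `u`.
#'
#' @param ts_k Fruit surface temperature (K).
#' @param ta_k Zone air temperature (K).
#' @param h Convective coefficient (W m-2 K-1), >= 0.
#' @param moisture `"on"` or `"off"`.
#' @param fruit,air,env Property objects.
#' @param u Zone superficial velocity (m s-1), feeds the film coefficient.
#' @return List: `convective` (W m-2), `latent` (W m-2), `mdot` (kg s-1 m-2).
#' @export
fruit_surface_flux <- function(ts_k, ta_k, h, moisture = c("off", "on"),
                               fruit = fruit_properties(),
                               air = air_properties(),
                               env = environment_conditions(), u = 0) {
  moisture <- match.arg(moisture)
  if (any(h < 0)) stop("h must be >= 0")
  convective <- h * (ts_k - ta_k)
  if (moisture == "off") {
    return(list(convective = convective, latent = 0 * convective,
                mdot = 0 * convective))
  }
  st <- moisture_transfer_state(air, fruit, env, u,
                                t_surface_c = ts_k - 273.15,
                                t_air_c = ta_k - 273.15)
  list(convective = convective,
       latent = evaporative_heat_flux(st$mdot, st$L),
       mdot = st$mdot)
}

#' Air-zone energy balance
#'
#' Rate of change of a well-mixed zone's air temperature:
#' `rho_a V cp_a dTa/dt = sum(m_in cp_a (T_in - Ta)) + sum(h A (Ts - Ta))`.
#'
#' @param ta_c Zone air temperature (degC).
#' @param inflow_temps_c Temperatures of the inflow streams (degC).
#' @param inflow_flows Volumetric flows of the streams (m3 s-1), >= 0.
#' @param fruit_heat_w Net convective heat from the fruit into the air (W).
#' @param air An [air_properties()] object.
#' @param volume Zone air volume (m3), > 0.
#' @return dTa/dt (K s-1).
#' @export
air_zone_balance <- function(ta_c, inflow_temps_c, inflow_flows, fruit_heat_w,
                             air = air_properties(),
                             volume = .def("geometry", "zone_air_volume")) {
  if (volume <= 0) stop("zone air volume must be > 0")
  if (any(inflow_flows < 0)) stop("inflow_flows must be >= 0")
  adv <- sum(air$rho_a * air$cp_a * inflow_flows * (inflow_temps_c - ta_c))
  (adv + fruit_heat_w) / (air$rho_a * volume * air$cp_a)
}

#' Energy-conservation residual of a run
#'
#' Relative gap between the enthalpy lost by the fruit and the sum of air
#' enthalpy carried to the fan, air storage, and latent heat removed, at the
#' end of the run.
#'
#' @param result A `cooling_simulation`.
#' @return Dimensionless relative residual.
#' @export
energy_residual <- function(result) {
  stopifnot(inherits(result, "cooling_simulation"))
  utils::tail(result$energy$residual, 1)
}

#' Single sphere in a fixed air stream
#'
#' Convenience wrapper solving one radial-conduction fruit sphere with a
#' prescribed, constant air temperature and convective coefficient; used for
#' benchmark comparisons against analytic conduction solutions.
#'
#' @param fruit A [fruit_properties()] object.
#' @param h Convective coefficient (W m-2 K-1).
#' @param t_air_c Constant air temperature (degC).
#' @param t0_c Initial uniform fruit temperature (degC).
#' @param times Output times (s).
#' @param n_shells Radial shells.
#' @param moisture,air,env,u Passed to the surface model when moisture is on.
#' @param rtol,atol Integrator tolerances.
#' @return List: `times`, `center`, `surface`, `mass_avg` vectors.
#' @export
simulate_sphere_cooling <- function(fruit, h, t_air_c, t0_c, times,
                                    n_shells = 10,
                                    moisture = c("off", "on"),
                                    air = air_properties(),
                                    env = environment_conditions(),
                                    u = 0, rtol = 1e-8, atol = 1e-8) {
  moisture <- match.arg(moisture)
  moisture_on <- moisture == "on"
  grid <- .sphere_grid(fruit$d, n_shells)
  kg <- if (moisture_on) {
    blt <- boundary_layer_transfer(air, u, fruit$d)
    total_mass_transfer_coeff(blt$kg_conv, fruit$kg_skin)
  } else 0
  attr(kg, "dr") <- grid$dr
  pa <- env$rh * saturation_vapor_pressure(t_air_c)
  nsh <- n_shells
  rhs <- function(t, y, p) {
    ts <- .surface_temp(y[nsh], t_air_c, h, fruit, kg, pa, moisture_on)
    mdot <- if (moisture_on) {
      transpiration_flux(kg, fruit$vpl * saturation_vapor_pressure(ts), pa)
    } else 0
    q_surf <- h * (ts - t_air_c) + mdot * latent_heat(ts + 273.15)
    dT <- numeric(nsh)
    if (nsh > 1) {
      qface <- fruit$k_p * (y[-nsh] - y[-1]) / grid$dr * grid$a_edge[-nsh]
      dT[1] <- -qface[1]
      if (nsh > 2) dT[2:(nsh - 1)] <- qface[1:(nsh - 2)] - qface[2:(nsh - 1)]
      dT[nsh] <- qface[nsh - 1] - q_surf * grid$a_edge[nsh]
    } else {
      dT[1] <- -q_surf * grid$a_edge[nsh]
    }
    list(dT / (fruit$rho_p * fruit$cp_p * grid$vol))
  }
  sol <- deSolve::ode(rep(t0_c, nsh), times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  Tm <- as.matrix(sol)[, -1, drop = FALSE]
  w <- grid$vol / sum(grid$vol)
  ts <- vapply(seq_along(times), function(i) {
    .surface_temp(Tm[i, nsh], t_air_c, h, fruit, kg, pa, moisture_on)
  }, numeric(1))
  list(times = times, center = Tm[, 1], surface = ts,
       mass_avg = as.numeric(Tm %*% w))
}

#' @export
print.cooling_simulation <- function(x, ...) {
  cat(sprintf("Cooling simulation: %s, %s mode flow, moisture %s\n",
              x$design$name, x$flow$mode, x$config$moisture))
  cat(sprintf("  %d zones x %d fruits, %d shells, %.0f s run\n",
              nrow(x$zones), x$n_fruit, x$config$n_shells,
              utils::tail(x$times, 1)))
  fin <- utils::tail(x$mass_avg, 1)
  cat(sprintf("  final mass-average temps: %s degC\n",
              paste(sprintf("%s %.2f", colnames(x$mass_avg), fin), collapse = ", ")))
  cat(sprintf("  energy residual %.3g\n", energy_residual(x)))
  invisible(x)
}
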