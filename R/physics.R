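# Closed-form physics of the transpiration (moisture-loss) submodel:
# psychrometrics, latent heat, film/skin mass-transfer resistances and the
# Sherwood-Reynolds-Schmidt correlation. All functions are pure; internal
# temperature convention is kelvin, each formula converting at its boundary.

.C2K <- 273.15

#' Saturation water vapor pressure
#'
#' Magnus-type correlation `pw = exp(23.4795 - 3990.5 / (T + 233.833))` with
#' temperature in degrees Celsius. Agrees with steam tables to well under 1%
#' over the precooling range (0-30 degC).
#'
#' @param t_c Temperature (degC). Vectorised.
#' @return Saturation pressure (Pa).
#' @export
#' @examples
#' saturation_vapor_pressure(0)    # ~611 Pa
#' saturation_vapor_pressure(16)   # ~1819 Pa
saturation_vapor_pressure <- function(t_c) {
  denom <- t_c + 233.833
  if (any(denom <= 0)) {
    stop("saturation_vapor_pressure: temperature at or below -233.833 degC")
  }
  exp(23.4795 - 3990.5 / denom)
}

#' Latent heat of evaporation of water
#'
#' Quadratic correlation `L = 9.1 T^2 - 7512.9 T + 3875.1e3` with temperature
#' in kelvin; gives 2.502 MJ/kg at 0 degC, matching steam tables. The vertex
#' of the parabola lies above the physical range, so L is decreasing in T
#' throughout.
#'
#' @param t_k Temperature (K). A warning is issued outside 260-380 K.
#' @return Latent heat (J kg-1).
#' @export
#' @examples
#' latent_heat(273.15) / 1e6   # ~2.50 MJ/kg
latent_heat <- function(t_k) {
  if (any(t_k < 260) || any(t_k > 380)) {
    warning("latent_heat: temperature outside physical range 260-380 K")
  }
  9.1 * t_k^2 - 7512.9 * t_k + 3875.1e3
}

#' Surface and ambient water vapor pressures
#'
#' Surface pressure is saturation at the surface temperature depressed by the
#' fruit's vapor-pressure-lowering factor; ambient pressure is saturation at
#' the air temperature scaled by relative humidity.
#'
#' @param t_surface_c Fruit surface temperature (degC).
#' @param t_air_c Air temperature (degC).
#' @param fruit A [fruit_properties()] object (supplies `vpl`).
#' @param env An [environment_conditions()] object (supplies `rh`).
#' @return Named list with `ps` and `pa` (Pa).
#' @export
vapor_pressures <- function(t_surface_c, t_air_c, fruit, env) {
  list(ps = fruit$vpl * saturation_vapor_pressure(t_surface_c),
       pa = env$rh * saturation_vapor_pressure(t_air_c))
}

#' Boundary-layer mass transfer around a sphere
#'
#' Sherwood-Reynolds-Schmidt correlation `Sh = 2 + 0.522 Re^0.53 Sc^0.33`
#' (coefficients configurable through the defaults file), from which the film
#' coefficient `km = Sh D / d` (m s-1) and its pressure-based form
#' `kg_conv = rho_a M_h2o / (M_a p_atm) km` (s m-1) follow. At `u = 0` the
#' correlation collapses to the stagnant-film diffusion limit `Sh = 2`.
#'
#' @param air An [air_properties()] object.
#' @param u Superficial air velocity (m s-1), >= 0.
#' @param d Characteristic length / sphere diameter (m), > 0.
#' @return Named list: `Re`, `Sc`, `Sh`, `km` (m s-1), `kg_conv` (s m-1).
#' @export
#' @examples
#' blt <- boundary_layer_transfer(air_properties(), u = 0.0239, d = 0.03)
#' blt$Re   # ~54, the in-package flow regime
#' blt$Sh   # ~5.7
boundary_layer_transfer <- function(air, u, d) {
  if (d <= 0) stop("boundary_layer_transfer: d must be > 0")
  if (any(u < 0)) stop("boundary_layer_transfer: u must be >= 0")
  Re <- air$rho_a * u * d / air$mu_a
  Sc <- air$mu_a / (air$rho_a * air$D_wv)
  Sh <- 2 + .def("correlation", "sh_coeff") *
    Re^.def("correlation", "re_exp") * Sc^.def("correlation", "sc_exp")
  km <- Sh * air$D_wv / d
  kg_conv <- (air$rho_a * air$M_h2o) / (air$M_a * air$p_atm) * km
  list(Re = Re, Sc = Sc, Sh = Sh, km = km, kg_conv = kg_conv)
}

#' Combined surface mass-transfer coefficient
#'
#' Air-film and skin coefficients act as resistances in series:
#' `1/kg = 1/kg_conv + 1/kg_skin`. The result is bounded above by the
#' smaller of the two; an infinite `kg_skin` recovers the film-only value.
#'
#' @param kg_conv Air-film coefficient (s m-1), > 0.
#' @param kg_skin Skin coefficient (s m-1), > 0 or `Inf`.
#' @return Combined coefficient `kg` (s m-1).
#' @export
#' @examples
#' total_mass_transfer_coeff(3.3e-8, 5.5e-8)   # ~2.06e-8
total_mass_transfer_coeff <- function(kg_conv, kg_skin) {
  if (any(kg_conv <= 0) || any(kg_skin <= 0)) {
    stop("total_mass_transfer_coeff: coefficients must be positive")
  }
  1 / (1 / kg_conv + 1 / kg_skin)
}

#' Transpiration mass flux
#'
#' `mdot = kg (ps - pa)`: moisture leaves the fruit in proportion to the
#' vapor-pressure difference across the surface. By default a negative
#' driving force (humid air warmer than the fruit) is clamped to zero flux
#' rather than modelled as condensation; `signed = TRUE` returns the signed
#' value.
#'
#' @param kg Combined mass-transfer coefficient (s m-1), >= 0.
#' @param ps Surface vapor pressure (Pa).
#' @param pa Ambient vapor pressure (Pa).
#' @param signed Keep the sign of `ps - pa`? Default `FALSE` (clamp at 0).
#' @return Mass flux (kg s-1 m-2).
#' @export
transpiration_flux <- function(kg, ps, pa, signed = FALSE) {
  if (any(kg < 0)) stop("transpiration_flux: kg must be >= 0")
  m <- kg * (ps - pa)
  if (!signed) m <- pmax(m, 0)
  m
}

#' Evaporative heat flux at the fruit surface
#'
#' The latent sink `mdot * L` entering the fruit-side boundary condition of
#' the conduction problem.
#'
#' @param mdot Transpiration flux (kg s-1 m-2).
#' @param L Latent heat (J kg-1).
#' @return Heat flux (W m-2).
#' @export
evaporative_heat_flux <- function(mdot, L) mdot * L

#' Convective heat-transfer coefficient (heat-mass analogy)
#'
#' The zonal surrogate has no surface-resolved flow field, so the convective
#' coefficient is obtained by the heat-mass analogy applied to the Sherwood
#' correlation with Prandtl replacing Schmidt:
#' `Nu = 2 + 0.522 Re^0.53 Pr^0.33`, `h = Nu k_a / d`. At `u = 0` this is
#' the pure-conduction limit `h = 2 k_a / d`.
#'
#' @param air An [air_properties()] object.
#' @param u Superficial air velocity (m s-1), >= 0.
#' @param d Sphere diameter (m), > 0.
#' @return h (W m-2 K-1).
#' @export
#' @examples
#' convective_htc(air_properties(), u = 0.0239, d = 0.03)   # ~4.7 W/m2/K
convective_htc <- function(air, u, d) {
  if (d <= 0) stop("convective_htc: d must be > 0")
  if (any(u < 0)) stop("convective_htc: u must be >= 0")
  Re <- air$rho_a * u * d / air$mu_a
  Pr <- air$mu_a * air$cp_a / air$k_a
  Nu <- 2 + .def("correlation", "sh_coeff") *
    Re^.def("correlation", "re_exp") * Pr^.def("correlation", "sc_exp")
  Nu * air$k_a / d
}

#' Full moisture-transfer state at one operating point
#'
#' Convenience chain through the whole transpiration submodel: dimensionless
#' groups, film and combined coefficients, vapor pressures, latent heat and
#' the resulting flux, for a fruit surface at `t_surface_c` in zone air at
#' `t_air_c` moving at `u`.
#'
#' @inheritParams boundary_layer_transfer
#' @param t_surface_c Fruit surface temperature (degC).
#' @param t_air_c Zone air temperature (degC).
#' @param fruit A [fruit_properties()] object.
#' @param env An [environment_conditions()] object.
#' @param signed Passed to [transpiration_flux()].
#' @return `moisture_transfer_state` list: `Re`, `Sc`, `Sh`, `km`, `kg_conv`,
#'   `kg`, `pw`, `ps`, `pa`, `L`, `mdot`.
#' @export
moisture_transfer_state <- function(air, fruit, env, u, t_surface_c, t_air_c,
                                    signed = FALSE) {
  blt <- boundary_layer_transfer(air, u, fruit$d)
  kg <- total_mass_transfer_coeff(blt$kg_conv, fruit$kg_skin)
  vp <- vapor_pressures(t_surface_c, t_air_c, fruit, env)
  L <- latent_heat(t_surface_c + .C2K)
  mdot <- transpiration_flux(kg, vp$ps, vp$pa, signed = signed)
  structure(c(blt, list(kg = kg, pw = saturation_vapor_pressure(t_surface_c),
                        ps = vp$ps, pa = vp$pa, L = L, mdot = mdot)),
            class = "moisture_transfer_state")
}
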