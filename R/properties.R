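#' Thermophysical properties of the cooling air
#'
#' Defaults are dry air at 0 degC, the operating point of a strawberry
#' precooling room.
#'
#' @param rho_a Density (kg m-3).
#' @param mu_a Dynamic viscosity (Pa s).
#' @param cp_a Specific heat (J kg-1 K-1).
#' @param k_a Thermal conductivity (W m-1 K-1).
#' @param D_wv Diffusivity of water vapor in air (m2 s-1).
#' @param M_a Molar mass of air (kg mol-1).
#' @param M_h2o Molar mass of water (kg mol-1).
#' @param p_atm Atmospheric pressure (Pa).
#' @return An `air_properties` object (named list).
#' @export
#' @examples
#' air <- air_properties()
#' air$mu_a / (air$rho_a * air$D_wv)   # Schmidt number ~ 0.6
air_properties <- function(rho_a = .def("air", "rho_a"),
                           mu_a = .def("air", "mu_a"),
                           cp_a = .def("air", "cp_a"),
                           k_a = .def("air", "k_a"),
                           D_wv = .def("air", "D_wv"),
                           M_a = .def("air", "M_a"),
                           M_h2o = .def("air", "M_h2o"),
                           p_atm = .def("air", "p_atm")) {
  obj <- list(rho_a = rho_a, mu_a = mu_a, cp_a = cp_a, k_a = k_a,
              D_wv = D_wv, M_a = M_a, M_h2o = M_h2o, p_atm = p_atm)
  vals <- unlist(obj)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all air properties must be finite and strictly positive")
  }
  structure(obj, class = "air_properties")
}

#' Thermophysical and transpiration properties of the fruit
#'
#' Strawberry flesh conductivity, heat capacity and density, plus the
#' parameters of the transpiration submodel: equivalent sphere diameter,
#' vapor-pressure-lowering factor (VPL) and the skin (cuticle) mass-transfer
#' coefficient acting in series with the boundary-layer film.
#'
#' @param k_p Thermal conductivity (W m-1 K-1).
#' @param cp_p Specific heat (J kg-1 K-1).
#' @param rho_p Density (kg m-3).
#' @param d Equivalent sphere diameter (m).
#' @param vpl Vapor-pressure-lowering factor, 0 < vpl <= 1.
#' @param kg_skin Skin mass-transfer coefficient (s m-1); `Inf` models a
#'   skinless commodity (no cuticular resistance).
#' @return A `fruit_properties` object.
#' @export
fruit_properties <- function(k_p = .def("fruit", "k_p"),
                             cp_p = .def("fruit", "cp_p"),
                             rho_p = .def("fruit", "rho_p"),
                             d = .def("fruit", "d"),
                             vpl = .def("fruit", "vpl"),
                             kg_skin = .def("fruit", "kg_skin")) {
  obj <- list(k_p = k_p, cp_p = cp_p, rho_p = rho_p, d = d,
              vpl = vpl, kg_skin = kg_skin)
  finite <- unlist(obj[c("k_p", "cp_p", "rho_p", "d", "vpl")])
  if (any(!is.finite(finite)) || any(finite <= 0)) {
    stop("fruit properties must be finite and strictly positive")
  }
  if (vpl > 1) stop("vpl must satisfy 0 < vpl <= 1")
  if (is.na(kg_skin) || kg_skin <= 0) {
    stop("kg_skin must be positive (use Inf for no skin resistance)")
  }
  structure(obj, class = "fruit_properties")
}

#' Cooling-run environment
#'
#' @param t_air_in Inlet (cold-room) air temperature (degC).
#' @param rh Relative humidity of the cooling air, fraction in 0..1.
#' @param t_product_0 Initial product temperature (degC).
#' @param specific_airflow Specific airflow rate (L s-1 per kg product).
#' @return An `environment_conditions` object.
#' @export
#' @examples
#' environment_conditions()          # 1 degC / 80% RH / 16 degC / 0.4 L/s/kg
environment_conditions <- function(t_air_in = .def("environment", "t_air_in"),
                                   rh = .def("environment", "rh"),
                                   t_product_0 = .def("environment", "t_product_0"),
                                   specific_airflow = .def("environment", "specific_airflow")) {
  if (rh < 0 || rh > 1) stop("rh must be a fraction in [0, 1]")
  if (specific_airflow < 0) stop("specific_airflow must be >= 0")
  if (t_product_0 <= t_air_in) {
    stop("a cooling run needs t_product_0 > t_air_in")
  }
  structure(list(t_air_in = t_air_in, rh = rh, t_product_0 = t_product_0,
                 specific_airflow = specific_airflow),
            class = "environment_conditions")
}

#' @export
print.air_properties <- function(x, ...) {
  cat("Air properties (dry-air defaults at 0 degC):\n")
  cat(sprintf("  rho %.4g kg/m3, mu %.3g Pa s, cp %.4g J/kg/K, k %.4g W/m/K\n",
              x$rho_a, x$mu_a, x$cp_a, x$k_a))
  cat(sprintf("  D(H2O) %.3g m2/s, M_a %.4g, M_h2o %.4g kg/mol, p %.6g Pa\n",
              x$D_wv, x$M_a, x$M_h2o, x$p_atm))
  invisible(x)
}

#' @export
print.fruit_properties <- function(x, ...) {
  cat("Fruit properties:\n")
  cat(sprintf("  k %.3g W/m/K, cp %.4g J/kg/K, rho %.4g kg/m3, d %.3g m\n",
              x$k_p, x$cp_p, x$rho_p, x$d))
  cat(sprintf("  VPL %.3g, kg_skin %.3g s/m\n", x$vpl, x$kg_skin))
  invisible(x)
}

#' @export
print.environment_conditions <- function(x, ...) {
  cat(sprintf(
    "Cooling environment: air %.3g degC at RH %.0f%%, product starts %.3g degC, %.3g L/s/kg\n",
    x$t_air_in, 100 * x$rh, x$t_product_0, x$specific_airflow))
  invisible(x)
}
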