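# Shared fixtures and independent oracles for the test suite.

# Textbook saturation-pressure (Pa) and latent-heat (J/kg) steam-table
# values, 0-30 degC.
steam_table <- data.frame(
  t_c = c(0, 5, 10, 15, 20, 25, 30),
  psat_pa = c(611.4, 872.5, 1228.2, 1705.7, 2339.2, 3169.8, 4246.6),
  hfg_j_kg = 1e3 * c(2500.9, 2489.1, 2477.2, 2465.4, 2453.5, 2441.7, 2429.8)
)

# Analytic transient conduction in a sphere with prescribed surface
# temperature (infinite Biot): dimensionless center and mass-average
# temperatures as Fourier series in Fo = alpha t / R^2.
sphere_center_theta <- function(fo, n_terms = 80) {
  n <- seq_len(n_terms)
  vapply(fo, function(f) 2 * sum((-1)^(n + 1) * exp(-n^2 * pi^2 * f)), numeric(1))
}
sphere_mean_theta <- function(fo, n_terms = 80) {
  n <- seq_len(n_terms)
  vapply(fo, function(f) 6 / pi^2 * sum(exp(-n^2 * pi^2 * f) / n^2), numeric(1))
}

# Two-layer orifice network (coldroom -> mid_j -> fan) solved independently:
# equal-flow continuity through each branch gives the exact series
# combination Q_j = cd * A1 A2 / sqrt(A1^2 + A2^2) * sqrt(2 (-Pf) / rho),
# and the fan pressure follows in closed form from the total flow.
two_layer_oracle <- function(a_in, a_out, cd, total_flow, rho) {
  k <- cd * a_in * a_out / sqrt(a_in^2 + a_out^2)
  neg_pf <- (total_flow / sum(k))^2 * rho / 2
  k * sqrt(2 * neg_pf / rho)
}

# Build a synthetic tray_design whose vent graph is an arbitrary two-layer
# network, for exercising the orifice solver against the oracle.
make_network_design <- function(a_in, a_out, cd = 0.61) {
  stopifnot(length(a_in) == length(a_out))
  k <- length(a_in)
  zones <- data.frame(
    zone = paste0("z", seq_len(k)),
    package = rep(c("p1", "p2"), length.out = k),
    half = rep(c("first", "second"), length.out = k),
    stringsAsFactors = FALSE
  )
  vents <- data.frame(
    id = c(paste0("in", seq_len(k)), paste0("out", seq_len(k))),
    location = "lateral-exhaust",
    area_m2 = c(a_in, a_out),
    upstream = c(rep("coldroom", k), zones$zone),
    downstream = c(zones$zone, rep("fan", k)),
    cd = cd,
    stringsAsFactors = FALSE
  )
  structure(list(
    name = "NET", description = "synthetic orifice test network",
    zones = zones,
    packages = list(p1 = list(mass_kg = 1), p2 = list(mass_kg = 1)),
    splits = list(package = c(p1 = 0.5, p2 = 0.5),
                  first_half = c(p1 = 0.5, p2 = 0.5)),
    arp = "none", extra_inflows = list(), vents = vents,
    geometry = list(package_surface_area = 0.0833, zone_cross_area = 0.00835,
                    zone_air_volume = 6.25e-4, package_mass = 1)
  ), class = "tray_design")
}

# Minimal cooling_simulation stand-in for metric-level unit tests.
make_fake_result <- function(times, mass_avg, center = mass_avg,
                             n_fruit = rep(1L, ncol(mass_avg)),
                             moisture = "off", moisture_cum = NULL,
                             fruit_mass = 0.0113,
                             env = environment_conditions()) {
  zones <- data.frame(
    zone = colnames(mass_avg),
    package = rep(c("p1", "p2"), each = ncol(mass_avg) / 2),
    half = rep(c("first", "second"), times = ncol(mass_avg) / 2),
    n_fruit = n_fruit,
    stringsAsFactors = FALSE
  )
  if (is.null(moisture_cum)) {
    moisture_cum <- matrix(0, nrow(mass_avg), ncol(mass_avg),
                           dimnames = dimnames(mass_avg))
  }
  structure(list(
    times = times, zones = zones, mass_avg = mass_avg, center = center,
    moisture_cum = moisture_cum, fruit_mass = fruit_mass,
    config = list(moisture = moisture), env = env,
    design = list(name = "FAKE"), flow = list(mode = "prescribed")
  ), class = "cooling_simulation")
}

# Standard study conditions shared by the heavier tests.
std_env <- environment_conditions()
run_design <- function(name, duration = 36000, out_interval = 60,
                       moisture = "off", ...) {
  simulate_cooling(load_design(name),
                   config = simulation_config(duration = duration,
                                              out_interval = out_interval,
                                              moisture = moisture, ...))
}
t78_of <- function(result, package, env = std_env) {
  seven_eighths_cooling_time(package_average_temperature(result, package),
                             result$times, env$t_product_0, env$t_air_in)
}
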