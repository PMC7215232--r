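# Airflow distribution across packages and zones. Prescribed mode replays
# the published split tables (paper-reproduction mode); orifice mode solves
# node pressures on a discharge-coefficient resistance network and is an
# exploratory tool only - it is not expected to reproduce the published
# splits, which came from full CFD.

#' Total volumetric airflow from the specific rate
#'
#' @param specific_rate Specific airflow (L s-1 per kg product).
#' @param product_mass Total product mass (kg).
#' @return Volumetric flow (m3 s-1).
#' @export
#' @examples
#' total_airflow(0.4, 2)   # 8e-4 m3/s
total_airflow <- function(specific_rate, product_mass) {
  if (specific_rate < 0 || product_mass < 0) {
    stop("total_airflow: inputs must be >= 0")
  }
  specific_rate * product_mass / 1000
}

#' Solve the airflow distribution of a tray design
#'
#' In `"prescribed"` mode the design's split table is returned verbatim,
#' scaled by `total_flow`; inter-package extra-vent streams (IPAS) are
#' carried as warm inflows whose temperature is resolved by the simulator.
#' In `"orifice"` mode node pressures are solved so that every vent obeys
#' the orifice law `Q = Cd A sqrt(2 dP / rho)` and mass balances close at
#' every node.
#'
#' @param design A `tray_design`.
#' @param total_flow Total system airflow (m3 s-1), > 0.
#' @param mode `"prescribed"` (default) or `"orifice"`.
#' @param air An [air_properties()] object (orifice mode density).
#' @return A `flow_solution`: mode, total flow, package/first-half fractions,
#'   and a `zones` data frame with per-zone throughput, fresh/warm inflow,
#'   superficial velocity and to-fan flow.
#' @export
#' @examples
#' fs <- solve_flow_network(load_design("IPAS"), total_airflow(0.4, 2))
#' fs$package_fractions    # 0.444 / 0.556
solve_flow_network <- function(design, total_flow,
                               mode = c("prescribed", "orifice"),
                               air = air_properties()) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "tray_design"))
  if (total_flow <= 0) stop("total_flow must be > 0")
  rep <- validate_design(design)
  if (!rep$valid) stop("design fails validation; see validate_design()")
  if (mode == "prescribed") {
    .flow_prescribed(design, total_flow)
  } else {
    .flow_orifice(design, total_flow, air)
  }
}

.flow_prescribed <- function(design, total_flow) {
  zones <- design$zones
  pkg <- design$splits$package
  fh <- design$splits$first_half
  half_frac <- ifelse(zones$half == "first", fh[zones$package],
                      1 - fh[zones$package])
  frac <- unname(pkg[zones$package] * half_frac)
  flow <- frac * total_flow

  # warm_matrix[i, j]: flow arriving at zone i drawn from zone j's outflow.
  # An inter-package extra-vent stream is distributed over the receiving
  # package's halves like its split and drawn from the source package's
  # zones in proportion to their throughput, keeping every zone balance
  # mass- and enthalpy-consistent.
  nz <- nrow(zones)
  warm_matrix <- matrix(0, nz, nz, dimnames = list(zones$zone, zones$zone))
  for (p in names(design$extra_inflows)) {
    ex <- design$extra_inflows[[p]]
    if (is.null(ex) || is.na(ex$temp_zone)) next   # cold-room extras are already fresh
    idx <- which(zones$package == p)
    src_idx <- which(zones$package == ex$source)
    share <- flow[idx] / sum(flow[idx])
    src_share <- flow[src_idx] / sum(flow[src_idx])
    warm_matrix[idx, src_idx] <- warm_matrix[idx, src_idx] +
      ex$fraction * total_flow * outer(share, src_share)
  }
  warm_flow <- rowSums(warm_matrix)
  diverted <- colSums(warm_matrix)
  fresh <- flow - warm_flow
  if (any(fresh < -1e-12)) stop("warm inflow exceeds a zone's throughput")
  to_fan <- flow - diverted
  if (any(to_fan < -1e-12)) stop("diverted flow exceeds a zone's throughput")

  zones$frac <- frac
  zones$flow <- flow
  zones$fresh_flow <- pmax(fresh, 0)
  zones$warm_flow <- warm_flow
  zones$to_fan_flow <- pmax(to_fan, 0)
  zones$u <- flow / design$geometry$zone_cross_area

  structure(list(
    mode = "prescribed",
    total_flow = total_flow,
    package_fractions = pkg,
    first_half_fractions = fh,
    zones = zones,
    warm_matrix = warm_matrix,
    design = design$name
  ), class = "flow_solution")
}

# --- orifice-resistance network ------------------------------------------

# regularized orifice law, differentiable through dP = 0
.orifice_q <- function(dp, cd, area, rho, eps = 1e-9) {
  cd * area * sqrt(2 / rho) * dp / (abs(dp) + eps)^0.5
}

.flow_orifice <- function(design, total_flow, air) {
  v <- design$vents
  nodes <- union(v$upstream, v$downstream)
  if (!all(c("coldroom", "fan") %in% nodes)) {
    stop("orifice network needs coldroom and fan nodes")
  }
  unknowns <- setdiff(nodes, "coldroom")
  rho <- air$rho_a

  pressures <- function(x) {
    p <- c(coldroom = 0, stats::setNames(x, unknowns))
    p
  }
  edge_flows <- function(p) {
    .orifice_q(p[v$upstream] - p[v$downstream], v$cd, v$area_m2, rho)
  }
  residual <- function(x) {
    p <- pressures(x)
    q <- edge_flows(p)
    res <- numeric(length(unknowns))
    for (i in seq_along(unknowns)) {
      n <- unknowns[i]
      inflow <- sum(q[v$downstream == n])
      outflow <- sum(q[v$upstream == n])
      res[i] <- if (n == "fan") inflow - total_flow else inflow - outflow
    }
    res
  }

  # damped Newton with finite-difference Jacobian; the suction fan drives all
  # pressures negative, so start from a ramp along the topological order
  topo <- .topo_sort(v$upstream, v$downstream)
  depth <- stats::setNames(seq_along(topo) - 1, topo)
  scale0 <- (total_flow / (min(v$cd * v$area_m2) * sqrt(2 / rho)))^2
  x <- -scale0 * (depth[unknowns] + 1) / length(topo)
  for (iter in 1:200) {
    r <- residual(x)
    if (max(abs(r)) < 1e-12 * total_flow) break
    J <- matrix(0, length(x), length(x))
    hstep <- pmax(abs(x), scale0) * 1e-7
    for (j in seq_along(x)) {
      xj <- x
      xj[j] <- xj[j] + hstep[j]
      J[, j] <- (residual(xj) - r) / hstep[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) stop("singular orifice network (no path coldroom -> fan?)")
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (max(abs(residual(xn))) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- x + lam * step
  }
  r <- residual(x)
  if (max(abs(r)) > 1e-9 * total_flow) {
    stop("orifice solver did not converge (residual ",
         signif(max(abs(r)), 3), " m3/s)")
  }
  p <- pressures(x)
  q <- edge_flows(p)
  v$flow <- as.numeric(q)

  zones <- design$zones
  zones$flow <- vapply(zones$zone, function(z) sum(q[v$downstream == z]), numeric(1))
  zones$frac <- zones$flow / total_flow
  zones$fresh_flow <- vapply(zones$zone, function(z) {
    sum(q[v$downstream == z & !v$upstream %in% zones$zone])
  }, numeric(1))
  zones$warm_flow <- zones$flow - zones$fresh_flow
  nz <- nrow(zones)
  warm_matrix <- matrix(0, nz, nz, dimnames = list(zones$zone, zones$zone))
  inter <- which(v$upstream %in% zones$zone & v$downstream %in% zones$zone)
  for (e in inter) {
    warm_matrix[v$downstream[e], v$upstream[e]] <-
      warm_matrix[v$downstream[e], v$upstream[e]] + q[e]
  }
  zones$to_fan_flow <- vapply(zones$zone, function(z) {
    sum(q[v$upstream == z & !v$downstream %in% zones$zone])
  }, numeric(1))
  zones$u <- zones$flow / design$geometry$zone_cross_area

  pkg_flow <- tapply(zones$flow, zones$package, sum)
  pkg_frac <- stats::setNames(as.numeric(pkg_flow / sum(pkg_flow)),
                              names(pkg_flow))
  fh_frac <- vapply(names(pkg_frac), function(p) {
    sum(zones$flow[zones$package == p & zones$half == "first"]) /
      sum(zones$flow[zones$package == p])
  }, numeric(1))

  structure(list(
    mode = "orifice",
    total_flow = total_flow,
    package_fractions = pkg_frac,
    first_half_fractions = fh_frac,
    zones = zones,
    warm_matrix = warm_matrix,
    node_pressures = p,
    edges = v,
    design = design$name
  ), class = "flow_solution")
}

#' Superficial air velocity in one zone
#'
#' Zone throughput divided by the calibrated zone cross-sectional area.
#'
#' @param solution A `flow_solution`.
#' @param zone Zone id, e.g. `"p1_fh"`.
#' @param design The `tray_design` the solution was computed for.
#' @return Velocity (m s-1).
#' @export
zone_velocity <- function(solution, zone, design) {
  stopifnot(inherits(solution, "flow_solution"))
  i <- match(zone, solution$zones$zone)
  if (is.na(i)) stop("unknown zone '", zone, "'")
  area <- design$geometry$zone_cross_area
  if (is.null(area) || area <= 0) stop("zone cross-sectional area must be > 0")
  solution$zones$flow[i] / area
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Flow solution (%s mode) for %s: %.3g m3/s total\n",
              x$mode, x$design, x$total_flow))
  cat(sprintf("  package fractions: %s\n",
              paste(sprintf("%s %.1f%%", names(x$package_fractions),
                            100 * x$package_fractions), collapse = ", ")))
  z <- x$zones
  for (i in seq_len(nrow(z))) {
    cat(sprintf("  %-6s flow %.3g m3/s (u %.3g m/s)%s\n", z$zone[i], z$flow[i],
                z$u[i],
                if (z$warm_flow[i] > 0)
                  sprintf(", %.0f%% pre-warmed", 100 * z$warm_flow[i] / z$flow[i])
                else ""))
  }
  invisible(x)
}
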