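# Library of package/tray configurations for the two-package strawberry tray:
# PAS (parallel airflow system), MPAS (PAS + airflow restriction plate),
# ARP-M1 (relocated solid restriction plate) and IPAS (ARP-M1 + extra
# end-wall/tray vents). Each design is a directed vent/zone graph from the
# cold-room node to the suction-fan node, with two packages split into
# first-half / second-half well-mixed zones, plus the prescribed airflow-split
# table used in paper-reproduction mode.

.design_zones <- function() {
  data.frame(
    zone = c("p1_fh", "p1_sh", "p2_fh", "p2_sh"),
    package = c("p1", "p1", "p2", "p2"),
    half = c("first", "second", "first", "second"),
    stringsAsFactors = FALSE
  )
}

# vent graph shared by all designs: cold room -> inlet duct (duct 1) ->
# zone (lid vents) -> exhaust duct (duct 2) -> fan; lateral wall vents carry
# zone -> duct 2. Extra IPAS vents are appended by the builder.
.base_vents <- function(lateral_area, lid_area, tray_vent_area, cd) {
  v <- list()
  v[[1]] <- c("tray_inlet", "tray-side-A", 5 * tray_vent_area, "coldroom", "duct1")
  zones <- .design_zones()
  for (i in seq_len(nrow(zones))) {
    z <- zones$zone[i]
    p <- zones$package[i]
    # 9 lid vents per package, shared between the two halves (4.5 equivalent each)
    v[[length(v) + 1]] <- c(paste0("lid_", z), "lid", 4.5 * lid_area, "duct1", z)
    # 13 lateral vents per half (26 per package, 13 per side wall)
    v[[length(v) + 1]] <- c(paste0("lat_", z), "lateral-exhaust", 13 * lateral_area, z, "duct2")
  }
  v[[length(v) + 1]] <- c("tray_outlet", "tray-side-B", 5 * tray_vent_area, "duct2", "fan")
  df <- as.data.frame(do.call(rbind, v), stringsAsFactors = FALSE)
  names(df) <- c("id", "location", "area_m2", "upstream", "downstream")
  df$area_m2 <- as.numeric(df$area_m2)
  df$cd <- cd
  df
}

.build_design <- function(name, description, pkg_split, fh_split,
                          arp = "none", extra_vents = FALSE,
                          extra_inflows = list(), geometry = NULL) {
  defs <- precool_defaults()
  if (is.null(geometry)) {
    geometry <- list(
      package_surface_area = .def("geometry", "package_surface_area"),
      zone_cross_area = .def("geometry", "zone_cross_area"),
      zone_air_volume = .def("geometry", "zone_air_volume"),
      package_mass = .def("geometry", "package_mass")
    )
  }
  # base vent area calibrated so that 26 lateral + 9 lid vents open 28.2% of
  # the package surface; the 6 extra IPAS vents total 0.004 m2 per package
  base_total <- 0.282 * geometry$package_surface_area
  unit_area <- base_total / 35
  cd <- .def("flow", "cd_default")
  vents <- .base_vents(lateral_area = unit_area, lid_area = unit_area,
                       tray_vent_area = 0.003, cd = cd)
  extra_area_total <- 0.004
  if (extra_vents) {
    extra <- data.frame(
      id = c("extra_p1", "extra_p2"),
      location = c("end-wall-extra", "end-wall-extra"),
      area_m2 = c(extra_area_total, extra_area_total),
      upstream = c("coldroom", "p1_fh"),
      downstream = c("p1_fh", "p2_fh"),
      cd = cd,
      stringsAsFactors = FALSE
    )
    vents <- rbind(vents, extra)
  }
  if (abs(sum(pkg_split) - 1) > 1e-6) {
    stop("package split fractions must sum to 1")
  }
  design <- structure(list(
    name = name,
    description = description,
    zones = .design_zones(),
    packages = list(
      p1 = list(id = "p1", mass_kg = geometry$package_mass,
                lateral_vents = 26L, lid_vents = 9L,
                extra_end_vents = if (extra_vents) 6L else 0L),
      p2 = list(id = "p2", mass_kg = geometry$package_mass,
                lateral_vents = 26L, lid_vents = 9L,
                extra_end_vents = if (extra_vents) 6L else 0L)
    ),
    splits = list(package = pkg_split, first_half = fh_split),
    arp = arp,
    extra_inflows = extra_inflows,
    vents = vents,
    geometry = geometry
  ), class = "tray_design")
  design
}

.design_registry <- function() {
  list(
    "PAS" = function() .build_design(
      "PAS",
      "Parallel airflow system: twin ducts, no restriction plate.",
      pkg_split = c(p1 = 0.236, p2 = 0.764),
      fh_split = c(p1 = 0.50, p2 = 0.0378)
    ),
    "MPAS" = function() .build_design(
      "MPAS",
      paste("Modified PAS with a vented airflow restriction plate (ARP).",
            "Split table uses the tabulated 48/52; the narrative also cites",
            "about 46/54."),
      pkg_split = c(p1 = 0.48, p2 = 0.52),
      fh_split = c(p1 = 0.43, p2 = 0.25),
      arp = "ARP"
    ),
    "ARP-M1" = function() .build_design(
      "ARP-M1",
      "Solid restriction plate relocated 15 mm below the package lid.",
      pkg_split = c(p1 = 0.63, p2 = 0.37),
      fh_split = c(p1 = 0.428, p2 = 0.37),
      arp = "ARP-M1"
    ),
    "IPAS" = function() .build_design(
      "IPAS",
      paste("Improved PAS: ARP-M1 plus 6 extra end-wall vents per package",
            "(0.004 m2 total each) and extra tray vents; package 1 draws",
            "3.24% of total flow straight from the cold room, package 2",
            "receives 22% of total flow from package 1."),
      pkg_split = c(p1 = 0.444, p2 = 0.556),
      fh_split = c(p1 = 0.40, p2 = 0.33),
      arp = "ARP-M1",
      extra_vents = TRUE,
      extra_inflows = list(
        p1 = list(source = "coldroom", temp_zone = NA_character_, fraction = 0.0324),
        p2 = list(source = "p1", temp_zone = "p1_fh", fraction = 0.22)
      )
    )
  )
}

#' Names of the built-in tray designs
#' @return Character vector of registry names.
#' @export
list_designs <- function() names(.design_registry())

#' Load a tray design
#'
#' Either one of the built-ins (`"PAS"`, `"MPAS"`, `"ARP-M1"`, `"IPAS"`),
#' carrying the published airflow-split tables, or a YAML design file
#' produced by [write_design()].
#'
#' @param name Built-in design name (case-insensitive; `_` and `-`
#'   interchangeable).
#' @param file Path to a YAML design file (used when `name` is missing).
#' @return A validated `tray_design` object.
#' @export
#' @examples
#' d <- load_design("IPAS")
#' d$splits$package              # 0.444 / 0.556
load_design <- function(name = NULL, file = NULL) {
  if (!is.null(name)) {
    key <- toupper(gsub("_", "-", name))
    key <- if (key %in% c("ARPM1", "ARP-M-1")) "ARP-M1" else key
    reg <- .design_registry()
    if (!key %in% names(reg)) {
      stop("unknown design '", name, "'; built-ins: ",
           paste(names(reg), collapse = ", "))
    }
    design <- reg[[key]]()
  } else if (!is.null(file)) {
    design <- .design_from_list(yaml::read_yaml(file))
  } else {
    stop("supply a built-in design name or a design file")
  }
  rep <- validate_design(design)
  if (nrow(rep$findings) > 0) {
    stop("invalid design '", design$name, "': ",
         paste(rep$findings$message, collapse = "; "))
  }
  design
}

#' Serialize a tray design to YAML
#'
#' The written file round-trips: `load_design(file = path)` reproduces an
#' identical design.
#'
#' @param design A `tray_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "tray_design"))
  x <- unclass(design)
  x$schema_version <- 1
  x$zones <- lapply(seq_len(nrow(design$zones)), function(i) as.list(design$zones[i, ]))
  x$vents <- lapply(seq_len(nrow(design$vents)), function(i) as.list(design$vents[i, ]))
  x$splits <- list(package = as.list(design$splits$package),
                   first_half = as.list(design$splits$first_half))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

.design_from_list <- function(x) {
  if (is.null(x$schema_version)) stop("design file has no schema_version")
  zones <- do.call(rbind, lapply(x$zones, as.data.frame, stringsAsFactors = FALSE))
  vents <- do.call(rbind, lapply(x$vents, as.data.frame, stringsAsFactors = FALSE))
  vents$area_m2 <- as.numeric(vents$area_m2)
  vents$cd <- as.numeric(vents$cd)
  splits <- list(package = unlist(x$splits$package),
                 first_half = unlist(x$splits$first_half))
  if (abs(sum(splits$package) - 1) > 1e-6) {
    stop("package split fractions must sum to 1 (got ",
         signif(sum(splits$package), 6), ")")
  }
  structure(list(
    name = x$name, description = x$description, zones = zones,
    packages = x$packages, splits = splits, arp = x$arp,
    extra_inflows = x$extra_inflows, vents = vents, geometry = x$geometry
  ), class = "tray_design")
}

#' Total vent opening fraction of a package design
#'
#' Sum of package-located vent open areas (lid, lateral walls and extra
#' end-wall vents; tray duct vents excluded) divided by the package outer
#' surface area, averaged over the two packages.
#'
#' @param design A `tray_design`.
#' @return Fraction in `[0, 1)`.
#' @export
#' @examples
#' opening_area_fraction(load_design("MPAS"))   # ~0.282
#' opening_area_fraction(load_design("IPAS"))   # ~0.33
opening_area_fraction <- function(design) {
  stopifnot(inherits(design, "tray_design"))
  area <- design$geometry$package_surface_area
  if (is.null(area) || area <= 0) stop("package surface area must be > 0")
  pkg_vents <- design$vents[design$vents$location %in%
                              c("lid", "lateral-exhaust", "end-wall-extra"), ,
                            drop = FALSE]
  per_package <- sum(pkg_vents$area_m2) / 2
  per_package / area
}

#' Structural validation of a tray design
#'
#' Checks that the vent graph is acyclic and connects the cold room to the
#' fan, that every zone is served by at least one vent, that all vent areas
#' are positive, and that the prescribed split table is consistent.
#'
#' @param design A `tray_design`.
#' @return A `design_validation` object; its `findings` data frame is empty
#'   iff the design is valid.
#' @export
validate_design <- function(design) {
  findings <- list()
  note <- function(check, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      check = check, message = message, stringsAsFactors = FALSE)
  }
  v <- design$vents
  if (any(!is.finite(v$area_m2)) || any(v$area_m2 <= 0)) {
    note("area", "vent areas must be finite and > 0")
  }
  if (any(v$upstream == v$downstream)) {
    note("self-loop", "vent with identical upstream and downstream node")
  }
  nodes <- union(v$upstream, v$downstream)
  for (z in design$zones$zone) {
    if (!z %in% nodes) note("orphan-zone", paste0("zone ", z, " served by no vent"))
  }
  topo <- .topo_sort(v$upstream, v$downstream)
  if (is.null(topo)) {
    note("acyclic", "vent graph contains a cycle")
  } else {
    if (!.has_path(v, "coldroom", "fan")) {
      note("connectivity", "no path from coldroom to fan")
    }
  }
  ps <- design$splits$package
  if (abs(sum(ps) - 1) > 1e-6) {
    note("splits", paste0("package fractions sum to ", signif(sum(ps), 6)))
  }
  fh <- design$splits$first_half
  if (any(fh < 0) || any(fh > 1)) {
    note("splits", "first-half fractions must lie in [0, 1]")
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(check = character(), message = character(), stringsAsFactors = FALSE)
  structure(list(design = design$name, findings = findings,
                 valid = nrow(findings) == 0),
            class = "design_validation")
}

# Kahn topological sort; NULL when the edge set has a cycle
.topo_sort <- function(from, to) {
  nodes <- union(from, to)
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  order <- character()
  indeg <- vapply(nodes, function(n) sum(edges$to == n), integer(1))
  queue <- nodes[indeg == 0]
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    order <- c(order, n)
    out <- edges$to[edges$from == n]
    edges <- edges[edges$from != n, , drop = FALSE]
    for (m in out) {
      if (sum(edges$to == m) == 0 && !m %in% order && !m %in% queue) {
        queue <- c(queue, m)
      }
    }
  }
  if (nrow(edges) > 0) NULL else order
}

.has_path <- function(vents, from, to) {
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(vents$downstream[vents$upstream %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  to %in% seen
}

#' @export
print.tray_design <- function(x, ...) {
  cat(sprintf("Tray design '%s' (restriction plate: %s)\n", x$name, x$arp))
  cat(sprintf("  package split %.1f%% / %.1f%%; first-half split %.1f%% / %.1f%%\n",
              100 * x$splits$package[["p1"]], 100 * x$splits$package[["p2"]],
              100 * x$splits$first_half[["p1"]], 100 * x$splits$first_half[["p2"]]))
  cat(sprintf("  %d vents, opening fraction %.1f%% of package area\n",
              nrow(x$vents), 100 * opening_area_fraction(x)))
  invisible(x)
}

#' @export
print.design_validation <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("Design '%s': valid (no findings)\n", x$design))
  } else {
    cat(sprintf("Design '%s': %d finding(s)\n", x$design, nrow(x$findings)))
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s\n", x$findings$check[i], x$findings$message[i]))
    }
  }
  invisible(x)
}
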