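# Evaluation metrics of a cooling run: fractional (7/8th, half) cooling
# times, package-average trajectories, cooling heterogeneity and cumulative
# moisture loss, plus a multi-design summary table.

#' Fractional cooling time of a temperature trace
#'
#' First time at which the dimensionless temperature
#' `(T - Ta) / (T0 - Ta)` falls to `fraction`, by linear interpolation
#' between output samples. The 7/8th cooling time is `fraction = 1/8`; the
#' half cooling time is `fraction = 1/2`.
#'
#' @param trace Temperature time series (degC).
#' @param times Sample times (s), strictly increasing, same length.
#' @param t0 Initial product temperature (degC).
#' @param ta Cooling air temperature (degC), `ta < t0`.
#' @param fraction Target dimensionless temperature in (0, 1).
#' @return Time in minutes; `NA` with a warning when the threshold is never
#'   reached within the trace.
#' @export
fractional_cooling_time <- function(trace, times, t0, ta, fraction = 1 / 8) {
  stopifnot(length(trace) == length(times), ta < t0,
            fraction > 0, fraction < 1)
  theta <- (trace - ta) / (t0 - ta)
  below <- which(theta <= fraction)
  if (!length(below)) {
    warning("cooling threshold never reached within the trace")
    return(NA_real_)
  }
  i <- below[1]
  if (i == 1) return(times[1] / 60)
  t_cross <- times[i - 1] + (times[i] - times[i - 1]) *
    (theta[i - 1] - fraction) / (theta[i - 1] - theta[i])
  t_cross / 60
}

#' Seven-eighths cooling time
#'
#' @inheritParams fractional_cooling_time
#' @return Minutes to reach 1/8 of the initial product-air temperature
#'   difference; `NA` with a warning if never reached.
#' @export
#' @examples
#' tt <- seq(0, 3e4, 30)
#' tr <- 1 + 15 * exp(-tt / 3530)
#' seven_eighths_cooling_time(tr, tt, t0 = 16, ta = 1)   # ~ 3530 ln(8) / 60
seven_eighths_cooling_time <- function(trace, times, t0, ta) {
  fractional_cooling_time(trace, times, t0, ta, fraction = 1 / 8)
}

#' Package-average fruit temperature trajectory
#'
#' Mass-weighted (default) or center-temperature average over a package's
#' fruits at every output time. Fruits within a zone are identical, so the
#' average weights zones by their fruit mass (equal halves by construction).
#'
#' @param result A `cooling_simulation`.
#' @param package `"p1"` or `"p2"`.
#' @param kind `"mass-average"` or `"center-average"`.
#' @return Numeric vector along `result$times` (degC).
#' @export
package_average_temperature <- function(result, package,
                                        kind = c("mass-average", "center-average")) {
  kind <- match.arg(kind)
  stopifnot(inherits(result, "cooling_simulation"))
  zi <- which(result$zones$package == package)
  if (!length(zi)) stop("no zones belong to package '", package, "'")
  m <- if (kind == "mass-average") result$mass_avg else result$center
  w <- result$zones$n_fruit[zi]
  as.numeric(m[, zi, drop = FALSE] %*% (w / sum(w)))
}

#' Cooling heterogeneity at a given time
#'
#' @param result A `cooling_simulation`.
#' @param t_s Time (s), within the run.
#' @return List: `between` = absolute difference of the two package-average
#'   temperatures (degC); `spread` = max - min over all fruit mass-average
#'   temperatures (degC).
#' @export
heterogeneity <- function(result, t_s) {
  stopifnot(inherits(result, "cooling_simulation"))
  if (t_s < min(result$times) || t_s > max(result$times)) {
    stop("t_s outside the simulated range")
  }
  at <- function(y) stats::approx(result$times, y, xout = t_s)$y
  pkgs <- unique(result$zones$package)
  avgs <- vapply(pkgs, function(p) at(package_average_temperature(result, p)),
                 numeric(1))
  zone_T <- apply(result$mass_avg, 2, at)
  list(between = abs(diff(range(avgs))), spread = max(zone_T) - min(zone_T))
}

#' Cumulative moisture loss of a run
#'
#' Time-integrated transpiration flux over all fruit surfaces. For a
#' moisture-off run the loss is exactly zero and the result carries
#' `attr(, "moisture_off") = TRUE`.
#'
#' @param result A `cooling_simulation`.
#' @return List: `grams`, `percent_initial_mass`; see Details for the flag.
#' @export
cumulative_moisture_loss <- function(result) {
  stopifnot(inherits(result, "cooling_simulation"))
  per_fruit <- utils::tail(result$moisture_cum, 1)          # kg per fruit, by zone
  total_kg <- sum(per_fruit * result$zones$n_fruit)
  initial_mass <- sum(result$zones$n_fruit) * result$fruit_mass
  out <- list(grams = 1000 * total_kg,
              percent_initial_mass = 100 * total_kg / initial_mass)
  if (result$config$moisture == "off") attr(out, "moisture_off") <- TRUE
  out
}

#' Summary table across one or more cooling runs
#'
#' One row per run: 7/8th and half cooling times per package, airflow-split
#' echo, heterogeneity at 3 h and moisture loss — the shape of the published
#' design-comparison table.
#'
#' @param results A `cooling_simulation` or list of them.
#' @return A `cooling_summary` data frame.
#' @export
cooling_summary <- function(results) {
  if (inherits(results, "cooling_simulation")) results <- list(results)
  rows <- lapply(results, function(r) {
    env <- r$env
    t78 <- vapply(c("p1", "p2"), function(p) {
      seven_eighths_cooling_time(package_average_temperature(r, p), r$times,
                                 env$t_product_0, env$t_air_in)
    }, numeric(1))
    t12 <- vapply(c("p1", "p2"), function(p) {
      fractional_cooling_time(package_average_temperature(r, p), r$times,
                              env$t_product_0, env$t_air_in, fraction = 0.5)
    }, numeric(1))
    t_het <- min(10800, max(r$times))
    het <- heterogeneity(r, t_het)
    ml <- cumulative_moisture_loss(r)
    data.frame(
      design = r$design$name,
      flow_mode = r$flow$mode,
      moisture = r$config$moisture,
      t78_p1_min = t78[["p1"]], t78_p2_min = t78[["p2"]],
      t12_p1_min = t12[["p1"]], t12_p2_min = t12[["p2"]],
      split_p1_pct = 100 * r$flow$package_fractions[["p1"]],
      split_p2_pct = 100 * r$flow$package_fractions[["p2"]],
      fh_p1_pct = 100 * r$flow$first_half_fractions[["p1"]],
      fh_p2_pct = 100 * r$flow$first_half_fractions[["p2"]],
      dT_3h_C = het$between,
      spread_3h_C = het$spread,
      moisture_loss_g = ml$grams,
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows), class = c("cooling_summary", "data.frame"))
}

#' Write a cooling summary to CSV and JSON
#'
#' @param summary A [cooling_summary()] result.
#' @param dir Output directory (created if absent).
#' @return Paths of the two files, invisibly.
#' @export
write_cooling_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cooling_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "summary.csv")
  js <- file.path(dir, "summary.json")
  utils::write.csv(summary, csv, row.names = FALSE)
  jsonlite::write_json(summary, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Read back a written cooling summary
#'
#' @param path Path to the CSV written by [write_cooling_summary()].
#' @return A `cooling_summary` data frame.
#' @export
read_cooling_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("cooling_summary", "data.frame"))
}
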