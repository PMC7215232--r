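# Synthetic validation harness: emulates the instrumented-fruit cooling
# experiment (center-probe thermocouple traces at 1 degC / 80% RH) by
# resampling simulated center temperatures and adding Gaussian measurement
# noise, then measures goodness of fit and recovers the skin mass-transfer
# coefficient by least squares.

#' Default thermocouple probe layout
#'
#' Eight instrumented fruits, two per zone (four per package, spread across
#' first/second halves), sampled every `interval_s` seconds with independent
#' Gaussian noise.
#'
#' @param result A `cooling_simulation` (supplies the zone ids).
#' @param interval_s Sampling interval (s).
#' @param noise_sd_c Noise standard deviation (degC); 0.2 is the resolution
#'   class of a K-type thermocouple chain.
#' @return Data frame of probe specs: `probe_id`, `zone`, `interval_s`,
#'   `noise_sd_c`, `location`.
#' @export
default_probes <- function(result, interval_s = 60, noise_sd_c = 0.2) {
  zones <- result$zones$zone
  data.frame(
    probe_id = paste0("probe_", rep(zones, each = 2), c("_a", "_b")),
    zone = rep(zones, each = 2),
    interval_s = interval_s,
    noise_sd_c = noise_sd_c,
    location = "center",
    stringsAsFactors = FALSE
  )
}

#' Generate noisy synthetic thermocouple traces
#'
#' Resamples each probe's zone center temperature on the probe's sampling
#' grid and adds i.i.d. Gaussian noise. The same `(seed, config)` pair
#' reproduces the experiment bit for bit; the RNG state of the session is
#' left untouched.
#'
#' @param result A `cooling_simulation`.
#' @param probes Probe table as from [default_probes()].
#' @param seed Integer seed.
#' @param replicates Number of replicate experiments (default 3).
#' @return A `synthetic_experiment`: `traces` data frame
#'   (`replicate`, `probe_id`, `time_s`, `temp_c`), the probe table, `seed`
#'   and a reference to the generating run.
#' @export
generate_thermocouple_traces <- function(result, probes = default_probes(result),
                                         seed, replicates = 3) {
  stopifnot(inherits(result, "cooling_simulation"))
  unknown <- setdiff(probes$zone, result$zones$zone)
  if (length(unknown)) stop("unknown fruit zone(s): ", paste(unknown, collapse = ", "))
  if (any(probes$interval_s <= 0)) stop("probe interval must be > 0")
  if (any(probes$noise_sd_c < 0)) stop("probe noise sd must be >= 0")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  out <- list()
  for (r in seq_len(replicates)) {
    for (i in seq_len(nrow(probes))) {
      tt <- seq(0, max(result$times), by = probes$interval_s[i])
      base <- stats::approx(result$times, result$center[, probes$zone[i]],
                            xout = tt)$y
      out[[length(out) + 1]] <- data.frame(
        replicate = r,
        probe_id = probes$probe_id[i],
        time_s = tt,
        temp_c = base + stats::rnorm(length(tt), 0, probes$noise_sd_c[i]),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    traces = do.call(rbind, out),
    probes = probes,
    seed = seed,
    replicates = replicates,
    generating_run = list(design = result$design$name,
                          moisture = result$config$moisture)
  ), class = "synthetic_experiment")
}

# predicted temps aligned to an observed trace table
.predict_at_traces <- function(result, traces, probes) {
  zone_of <- stats::setNames(probes$zone, probes$probe_id)
  vapply(seq_len(nrow(traces)), function(i) {
    stats::approx(result$times, result$center[, zone_of[[traces$probe_id[i]]]],
                  xout = traces$time_s[i])$y
  }, numeric(1))
}

.trace_values <- function(x, ref_traces = NULL, probes = NULL) {
  if (inherits(x, "cooling_simulation")) {
    if (is.null(ref_traces)) stop("need observed traces to align a simulation")
    return(.predict_at_traces(x, ref_traces, probes))
  }
  if (inherits(x, "synthetic_experiment")) x <- x$traces
  x$temp_c
}

#' Goodness of fit between simulated and observed traces
#'
#' Root-mean-square error, coefficient of determination (against the
#' observed mean) and maximum absolute error, pooled over all probes,
#' replicates and time points.
#'
#' @param simulated A `cooling_simulation` (aligned to the observed grid) or
#'   a second `synthetic_experiment` with an identical layout.
#' @param observed A `synthetic_experiment`.
#' @return List: `rmse_c`, `r_squared`, `max_abs_error_c`, `n`.
#' @export
goodness_of_fit <- function(simulated, observed) {
  stopifnot(inherits(observed, "synthetic_experiment"))
  obs <- observed$traces$temp_c
  pred <- .trace_values(simulated, observed$traces, observed$probes)
  if (length(pred) != length(obs)) stop("trace layouts do not match")
  keep <- is.finite(pred) & is.finite(obs)
  if (!any(keep)) stop("disjoint time ranges")
  obs <- obs[keep]; pred <- pred[keep]
  resid <- obs - pred
  list(rmse_c = sqrt(mean(resid^2)),
       r_squared = 1 - sum(resid^2) / sum((obs - mean(obs))^2),
       max_abs_error_c = max(abs(resid)),
       n = length(obs))
}

#' Recover the skin mass-transfer coefficient from probe traces
#'
#' Least-squares fit of `kg_skin`: the moisture-on simulation is rerun over
#' a log-spaced search interval and the value minimising the RMSE between
#' simulated and observed center temperatures is returned (golden-section
#' search on log10(kg_skin)). Estimates pinned at a search bound are
#' flagged.
#'
#' @param observed A `synthetic_experiment` generated from a moisture-on run.
#' @param design A `tray_design` (the generating design).
#' @param fruit,air,env Property objects of the generating run (the fitted
#'   `kg_skin` replaces `fruit$kg_skin`).
#' @param config The generating [simulation_config()] (moisture must be on).
#' @param bounds Search interval for `kg_skin` (s m-1).
#' @param tol Relative convergence tolerance on log10(kg_skin).
#' @return A `skin_recovery` list: `kg_skin`, `rmse_c`, `pinned`,
#'   `evaluations`, `bounds`.
#' @export
recover_skin_coefficient <- function(observed, design,
                                     fruit = fruit_properties(),
                                     air = air_properties(),
                                     env = environment_conditions(),
                                     config = simulation_config(moisture = "on"),
                                     bounds = c(5e-9, 5.5e-7),
                                     tol = 1e-3) {
  stopifnot(inherits(observed, "synthetic_experiment"),
            config$moisture == "on", bounds[1] > 0, bounds[2] > bounds[1])
  evals <- 0L
  objective <- function(log_kgs) {
    evals <<- evals + 1L
    f <- fruit
    f$kg_skin <- 10^log_kgs
    res <- simulate_cooling(design, fruit = f, air = air, env = env,
                            config = config)
    goodness_of_fit(res, observed)$rmse_c
  }
  opt <- stats::optimize(objective, interval = log10(bounds), tol = tol)
  est <- 10^opt$minimum
  # optimize never evaluates exactly at the interval ends; treat estimates
  # within half a tolerance band of a bound as pinned
  pin_band <- 2 * tol * diff(log10(bounds))
  pinned <- (log10(est) - log10(bounds[1]) < pin_band) ||
    (log10(bounds[2]) - log10(est) < pin_band)
  if (pinned) warning("kg_skin estimate pinned at a search bound")
  structure(list(kg_skin = est, rmse_c = opt$objective, pinned = pinned,
                 evaluations = evals, bounds = bounds),
            class = "skin_recovery")
}

#' Write a synthetic experiment to CSV (+ JSON sidecar)
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory.
#' @return File paths, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "traces.csv")
  js <- file.path(dir, "experiment.json")
  utils::write.csv(experiment$traces, csv, row.names = FALSE)
  jsonlite::write_json(
    list(seed = experiment$seed, replicates = experiment$replicates,
         probes = experiment$probes, generating_run = experiment$generating_run),
    js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic experiment: %d probes x %d replicates, seed %s (run: %s, moisture %s)\n",
    nrow(x$probes), x$replicates, x$seed,
    x$generating_run$design, x$generating_run$moisture))
  invisible(x)
}

#' @export
print.skin_recovery <- function(x, ...) {
  cat(sprintf("Recovered kg_skin = %.3g s/m (RMSE %.3g degC, %d model runs%s)\n",
              x$kg_skin, x$rmse_c, x$evaluations,
              if (x$pinned) ", PINNED AT BOUND" else ""))
  invisible(x)
}
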