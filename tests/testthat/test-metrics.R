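# Cooling metrics: fractional cooling times, package averages,
# heterogeneity, moisture loss, summary round-trip.

test_that("7/8 cooling time of an exponential trace equals tau ln 8", {
  tt <- seq(0, 40000, by = 30)
  t78 <- seven_eighths_cooling_time(1 + 15 * exp(-tt / 3530), tt, 16, 1)
  expect_equal(t78, 3530 * log(8) / 60, tolerance = 1e-4)
  # property sweep over random time constants, 0.1% agreement
  set.seed(5)
  for (tau in stats::runif(20, 500, 8000)) {
    got <- seven_eighths_cooling_time(1 + 15 * exp(-tt / tau), tt, 16, 1)
    expect_equal(got, tau * log(8) / 60, tolerance = 1e-3)
  }
  # half time < 7/8 time
  t12 <- fractional_cooling_time(1 + 15 * exp(-tt / 3530), tt, 16, 1, 0.5)
  expect_lt(t12, t78)
})

test_that("unreached thresholds signal explicitly", {
  tt <- seq(0, 1000, by = 10)
  expect_warning(out <- seven_eighths_cooling_time(rep(16, length(tt)), tt, 16, 1),
                 "never reached")
  expect_true(is.na(out))
})

test_that("10x denser output sampling moves the 7/8 time by < 0.5%", {
  coarse <- seq(0, 40000, by = 300)
  fine <- seq(0, 40000, by = 30)
  trace <- function(tt) 1 + 15 * exp(-tt / 4000) * (1 + 0.1 * sin(tt / 2000))
  a <- seven_eighths_cooling_time(trace(coarse), coarse, 16, 1)
  b <- seven_eighths_cooling_time(trace(fine), fine, 16, 1)
  expect_lt(abs(a - b) / b, 0.005)
})

test_that("package averages weight fruits correctly", {
  tt <- seq(0, 600, by = 300)
  m <- cbind(p1_fh = c(16, 2), p1_sh = c(16, 4),
             p2_fh = c(16, 3), p2_sh = c(16, 3))
  res <- make_fake_result(tt, m)
  expect_equal(package_average_temperature(res, "p1")[2], 3)   # two equal fruits
  expect_equal(package_average_temperature(res, "p2")[2], 3)
  # unequal loading shifts the mass-average
  res2 <- make_fake_result(tt, m, n_fruit = c(3L, 1L, 1L, 1L))
  expect_equal(package_average_temperature(res2, "p1")[2], (3 * 2 + 4) / 4)
  # center-average reads the center matrix
  res3 <- make_fake_result(tt, m, center = m + 1)
  expect_equal(package_average_temperature(res3, "p1", "center-average")[2], 4)
  expect_error(package_average_temperature(res, "p9"), "no zones")
})

test_that("heterogeneity is symmetric, nonnegative, and spread bounds between", {
  tt <- c(0, 10800)
  sym <- make_fake_result(tt, cbind(p1_fh = c(16, 3), p1_sh = c(16, 5),
                                    p2_fh = c(16, 3), p2_sh = c(16, 5)))
  h <- heterogeneity(sym, 10800)
  expect_equal(h$between, 0)
  expect_equal(h$spread, 2)
  # relabeling packages leaves the absolute difference unchanged
  asym <- make_fake_result(tt, cbind(p1_fh = c(16, 2), p1_sh = c(16, 3),
                                     p2_fh = c(16, 4), p2_sh = c(16, 6)))
  swapped <- make_fake_result(tt, cbind(p1_fh = c(16, 4), p1_sh = c(16, 6),
                                        p2_fh = c(16, 2), p2_sh = c(16, 3)))
  expect_equal(heterogeneity(asym, 10800)$between,
               heterogeneity(swapped, 10800)$between)
  # spread >= between, always
  set.seed(9)
  for (i in 1:20) {
    temps <- matrix(stats::runif(8, 1, 16), 2, 4,
                    dimnames = list(NULL, c("p1_fh", "p1_sh", "p2_fh", "p2_sh")))
    temps[1, ] <- 16
    r <- make_fake_result(tt, temps)
    hh <- heterogeneity(r, 10800)
    expect_gte(hh$spread, hh$between - 1e-12)
  }
  expect_error(heterogeneity(sym, 1e6), "outside")
})

test_that("cumulative moisture loss integrates flux and flags moisture-off", {
  tt <- c(0, 10800)
  # constant flux 6e-6 kg/s/m2 over 2.8e-3 m2 for 3 h -> 0.181 g per fruit
  per_fruit <- 6e-6 * 2.8e-3 * 10800
  cum <- matrix(c(0, per_fruit), 2, 4,
                dimnames = list(NULL, c("p1_fh", "p1_sh", "p2_fh", "p2_sh")))
  res <- make_fake_result(tt, matrix(16, 2, 4,
                                     dimnames = dimnames(cum)),
                          moisture = "on", moisture_cum = cum)
  out <- cumulative_moisture_loss(res)
  expect_equal(out$grams, 4 * 0.18144, tolerance = 1e-3)
  expect_equal(out$percent_initial_mass,
               100 * 4 * per_fruit / (4 * 0.0113), tolerance = 1e-3)

  off <- make_fake_result(tt, matrix(16, 2, 4, dimnames = dimnames(cum)))
  out_off <- cumulative_moisture_loss(off)
  expect_identical(out_off$grams, 0)
  expect_true(attr(out_off, "moisture_off"))
})

test_that("moisture loss over a default 3 h moisture-on run stays below 2%", {
  res <- run_design("IPAS", duration = 10800, out_interval = 120,
                    moisture = "on")
  loss <- cumulative_moisture_loss(res)
  expect_gt(loss$grams, 0)
  expect_lt(loss$percent_initial_mass, 2)
  # nondecreasing cumulative loss
  expect_true(all(diff(res$moisture_cum) >= -1e-15))
})

test_that("cooling summaries tabulate runs and round-trip through CSV", {
  res <- run_design("MPAS", duration = 36000, out_interval = 120)
  summ <- cooling_summary(res)
  expect_s3_class(summ, "cooling_summary")
  expect_identical(nrow(summ), 1L)
  expect_equal(summ$split_p1_pct, 48)
  expect_equal(summ$fh_p2_pct, 25)
  expect_lt(summ$t12_p1_min, summ$t78_p1_min)

  dir <- withr::local_tempdir()
  write_cooling_summary(summ, dir)
  back <- read_cooling_summary(file.path(dir, "summary.csv"))
  expect_equal(back$t78_p1_min, summ$t78_p1_min, tolerance = 1e-9)
  expect_identical(back$design, summ$design)
})
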