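test_that("hourly differencing of cumulative counts", {
  expect_equal(hourly_new_particles(c(0, 10, 25, 25)), c(10, 15, 0))
  expect_equal(hourly_new_particles(c(7, 7, 7)), c(0, 0))
  expect_error(hourly_new_particles(c(5, 3, 8)), "integrative")
  expect_error(hourly_new_particles(5), "at least two")
  m <- rbind(a = c(0, 2, 5), b = c(1, 1, 4))
  expect_equal(hourly_new_particles(m),
               rbind(a = c(2, 3), b = c(0, 3)))
})

test_that("captured mass concentration matches the direct arithmetic oracle", {
  # one 1-um polystyrene sphere in one hour at 4.5 L/min:
  # mass = pi/6 * (1e-6 m)^3 * 1050 kg/m^3 = 5.497787e-16 kg = 5.497787e-7 ug
  # air volume = 4.5 L/min * 60 min = 270 L = 0.27 m^3
  oracle <- (pi / 6 * (1e-6)^3 * 1050) * 1e9 / 0.27
  expect_equal(captured_mass_concentration(1000, 1050, 4.5, 1), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 2.0362175e-06, tolerance = 1e-7)
  # cubic scaling in diameter
  expect_equal(captured_mass_concentration(2000, 1050, 4.5, 1),
               8 * oracle, tolerance = 1e-12)
  expect_equal(captured_mass_concentration(numeric(0)), 0)
  # PM2.5 cutoff: a 3 um particle does not count
  expect_equal(captured_mass_concentration(c(1000, 3000), 1050, 4.5, 1),
               oracle, tolerance = 1e-12)
  det <- data.frame(diameter_nm = c(500, NA, NA))
  expect_error(captured_mass_concentration(det), "2, 3")
})

test_that("ambient concentration is captured over eta", {
  expect_equal(ambient_concentration(0, 0.5), 0)
  expect_equal(ambient_concentration(3, 1), 3)
  expect_equal(ambient_concentration(2.5e-4, 1.91e-4), 2.5e-4 / 1.91e-4)
  expect_error(ambient_concentration(1, 0), "eta")
  # per-size-bin efficiency hook: applied row-wise to a bins x hours matrix
  bins <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(ambient_concentration(bins, c(0.5, 0.25)),
               bins / c(0.5, 0.25))
  expect_error(ambient_concentration(c(1, 2, 3), c(0.5, 0.2)),
               "bins-by-hours")
  set.seed(1)
  for (i in 1:20) {
    pm_cap <- runif(1, 0, 1e-3); eta <- runif(1, 1e-5, 1)
    expect_equal(ambient_concentration(pm_cap, eta) * eta, pm_cap)
  }
})

test_that("collection efficiency estimation is exact, equivariant, and guarded", {
  ref <- c(2, 5, 3, 8, 6, 4, 7, 9, 5, 3, 2, 6)
  pm_cap <- 2e-4 * ref
  fit <- estimate_eta(pm_cap, ref)
  expect_equal(fit$eta, 2e-4, tolerance = 1e-12)
  expect_equal(fit$rmse_ugm3, 0, tolerance = 1e-9)
  # scale equivariance
  fit10 <- estimate_eta(10 * pm_cap, ref)
  expect_equal(fit10$eta, 10 * fit$eta, tolerance = 1e-12)
  expect_error(estimate_eta(rep(0, 12), ref), "zero")
  expect_error(estimate_eta(pm_cap, rep(0, 12)), "<= 0")
  expect_error(estimate_eta(pm_cap[1:2], ref[1:2]), "3 aligned")
  # reference rounding noise of 0.5 ug/m3 leaves eta within 5% over seeds
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- pmax(ref + rnorm(12, 0, 0.5), 0.5)
    abs(estimate_eta(pm_cap, noisy)$eta - 2e-4) / 2e-4
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("sensor capacity follows the footprint model", {
  expect_equal(sensor_capacity(1e7, 10), 1e5)
  expect_equal(sensor_capacity(optics_config(sensor_shape = c(100, 100)), 10),
               100)
  expect_equal(sensor_capacity(optics_config(sensor_shape = c(100, 100)), 1),
               10000)
  expect_error(sensor_capacity(1e7, 0), "positive integer")
})

test_that("saturation forecast reproduces the linear-accumulation estimates", {
  f <- saturation_forecast(1e5, 1e3, 6, 6)
  expect_equal(f$ceiling_ugm3, 600)
  expect_equal(f$hours_to_saturation, 100)
  f10 <- saturation_forecast(1e5, 1e3, 6, 60)
  expect_equal(f10$hours_to_saturation, 10)
  expect_error(saturation_forecast(-1, 1e3, 6, 6), "positive")
})

test_that("EPA metrics: perfect agreement, replicate CV, and guards", {
  ref <- c(2, 5, 3, 8, 6, 4, 7, 9, 5, 3, 2, 6)
  m <- epa_metrics(ref, ref)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0, tolerance = 1e-12)
  reps <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(epa_metrics(ref, ref, replicates = reps)$cv_percent, 0)
  expect_error(epa_metrics(ref, rep(4, 12)), "zero variance")
  # a generator calibrated for R^2 ~ 0.86 is measured back near 0.86
  set.seed(12)
  n <- 48
  x <- runif(n, 1, 9)
  sigma <- sd(x) * sqrt(1 / 0.86 - 1)
  y <- x + rnorm(n, 0, sigma)
  expect_equal(epa_metrics(y, x)$r_squared, 0.86, tolerance = 0.12)
})

test_that("size-resolved hourly PM sums exactly to the total", {
  set.seed(8)
  det <- data.frame(diameter_nm = exp(runif(60, log(80), log(2400))),
                    hour = sample(1:4, 60, replace = TRUE))
  bins <- hourly_pm_by_size(det, 4)
  total <- vapply(1:4, function(h)
    captured_mass_concentration(det$diameter_nm[det$hour == h],
                                Q_Lpm = 4.5, t_h = 1), numeric(1))
  expect_equal(colSums(bins), total, tolerance = 1e-12)
  expect_equal(dim(bins), c(5L, 4L))
})

test_that("a simulated field day with known eta is recovered end to end", {
  opt <- optics_config(sensor_shape = c(2748L, 3664L))
  prof <- c(2, 3, 4, 6, 5, 4, 3, 5, 6, 4, 3, 2)
  sim <- simulate_time_series(prof, field_sampler, opt, duration_h = 12,
                              seed = 19, eta = 1.91e-4, render = FALSE,
                              keep = "none")
  man <- sim$manifest
  hour <- floor(man$deposit_time_s / 3600) + 1
  pm_cap <- vapply(1:12, function(h)
    captured_mass_concentration(man$diameter_nm[hour == h],
                                Q_Lpm = 4.5, t_h = 1), numeric(1))
  # reference: the PM2.5 share of the generating concentration
  frac25 <- local({
    set.seed(99); d <- field_sampler(2e5)
    sum(d[d <= 2500]^3) / sum(d^3)
  })
  fit <- estimate_eta(pm_cap, prof * frac25)
  expect_lt(abs(fit$eta - 1.91e-4) / 1.91e-4, 0.10)
  pm <- ambient_concentration(pm_cap, 1.91e-4)
  expect_lt(sqrt(mean(((pm - prof * frac25) / (prof * frac25))^2)), 0.25)
})

test_that("mean particle mass estimation matches a fixed-size sampler", {
  m <- mean_particle_mass_ug(function(n) rep(500, n))
  expect_equal(m, pi / 6 * (500e-9)^3 * 1050 * 1e9, tolerance = 1e-12)
})
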