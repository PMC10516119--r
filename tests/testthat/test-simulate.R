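test_that("empty particle list gives a unit-amplitude zero-phase field", {
  opt <- test_optics(c(64, 64))
  f <- object_transmittance(NULL, film_model(), opt)
  expect_equal(Mod(f$values), matrix(1, 64, 64))
  expect_equal(Arg(f$values), matrix(0, 64, 64))
})

test_that("a particle imprints its peak phase at its center pixel", {
  opt <- test_optics(c(64, 64))
  man <- ground_truth_particles(30 * 1.67, 40 * 1.67, 300,
                                peak_phase_rad = 0.5)
  f <- object_transmittance(man, film_model(), opt)
  ph <- Arg(f$values)
  expect_equal(max(ph), 0.5)
  expect_equal(which(ph == max(ph), arr.ind = TRUE)[1, ],
               c(row = 41L, col = 31L))  # 0-based (40, 30)
})

test_that("out-of-view particles and overlapping bumps are flagged", {
  opt <- test_optics(c(64, 64))
  man <- ground_truth_particles(c(10, 500) * 1.67, c(10, 10) * 1.67,
                                c(200, 200))
  expect_error(object_transmittance(man, film_model(), opt),
               "particle\\(s\\) 2 outside")
  close_pair <- ground_truth_particles(c(30, 31) * 1.67, c(30, 30) * 1.67,
                                       c(200, 200))
  expect_warning(object_transmittance(close_pair, film_model(), opt),
                 "overlapping")
  # overlapping phases add
  f <- suppressWarnings(object_transmittance(close_pair, film_model(), opt))
  single <- object_transmittance(close_pair[1, ], film_model(), opt)
  expect_gt(max(Arg(f$values)), max(Arg(single$values)))
})

test_that("film evaporation buries small particles first", {
  film <- film_model()
  # retention decreasing in time, increasing in diameter
  expect_true(all(diff(phase_retention(film, 200, c(0, 6, 12, 24))) < 0))
  expect_true(all(diff(phase_retention(film, c(100, 200, 500, 1000), 24)) > 0))
  opt <- test_optics(c(96, 96))
  man <- ground_truth_particles(c(30, 64) * 1.67, c(30, 64) * 1.67,
                                c(100, 1000))
  day1 <- object_transmittance(man, film, opt, time_s = 24 * 3600)
  ph <- Arg(day1$values)
  # the 100 nm bump has decayed below any usable detection floor ...
  expect_lt(max(ph[1:48, 1:48]), 1e-4)
  # ... while the 1 um bump persists
  expect_gt(max(ph[49:96, 49:96]),
            0.5 * phase_for_diameter(true_phase_curve(), 1000))
  expect_warning(check_film_age(film, 30), "sub-200 nm")
})

test_that("rendering is deterministic and flat fields stay flat", {
  opt <- test_optics(c(96, 96), z_um = 600)
  nm <- noise_model(seed = 11L)
  uniform <- complex_field(matrix(1 + 0i, 96, 96), 1.67, 528)
  a <- render_hologram(uniform, opt, nm)
  b <- render_hologram(uniform, opt, nm)
  expect_identical(a$intensity, b$intensity)
  clean <- render_hologram(uniform, opt,
                           noise_model(read_noise_sigma = 0, seed = 1L))
  expect_equal(length(unique(as.vector(clean$intensity))), 1L)
  expect_true(all(a$intensity >= 0))
})

test_that("rendered holograms round-trip to the particle location", {
  opt <- test_optics()
  man <- ground_truth_particles(50 * 1.67, 80 * 1.67, 500)
  obj <- object_transmittance(man, film_model(), opt)
  fr <- render_hologram(obj, opt, noise_model(read_noise_sigma = 0))
  rec <- backpropagate(normalize_background(fr), 1000, opt)
  ph <- phase_image(rec)
  peak <- which(ph == max(ph), arr.ind = TRUE)
  expect_lte(abs(peak[1, "row"] - 81), 1)
  expect_lte(abs(peak[1, "col"] - 51), 1)
})

test_that("a mismatched object-field pitch is rejected", {
  opt <- test_optics(c(64, 64))
  f <- complex_field(matrix(1 + 0i, 64, 64), 2.2, 528)
  expect_error(render_hologram(f, opt, noise_model()), "pixel pitch")
})

test_that("zero concentration yields an empty manifest and background frames", {
  opt <- test_optics(c(96, 96), z_um = 600)
  sim <- simulate_time_series(0, field_sampler, opt, duration_h = 1,
                              seed = 1, eta = 1e-6, keep = "epoch_mean")
  expect_equal(nrow(sim$manifest), 0L)
  expect_equal(sim$epochs$cumulative_particles, rep(0L, 6))
  # frames are pure background: no structure beyond noise
  expect_lt(sd(sim$frames[[6]]$intensity) / mean(sim$frames[[6]]$intensity),
            0.01)
})

test_that("deposition is Poisson with mean linear in concentration", {
  opt <- optics_config(sensor_shape = c(2748L, 3664L))
  const500 <- function(n) rep(500, n)
  m_ug <- pi / 6 * (500e-9)^3 * 1050 * 1e9
  expected_h <- 6 / m_ug * (4.5e-3 * 60) * 1.91e-4
  hourly <- c()
  for (s in 1:50) {
    sim <- simulate_time_series(6, const500, opt, duration_h = 1, seed = s,
                                render = FALSE, keep = "none")
    hourly <- c(hourly, sum(sim$epochs$new_particles))
  }
  expect_lt(abs(mean(hourly) - expected_h), 3 * sqrt(expected_h / 50))
  # doubling concentration doubles the mean deposition rate
  hourly2 <- c()
  for (s in 1:25) {
    sim <- simulate_time_series(12, const500, opt, duration_h = 1, seed = s,
                                render = FALSE, keep = "none")
    hourly2 <- c(hourly2, sum(sim$epochs$new_particles))
  }
  expect_equal(mean(hourly2) / mean(hourly), 2, tolerance = 0.05)
})

test_that("the manifest is reproducible and cumulative counts never decrease", {
  opt <- optics_config(sensor_shape = c(512L, 512L))
  a <- simulate_time_series(6, field_sampler, opt, duration_h = 2, seed = 9,
                            eta = 1.91e-4 * 512^2 / 1e7 * 20,
                            render = FALSE, keep = "none")
  b <- simulate_time_series(6, field_sampler, opt, duration_h = 2, seed = 9,
                            eta = 1.91e-4 * 512^2 / 1e7 * 20,
                            render = FALSE, keep = "none")
  expect_identical(a$manifest, b$manifest)
  expect_true(all(diff(a$epochs$cumulative_particles) >= 0))
  expect_true(all(a$manifest$deposit_time_s >= 0))
})

test_that("expected deposition beyond sensor capacity raises a saturation error", {
  opt <- test_optics(c(64, 64))
  expect_error(
    simulate_time_series(1e9, function(n) rep(500, n), opt, duration_h = 1,
                         seed = 1, eta = 1, render = FALSE, keep = "none"),
    "saturated")
})
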