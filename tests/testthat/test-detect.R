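test_that("threshold schedules are validated", {
  expect_s3_class(threshold_schedule(c(0.5, 0.3, 0.2, 0.1, 0.05)),
                  "threshold_schedule")
  expect_error(threshold_schedule(c(0.5, 0.3, 0.2, 0.1)), "exactly 5")
  expect_error(threshold_schedule(c(0.5, 0.5, 0.2, 0.1, 0.05)),
               "strictly decreasing")
  expect_error(threshold_schedule(c(0.5, 0.3, 0.2, 0.1, -0.1)),
               "positive")
})

test_that("default thresholds span 0.9*max down to 3x the noise MAD", {
  set.seed(5)
  ph <- matrix(rnorm(128^2, 0, 0.01), 128, 128)
  ph[60:64, 60:64] <- 1.0
  s <- default_thresholds(ph)
  expect_length(s, 5L)
  expect_equal(s[1], 0.9 * max(ph))
  expect_equal(s[5], 3 * mad(ph))
  expect_true(all(diff(unclass(s)) < 0))
  # homogeneity: scaling the image scales the schedule
  s2 <- default_thresholds(2 * ph)
  expect_equal(unclass(s2), 2 * unclass(s), tolerance = 1e-12)
  expect_error(default_thresholds(matrix(rnorm(64^2, 0, 0.01), 64, 64)),
               "no signal")
})

test_that("detection at a threshold finds the right components", {
  ph <- phase_with_bumps(96, 96, list(c(30, 30), c(60, 70), c(80, 20)),
                         c(0.8, 0.5, 0.1))
  det <- detect_at_threshold(ph, 0.3, pitch_um = 1.67)
  expect_equal(nrow(det), 2L)
  # subpixel centroids within 1 px of the true centers (0-based)
  expect_lt(abs(det$y_px[1] - 29), 1); expect_lt(abs(det$x_px[1] - 29), 1)
  expect_lt(abs(det$y_px[2] - 59), 1); expect_lt(abs(det$x_px[2] - 69), 1)
  expect_equal(det$peak_phase_rad, c(0.8, 0.5), tolerance = 1e-9)
  expect_equal(nrow(detect_at_threshold(ph, 0.9, pitch_um = 1.67)), 0L)
})

test_that("components touching the border are discarded", {
  ph <- phase_with_bumps(64, 64, list(c(2, 30), c(32, 32)), c(0.6, 0.5))
  det <- detect_at_threshold(ph, 0.2, pitch_um = 1.67)
  expect_equal(nrow(det), 1L)
  expect_equal(det$peak_phase_rad, 0.5, tolerance = 1e-9)
})

test_that("detection count is non-increasing in the threshold", {
  opt <- test_optics()
  sc <- simulate_scene(c(100, 200, 300, 500, 1000), opt, seed = 13)
  rec <- backpropagate(normalize_background(sc$frame), 1000, opt)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.3),
                   function(th) nrow(detect_at_threshold(rec, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("removing a large particle preserves its small neighbour's phase", {
  opt <- test_optics()
  big <- ground_truth_particles(45 * 1.67, 45 * 1.67, 1000)
  small <- ground_truth_particles(85 * 1.67, 85 * 1.67, 200)
  both <- rbind(big, small); both$id <- 1:2
  fr_both <- normalize_background(simulate_scene(both, opt, seed = 21)$frame)
  fr_small <- normalize_background(simulate_scene(small, opt, seed = 21)$frame)
  rec <- backpropagate(fr_both, 1000, opt)
  det <- detect_at_threshold(rec, 0.2)   # only the large particle
  expect_equal(nrow(det), 1L)
  cleaned <- remove_particle_and_twin(fr_both, det[1, ], 1000, opt)
  ph_clean <- phase_image(backpropagate(cleaned, 1000, opt))
  ph_alone <- phase_image(backpropagate(fr_small, 1000, opt))
  win <- 83:89
  expect_equal(max(ph_clean[win, win]), max(ph_alone[win, win]),
               tolerance = 0.1)
})

test_that("removal suppresses fringes, is idempotent, and acts locally", {
  opt <- test_optics()
  one <- ground_truth_particles(60 * 1.67, 60 * 1.67, 500)
  fr <- normalize_background(simulate_scene(one, opt, seed = 22)$frame)
  empty <- normalize_background(
    simulate_scene(one[0, ], opt, seed = 22)$frame)
  rec <- backpropagate(fr, 1000, opt)
  det <- detect_at_threshold(rec, 0.05)[1, ]
  cleaned <- remove_particle_and_twin(fr, det, 1000, opt)
  # fringe energy around the particle strictly reduced
  ann <- function(I) {
    d <- sqrt(outer((1:128 - 61)^2, rep(1, 128)) +
              outer(rep(1, 128), (1:128 - 61)^2))
    I[d > 8 & d < 25]
  }
  expect_lt(var(ann(cleaned$intensity)), var(ann(fr$intensity)))
  # residual background variance comparable to a particle-free hologram
  expect_lt(var(as.vector(cleaned$intensity)),
            2 * var(as.vector(empty$intensity)) + 1e-6)
  # idempotence: a second removal changes almost nothing
  again <- remove_particle_and_twin(cleaned, det, 1000, opt)
  expect_lt(max(abs(again$intensity - cleaned$intensity)) /
              mean(cleaned$intensity), 1e-3)
  # pixels far from the detection change by < 1% relative
  d <- sqrt(outer((1:128 - 61)^2, rep(1, 128)) +
            outer(rep(1, 128), (1:128 - 61)^2))
  far <- d > 45
  expect_lt(max(abs(cleaned$intensity[far] - fr$intensity[far])), 0.01)
})

test_that("iterative detection finds a mixed scene once each, well localized", {
  opt <- test_optics()
  ds <- c(100, 150, 200, 300, 400, 500, 650, 800, 1000, 250)
  sc <- simulate_scene(ds, opt, seed = 31)
  det <- iterative_detect(normalize_background(sc$frame), opt, z_hint = 1000)
  s <- score_detections(det, sc$manifest)
  expect_gte(s$recall, 0.9)
  expect_gte(s$precision, 0.95)
  expect_lte(s$max_loc_px, 1)
  # no duplicates: detections are at least one footprint apart
  if (nrow(det) > 1) {
    dd <- as.matrix(dist(cbind(det$x_um, det$y_um)))
    diag(dd) <- Inf
    expect_gt(min(dd), 6 * 1.67)
  }
  expect_true(all(det$pass_index %in% 1:5))
  expect_true(all(diff(det$peak_phase_rad) <= 0))
})

test_that("iterative detection returns nothing for empty or buried scenes", {
  opt <- test_optics()
  sched <- threshold_schedule(c(0.3, 0.2, 0.1, 0.05, 0.02))
  empty <- normalize_background(
    simulate_scene(ground_truth_particles(numeric(0), numeric(0),
                                          numeric(0)), opt, seed = 41)$frame)
  expect_equal(nrow(iterative_detect(empty, opt, sched, z_hint = 1000)), 0L)
  # sub-200 nm particles under a 3-day-old film are buried below every pass
  buried <- ground_truth_particles(c(40, 80) * 1.67, c(40, 80) * 1.67,
                                   c(100, 150))
  fr <- normalize_background(
    simulate_scene(buried, opt, time_s = 72 * 3600, seed = 42)$frame)
  expect_equal(nrow(iterative_detect(fr, opt, sched, z_hint = 1000)), 0L)
})
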