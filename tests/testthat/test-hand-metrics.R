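test_that("constant-velocity motion gives constant speed away from edges", {
  n <- 240
  hp <- cbind((0:(n - 1)) * 0.1 / 120, 0, 0)  # 0.1 m/s along x
  rec <- make_recording(hp)
  sp <- compute_speed(rec, sample_window(1, n + 1))
  interior <- 30:(n - 30)
  expect_equal(sp$speed[interior], rep(0.1, length(interior)), tolerance = 1e-6)
})

test_that("a stationary hand has zero speed and zero units with warning", {
  rec <- make_recording(matrix(0.2, 240, 3))
  sp <- compute_speed(rec, sample_window(1, 241))
  expect_lt(max(sp$speed), 1e-4)
  expect_warning(u <- count_movement_units(make_profile(rep(0, 240))),
                 class = "feedkin_warning")
  expect_identical(u, 0L)
})

test_that("min-jerk transport matches the analytic identities", {
  mj <- min_jerk_segment(c(0, 0, 0), c(0.2, 0, 0), 1.0, 120)
  rec <- make_recording(mj$pos)
  w <- sample_window(1, nrow(mj$pos) + 1)
  sp <- compute_speed(rec, w)
  vm <- velocity_metrics(sp)
  expect_equal(vm$max_velocity_mps, 1.875 * 0.2 / 1.0, tolerance = 0.01)
  expect_lt(abs(vm$timing_max_velocity_pct - 50), 1)
  expect_identical(count_movement_units(sp), 1L)
  # D = 0.14 m, T = 0.9 s: mean D/T, peak 1.875 D/T
  mj2 <- min_jerk_segment(c(0, 0, 0), c(0, 0.14, 0), 0.9, 120)
  vm2 <- velocity_metrics(compute_speed(make_recording(mj2$pos),
                                        sample_window(1, nrow(mj2$pos) + 1)))
  expect_equal(vm2$mean_velocity_mps, 0.14 / 0.9, tolerance = 0.01)
  expect_equal(vm2$max_velocity_mps, 1.875 * 0.14 / 0.9, tolerance = 0.01)
  expect_equal(vm2$max_velocity_mps / vm2$mean_velocity_mps, 1.875,
               tolerance = 0.01)
})

test_that("constant speed means mean equals max and timing 0 by tie-break", {
  sp <- make_profile(rep(0.25, 120))
  vm <- velocity_metrics(sp)
  expect_equal(vm$mean_velocity_mps, vm$max_velocity_mps)
  expect_equal(vm$timing_max_velocity_pct, 0)
})

test_that("path metrics handle collinear, right-angle and degenerate paths", {
  rec <- make_recording(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0)))
  pm <- path_metrics(rec, sample_window(1, 4), cutoff_hz = 120)
  expect_equal(pm$actual_distance_m, 0.2)
  expect_equal(pm$relative_distance, 1.0)
  rec2 <- make_recording(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.1, 0)))
  pm2 <- path_metrics(rec2, sample_window(1, 4), cutoff_hz = 120)
  expect_equal(pm2$actual_distance_m, 0.2)
  expect_equal(pm2$relative_distance, 0.2 / sqrt(0.02), tolerance = 1e-6)
  loop <- make_recording(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0, 0)))
  expect_error(path_metrics(loop, sample_window(1, 4), cutoff_hz = 120),
               class = "feedkin_validation_error")
})

test_that("relative distance is at least 1 on filtered synthetic transports", {
  set.seed(51)
  for (s in 1:5) {
    tr <- synth_trial(sim_config(), sample(c("chopsticks", "spoon"), 1),
                      seed = 5000 + s)
    for (seg in segment_trial(tr$recording)) {
      pm <- path_metrics(tr$recording, seg$phases$Tr)
      expect_gte(pm$relative_distance, 1)
    }
  }
})

test_that("commanded detour ratio is recovered within 1% on noise-free trials", {
  for (cond in c("chopsticks", "spoon")) {
    tr <- synth_trial(noise_free_config("female"), cond, seed = 52)
    seg <- segment_trial(tr$recording)[[1]]
    pm <- path_metrics(tr$recording, seg$phases$Tr)
    expect_equal(pm$relative_distance, tr$truth$commanded$detour_ratio,
                 tolerance = 0.01)
  }
})

test_that("two separated submovements count as two units", {
  # two min-jerk bumps 0.3 s apart with a deep inter-peak trough
  rate <- 120
  mj <- function(D, T) {
    tau <- seq(0, 1, length.out = T * rate)
    1.875 * D / T * (30 * tau^2 * (1 - tau)^2) / 1.875
  }
  sp <- make_profile(c(mj(0.1, 0.4), rep(0.001, 0.1 * rate), mj(0.1, 0.4)))
  expect_identical(count_movement_units(sp), 2L)
  expect_identical(
    oracle_movement_units(sp$time, sp$speed), 2L)
})

test_that("sub-threshold ripple does not create extra units", {
  mj <- min_jerk_segment(c(0, 0, 0), c(0.2, 0, 0), 1.0, 120)
  sp <- compute_speed(make_recording(mj$pos), sample_window(1, nrow(mj$pos) + 1),
                      cutoff_hz = 120)
  sp$speed <- sp$speed + 0.008 * sin(2 * pi * 4 * sp$time)
  sp$speed <- pmax(sp$speed, 0)
  expect_identical(count_movement_units(sp), 1L)
  expect_identical(oracle_movement_units(sp$time, sp$speed), 1L)
})

test_that("the movement-unit count agrees exactly with the naive oracle", {
  set.seed(53)
  for (i in 1:120) {
    sp <- random_speed_profile(n = sample(60:360, 1))
    got <- suppressWarnings(count_movement_units(sp))
    want <- oracle_movement_units(sp$time, sp$speed)
    expect_identical(got, want)
  }
})

test_that("unit counts are non-increasing in both thresholds", {
  set.seed(54)
  amps <- c(0.005, 0.01, 0.02, 0.04, 0.08)
  ints <- c(0.05, 0.1, 0.15, 0.25, 0.4)
  for (i in 1:40) {
    sp <- random_speed_profile()
    by_amp <- vapply(amps, function(a) {
      suppressWarnings(count_movement_units(sp, movement_unit_params(a, 0.15)))
    }, integer(1))
    expect_true(all(diff(by_amp) <= 0))
    by_int <- vapply(ints, function(g) {
      suppressWarnings(count_movement_units(sp, movement_unit_params(0.02, g)))
    }, integer(1))
    expect_true(all(diff(by_int) <= 0))
  }
})

test_that("windows shorter than the minimum are rejected", {
  rec <- make_recording(matrix(0.1, 10, 3))
  expect_error(compute_speed(rec, sample_window(1, 3)),
               class = "feedkin_validation_error")
  expect_error(count_movement_units(make_profile(c(0.1, 0.2))),
               class = "feedkin_validation_error")
})
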