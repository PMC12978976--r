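test_that("min-jerk segments honour the analytic endpoint properties", {
  mj <- min_jerk_segment(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1), 1.0, 120)
  expect_equal(mj$pos[1, ], c(x = 0.1, y = 0.2, z = 0.3))
  expect_equal(mj$pos[nrow(mj$pos), ], c(x = 0.3, y = 0.2, z = 0.1))
  mid <- which(abs(mj$time - 0.5) < 1e-9)
  expect_equal(unname(mj$pos[mid, ]), c(0.2, 0.2, 0.2))  # symmetry
  same <- min_jerk_segment(c(1, 1, 1), c(1, 1, 1), 0.5, 120)
  expect_true(all(same$pos == 1))
  expect_error(min_jerk_segment(c(0, 0, 0), c(1, 0, 0), 0),
               class = "feedkin_validation_error")
})

test_that("identical seeds give bit-identical trials", {
  cfg <- sim_config("female")
  a <- synth_trial(cfg, "spoon", seed = 71)
  b <- synth_trial(cfg, "spoon", seed = 71)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth$commanded, b$truth$commanded)
  c <- synth_trial(cfg, "spoon", seed = 72)
  expect_false(identical(a$recording$hand_pos, c$recording$hand_pos))
})

test_that("commanded submovement counts are recovered exactly when noise-free", {
  for (nsub in c(2L, 4L, 6L)) {
    cfg <- noise_free_config(
      n_submovements = c(chopsticks = nsub, spoon = nsub),
      n_submovement_jitter = 0)
    tr <- synth_trial(cfg, "chopsticks", seed = 73)
    for (seg in segment_trial(tr$recording)) {
      m <- transport_metrics(tr$recording, seg)
      expect_identical(m$n_movement_units, nsub)
    }
  }
})

test_that("noise-free pipeline metrics match ground truth within tolerance", {
  for (cond in c("chopsticks", "spoon")) {
    tr <- synth_trial(noise_free_config("male"), cond, seed = 74)
    segs <- segment_trial(tr$recording)
    for (i in seq_along(segs)) {
      m <- transport_metrics(tr$recording, segs[[i]])
      tt <- tr$truth$transport[i, ]
      expect_equal(m$actual_distance_m, tt$actual_distance_m,
                   tolerance = 0.01)
      expect_equal(m$max_velocity_mps, tt$max_velocity_mps,
                   tolerance = 0.01)
      expect_equal(m$timing_max_velocity_pct, tt$timing_max_velocity_pct,
                   tolerance = 0.01)
      expect_identical(m$n_movement_units, tt$n_movement_units)
    }
    ang <- tr$truth$angle_summaries
    seg1 <- segs[[1]]
    for (ch in joint_channels()) {
      got <- phase_angle_summary(tr$recording, seg1, ch)
      want <- ang[ang$cycle == 1 & ang$channel == ch, ]
      expect_equal(got$max_deg, want$max_deg, tolerance = 0.5)
      expect_equal(got$min_deg, want$min_deg, tolerance = 0.5)
    }
  }
})

test_that("cohorts have one trial per participant and condition", {
  co <- synth_cohort(cohort_spec(n_male = 2, n_female = 1, seed = 75),
                     cfg_male = sim_config("male", n_eats = 2),
                     cfg_female = sim_config("female", n_eats = 2))
  expect_length(co$trials, 6)  # 2 conditions x 3 participants
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_length(list.files(d, pattern = "^[MF].*\\.csv$"), 6)
  expect_length(list.files(d, pattern = "_events\\.json$"), 6)
  expect_true(file.exists(file.path(d, "truth.csv")))
})

test_that("cohort generation is reproducible file-for-file", {
  spec <- cohort_spec(n_male = 1, n_female = 1, seed = 76)
  cfgs <- list(m = sim_config("male", n_eats = 2),
               f = sim_config("female", n_eats = 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(synth_cohort(spec, cfgs$m, cfgs$f), d1)
  write_cohort(synth_cohort(spec, cfgs$m, cfgs$f), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("participant effects are shared across conditions", {
  spec <- cohort_spec(n_male = 3, n_female = 0, angle_between_sd = 10,
                      null_conditions = TRUE, seed = 77)
  co <- synth_cohort(spec, cfg_male = sim_config("male", n_eats = 2,
                                                 angle_noise_sd = 0,
                                                 position_noise_sd = 0))
  # paired trials share the participant offset: per-participant condition
  # differences in a channel mean are far smaller than between-participant
  # spread
  mean_ang <- function(tr, ch) mean(tr$recording$angles[, ch])
  ids <- sub("_(chopsticks|spoon)$", "", names(co$trials))
  for (id in unique(ids)) {
    d <- mean_ang(co$trials[[paste0(id, "_chopsticks")]], "hip_flexion") -
      mean_ang(co$trials[[paste0(id, "_spoon")]], "hip_flexion")
    expect_lt(abs(d), 6)
  }
  between <- vapply(unique(ids), function(id) {
    mean_ang(co$trials[[paste0(id, "_chopsticks")]], "hip_flexion")
  }, numeric(1))
  expect_gt(max(between) - min(between), 1)
})

test_that("a commanded shoulder-flexion shift is recovered in the medians", {
  spec <- cohort_spec(n_male = 8, n_female = 0,
                      angle_shift = c(shoulder_flexion = -14),
                      null_conditions = TRUE, seed = 78)
  co <- synth_cohort(spec, cfg_male = sim_config("male", n_eats = 2,
                                                 angle_noise_sd = 0.5,
                                                 keyframe_jitter_sd = 0.5,
                                                 position_noise_sd = 0))
  diffs <- vapply(unique(sub("_(chopsticks|spoon)$", "", names(co$trials))),
                  function(id) {
    get_max <- function(cond) {
      tr <- co$trials[[paste0(id, "_", cond)]]
      seg <- select_success_cycle(segment_trial(tr$recording,
                                                annotations = tr$annotations))
      out <- phase_angle_summary(tr$recording, seg, "shoulder_flexion")
      out$max_deg[out$phase == "Re"]
    }
    get_max("chopsticks") - get_max("spoon")
  }, numeric(1))
  expect_equal(median(diffs), -14, tolerance = 2)
})

test_that("metric-level paired samples carry the commanded shift", {
  set.seed(79)
  s <- synth_paired_metric(2000, shift = -14, between_sd = 5, noise_sd = 2)
  expect_equal(mean(s$a - s$b), -14, tolerance = 0.5)
  expect_equal(sd(s$a - s$b), sqrt(8), tolerance = 0.3)
})
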