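# a hand-built trajectory visiting the mouth region twice, 2 s apart
two_visit_recording <- function() {
  rate <- 120
  mouth <- c(0, 0, 0); far <- c(0.5, 0, 0)
  seg <- function(a, b, T) min_jerk_segment(a, b, T, rate)$pos
  hp <- rbind(seg(mouth, far, 1.0), seg(far, mouth, 1.0),
              matrix(mouth, 60, 3, byrow = TRUE),
              seg(mouth, far, 1.0), seg(far, mouth, 1.0),
              matrix(mouth, 60, 3, byrow = TRUE))
  make_recording(hp, mouth = mouth, bowl = c(5, 5, 5))
}

test_that("three sequential eats yield two cycles matching ground truth", {
  tr <- synth_trial(noise_free_config(), "chopsticks", seed = 21)
  cycles <- detect_cycles(tr$recording)
  expect_length(cycles, 2)
  for (k in 1:2) {
    expect_lte(abs(cycles[[k]][["start"]] - tr$truth$cycles[[k]][["start"]]), 2)
    expect_lte(abs(cycles[[k]][["end"]] - tr$truth$cycles[[k]][["end"]]), 2)
  }
})

test_that("a hand held far from the mouth produces zero cycles", {
  hp <- matrix(rep(c(0.5, 0, 0), each = 240), 240, 3)
  rec <- make_recording(hp, mouth = c(0, 0, 0), bowl = c(1, 0, 0))
  expect_warning(cycles <- detect_cycles(rec), class = "feedkin_warning")
  expect_length(cycles, 0)
})

test_that("two mouth visits separated by 2 s give exactly one cycle", {
  cycles <- detect_cycles(two_visit_recording())
  expect_length(cycles, 1)
})

test_that("recordings shorter than 1 s are rejected", {
  rec <- make_recording(matrix(0.1, 60, 3))
  expect_error(detect_cycles(rec), class = "feedkin_validation_error")
})

test_that("noise-free segmentation recovers all boundaries within 2 samples", {
  set.seed(31)
  n_ok <- 0L; n_tot <- 0L
  for (s in 1:20) {
    cond <- if (s %% 2) "chopsticks" else "spoon"
    sex <- if (s %% 4 < 2) "male" else "female"
    tr <- synth_trial(noise_free_config(sex), cond, seed = 1000 + s)
    segs <- segment_trial(tr$recording)
    expect_length(segs, length(tr$truth$segmentations))
    for (i in seq_along(segs)) {
      expect_false(is.null(segs[[i]]$phases))
      err <- abs(unlist(segs[[i]]$phases) -
                   unlist(tr$truth$segmentations[[i]]$phases))
      n_tot <- n_tot + length(err)
      n_ok <- n_ok + sum(err <= 2)
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("phase windows always partition the cycle without gaps or overlap", {
  set.seed(32)
  for (s in 1:6) {
    tr <- synth_trial(sim_config(), sample(c("chopsticks", "spoon"), 1),
                      seed = 2000 + s)
    for (seg in segment_trial(tr$recording)) {
      ph <- seg$phases
      expect_identical(names(ph), c("Re", "Ta", "Tr", "Mo"))
      expect_identical(ph$Re[["start"]], seg$cycle[["start"]])
      expect_identical(ph$Re[["end"]], ph$Ta[["start"]])
      expect_identical(ph$Ta[["end"]], ph$Tr[["start"]])
      expect_identical(ph$Tr[["end"]], ph$Mo[["start"]])
      expect_identical(ph$Mo[["end"]], seg$cycle[["end"]])
      expect_true(all(vapply(ph, window_length, integer(1)) >= 2L))
    }
  }
})

test_that("segmentation is deterministic for fixed input and thresholds", {
  tr <- synth_trial(sim_config(), "spoon", seed = 77)
  s1 <- segment_trial(tr$recording)
  s2 <- segment_trial(tr$recording)
  expect_identical(s1, s2)
})

test_that("manual phase boundaries are returned verbatim", {
  tr <- synth_trial(noise_free_config(), "chopsticks", seed = 5)
  ann <- event_annotations(
    data.frame(start = 100L, end = 700L, success = TRUE,
               exclusion_reason = "none"),
    phase_boundaries = list(c(Re = 100L, Ta = 300L, Tr = 450L, Mo = 600L,
                              end = 700L)))
  seg <- segment_phases(tr$recording, sample_window(100, 700),
                        annotations = ann, cycle_index = 1L)
  expect_identical(unname(seg$phases$Ta), c(300L, 450L))
  expect_identical(unname(seg$phases$Mo), c(600L, 700L))
})

test_that("a trajectory that never approaches the bowl names bowl-entry", {
  rec <- two_visit_recording()  # bowl at (5,5,5): never approached
  cycles <- detect_cycles(rec)
  expect_error(segment_phases(rec, cycles[[1]]), "bowl-entry",
               class = "feedkin_segmentation_error")
})

test_that("the first successful cycle is selected; failures are skipped", {
  tr <- synth_trial(noise_free_config(), "chopsticks", seed = 9)
  segs <- segment_trial(tr$recording)
  expect_identical(select_success_cycle(segs), segs[[1]])
  segs[[1]]$success <- FALSE
  segs[[1]]$exclusion_reason <- "multiple_scoops"
  expect_identical(select_success_cycle(segs), segs[[2]])
  segs[[2]]$success <- FALSE
  expect_error(select_success_cycle(segs),
               class = "feedkin_participant_exclusion")
})

test_that("mid-reach pauses are flagged on noise-free trials", {
  cfg <- noise_free_config(pause_probability = c(chopsticks = 1, spoon = 1))
  tr <- synth_trial(cfg, "chopsticks", seed = 13)
  segs <- segment_trial(tr$recording)
  expect_true(all(vapply(segs, `[[`, logical(1), "pause_detected_in_reach")))
  cfg0 <- noise_free_config(pause_probability = c(chopsticks = 0, spoon = 0))
  tr0 <- synth_trial(cfg0, "chopsticks", seed = 13)
  segs0 <- segment_trial(tr0$recording)
  expect_false(any(vapply(segs0, `[[`, logical(1), "pause_detected_in_reach")))
})
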