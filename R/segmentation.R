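#' Event-detection thresholds for phase segmentation
#'
#' Phase boundaries are detected from the proximity of the (low-pass
#' filtered) hand origin to the mouth and bowl reference points. A boundary
#' event fires when the relevant distance crosses its radius and stays on
#' the far side for at least `min_dwell` seconds; bowl exit additionally
#' requires clearing the radius by `hysteresis` so that jitter at the rim
#' does not toggle events.
#'
#' @param d_mouth Hand-mouth proximity radius in metres (default 0.10).
#' @param d_bowl Hand-bowl proximity radius in metres (default 0.08).
#' @param hysteresis Extra clearance for exit events in metres (default 0.02).
#' @param min_dwell Minimum dwell beyond a threshold in seconds (default 0.05).
#' @param smoothing_cutoff Low-pass cutoff for positions in Hz (default 6).
#' @return Object of class `event_thresholds`.
#' @export
event_thresholds <- function(d_mouth = 0.10, d_bowl = 0.08, hysteresis = 0.02,
                             min_dwell = 0.05, smoothing_cutoff = 6) {
  vals <- c(d_mouth = d_mouth, d_bowl = d_bowl, hysteresis = hysteresis,
            min_dwell = min_dwell, smoothing_cutoff = smoothing_cutoff)
  if (any(vals <= 0)) {
    fk_stop("all thresholds must be strictly positive", "feedkin_validation_error")
  }
  if (hysteresis >= d_mouth || hysteresis >= d_bowl) {
    fk_stop("hysteresis must be smaller than both proximity radii",
            "feedkin_validation_error")
  }
  structure(as.list(vals), class = "event_thresholds")
}

# first indices where `d` crosses `thr` and stays on the far side for
# `dwell_n` samples; searched within [from, to) (1-based, half-open)
sustained_crossings <- function(d, thr, direction = c("above", "below"),
                                dwell_n, from = 2L, to = length(d) + 1L,
                                first_only = FALSE) {
  direction <- match.arg(direction)
  far <- if (direction == "above") d > thr else d < thr
  n <- length(d)
  hits <- integer()
  i <- max(2L, from)
  while (i < to) {
    if (far[i] && !far[i - 1L]) {
      j <- i + dwell_n - 1L
      if (j <= n && all(far[i:j])) {
        hits <- c(hits, i)
        if (first_only) return(hits)
        # skip ahead to the next return to the near side
        k <- i + 1L
        while (k <= n && far[k]) k <- k + 1L
        i <- k
        next
      }
    }
    i <- i + 1L
  }
  hits
}

# hand-landmark distances on low-pass filtered hand positions
landmark_distances <- function(rec, thr) {
  hp <- lowpass_butter(rec$hand_pos, thr$smoothing_cutoff, rec$sample_rate)
  list(
    mouth = sqrt(rowSums((hp - rec$mouth_pos)^2)),
    bowl = sqrt(rowSums((hp - rec$bowl_pos)^2))
  )
}

#' Detect eating cycles in a recording
#'
#' An eating cycle runs from just after the utensil leaves the mouth to just
#' before it next leaves the mouth. Mouth-exit events are detected as
#' outward crossings of the hand-mouth distance through `d_mouth`, sustained
#' for at least `min_dwell`; each cycle is the half-open window between
#' consecutive exits, and the incomplete trailing stretch after the last
#' exit is discarded.
#'
#' @param rec A `motion_recording`.
#' @param thr [event_thresholds()].
#' @return List of `c(start, end)` sample windows (possibly empty).
#' @export
detect_cycles <- function(rec, thr = event_thresholds()) {
  if (length(rec$time) < rec$sample_rate) {
    fk_stop("recording shorter than 1 s", "feedkin_validation_error")
  }
  d <- landmark_distances(rec, thr)
  dwell_n <- max(1L, as.integer(round(thr$min_dwell * rec$sample_rate)))
  exits <- sustained_crossings(d$mouth, thr$d_mouth, "above", dwell_n)
  if (length(exits) == 0L) {
    fk_warn("no mouth-exit events found; returning zero cycles")
    return(list())
  }
  if (length(exits) < 2L) return(list())
  lapply(seq_len(length(exits) - 1L), function(k) {
    sample_window(exits[k], exits[k + 1L])
  })
}

#' Split one eating cycle into the four feeding phases
#'
#' Phases are contiguous half-open windows that exactly partition the cycle:
#' reaching (cycle start to bowl entry), table (bowl entry to bowl exit,
#' i.e. picking or scooping), transporting (bowl exit to mouth entry), and
#' mouth (mouth entry to cycle end). Bowl entry is a sustained inward
#' crossing of `d_bowl`; bowl exit a sustained outward crossing of
#' `d_bowl + hysteresis`; mouth entry a sustained inward crossing of
#' `d_mouth`. Manually confirmed boundaries in `annotations` are returned
#' verbatim and event detection is skipped. A pause flag records whether the
#' hand speed dropped below 5% of the reach peak for at least 0.3 s during
#' the reaching phase (pauses are flagged, never excluded).
#'
#' @param rec A `motion_recording`.
#' @param cycle A `c(start, end)` window from [detect_cycles()].
#' @param thr [event_thresholds()].
#' @param annotations Optional `event_annotations`.
#' @param cycle_index Index of `cycle` within the annotation list, used to
#'   look up flags and manual boundaries.
#' @return Object of class `cycle_segmentation` with elements `cycle`,
#'   `phases` (named list Re/Ta/Tr/Mo of windows), `success`,
#'   `exclusion_reason`, and `pause_detected_in_reach`.
#' @export
segment_phases <- function(rec, cycle, thr = event_thresholds(),
                           annotations = NULL, cycle_index = NULL) {
  manual <- NULL
  if (!is.null(annotations) && !is.null(cycle_index) &&
      !is.null(annotations$phase_boundaries)) {
    manual <- annotations$phase_boundaries[[cycle_index]]
  }
  if (!is.null(manual)) {
    phases <- list(Re = sample_window(manual[["Re"]], manual[["Ta"]]),
                   Ta = sample_window(manual[["Ta"]], manual[["Tr"]]),
                   Tr = sample_window(manual[["Tr"]], manual[["Mo"]]),
                   Mo = sample_window(manual[["Mo"]], manual[["end"]]))
    cycle <- sample_window(manual[["Re"]], manual[["end"]])
  } else {
    d <- landmark_distances(rec, thr)
    dwell_n <- max(1L, as.integer(round(thr$min_dwell * rec$sample_rate)))
    s <- cycle[["start"]]; e <- cycle[["end"]]
    b_in <- sustained_crossings(d$bowl, thr$d_bowl, "below", dwell_n,
                                from = s + 1L, to = e, first_only = TRUE)
    if (!length(b_in)) {
      fk_stop("segmentation failed: no bowl-entry event in cycle",
              "feedkin_segmentation_error")
    }
    b_out <- sustained_crossings(d$bowl, thr$d_bowl + thr$hysteresis, "above",
                                 dwell_n, from = b_in + 1L, to = e,
                                 first_only = TRUE)
    if (!length(b_out)) {
      fk_stop("segmentation failed: no bowl-exit event in cycle",
              "feedkin_segmentation_error")
    }
    m_in <- sustained_crossings(d$mouth, thr$d_mouth, "below", dwell_n,
                                from = b_out + 1L, to = e, first_only = TRUE)
    if (!length(m_in)) {
      fk_stop("segmentation failed: no mouth-entry event in cycle",
              "feedkin_segmentation_error")
    }
    phases <- list(Re = sample_window(s, b_in), Ta = sample_window(b_in, b_out),
                   Tr = sample_window(b_out, m_in), Mo = sample_window(m_in, e))
  }
  short <- vapply(phases, window_length, integer(1)) < 2L
  if (any(short)) {
    fk_stop(paste0("segmentation failed: phase(s) shorter than 2 samples: ",
                   paste(names(phases)[short], collapse = ", ")),
            "feedkin_segmentation_error")
  }
  seg <- structure(list(
    cycle = cycle, phases = phases, success = TRUE,
    exclusion_reason = "none",
    pause_detected_in_reach = detect_reach_pause(rec, phases$Re, thr)
  ), class = "cycle_segmentation")
  if (!is.null(annotations) && !is.null(cycle_index)) {
    seg$success <- annotations$cycles$success[cycle_index]
    seg$exclusion_reason <- annotations$cycles$exclusion_reason[cycle_index]
  }
  seg
}

# pause: hand speed < 5% of the reach peak for >= 0.3 s inside the reach
detect_reach_pause <- function(rec, re_window, thr) {
  if (window_length(re_window) < 3L) return(FALSE)
  sp <- compute_speed(rec, re_window, cutoff_hz = thr$smoothing_cutoff)
  peak <- max(sp$speed)
  if (peak <= 0) return(FALSE)
  slow <- sp$speed < 0.05 * peak
  runs <- rle(slow)
  any(runs$values & runs$lengths >= 0.3 * rec$sample_rate)
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  ph <- vapply(x$phases, function(w) sprintf("[%d,%d)", w[["start"]], w[["end"]]),
               character(1))
  cat(sprintf("<cycle_segmentation> cycle [%d,%d) %s success=%s%s\n",
              x$cycle[["start"]], x$cycle[["end"]],
              paste(names(ph), ph, sep = "=", collapse = " "),
              x$success,
              if (x$pause_detected_in_reach) " (pause in reach)" else ""))
  invisible(x)
}

#' Detect and segment all cycles of a trial
#'
#' Convenience wrapper: uses annotated cycle windows when provided
#' (otherwise [detect_cycles()]), segments each cycle, applies
#' success/exclusion flags, and marks cycles whose segmentation fails as
#' unusable rather than aborting the trial.
#'
#' @inheritParams segment_phases
#' @return List of `cycle_segmentation` objects (unusable cycles carry
#'   `success = FALSE` and an `error` message).
#' @export
segment_trial <- function(rec, thr = event_thresholds(), annotations = NULL) {
  cycles <- if (!is.null(annotations)) {
    lapply(seq_len(nrow(annotations$cycles)), function(i) {
      sample_window(annotations$cycles$start[i], annotations$cycles$end[i])
    })
  } else {
    detect_cycles(rec, thr)
  }
  lapply(seq_along(cycles), function(i) {
    tryCatch(
      segment_phases(rec, cycles[[i]], thr, annotations = annotations,
                     cycle_index = if (!is.null(annotations)) i),
      feedkin_segmentation_error = function(e) {
        structure(list(cycle = cycles[[i]], phases = NULL, success = FALSE,
                       exclusion_reason = "none",
                       pause_detected_in_reach = FALSE,
                       error = conditionMessage(e)),
                  class = "cycle_segmentation")
      })
  })
}

#' Select the analysed success cycle
#'
#' Mirrors the study's selection rule: of the candidate cycles in a trial
#' (two complete cycles when the participant eats three times), the first
#' successful one is analysed. If no cycle is successful the participant is
#' excluded for that condition, signalled as a classed error
#' (`feedkin_participant_exclusion`).
#'
#' @param segs List of `cycle_segmentation` objects with flags applied.
#' @return The first successful `cycle_segmentation`.
#' @export
select_success_cycle <- function(segs) {
  if (!length(segs)) {
    fk_stop("no candidate cycles", "feedkin_participant_exclusion")
  }
  ok <- vapply(segs, function(s) isTRUE(s$success) && !is.null(s$phases),
               logical(1))
  if (!any(ok)) {
    fk_stop("no successful eating cycle; participant excluded for this condition",
            "feedkin_participant_exclusion")
  }
  segs[[which(ok)[1L]]]
}
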