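#' Per-phase joint-angle summary for one channel
#'
#' Maximum and minimum joint angle (degrees, reported sign convention),
#' range of angle change (max - min), and movement time for each of the four
#' feeding phases of a segmented cycle. Extrema are taken over the raw
#' samples inside each half-open phase window; angles are not smoothed
#' unless `cutoff_hz` is given.
#'
#' @param rec A `motion_recording`.
#' @param seg A successful `cycle_segmentation`.
#' @param channel One of [joint_channels()].
#' @param cutoff_hz Optional low-pass cutoff applied to the angle series
#'   before taking extrema (default `NULL`: no smoothing).
#' @return Data frame with one row per phase: `channel`, `phase`,
#'   `max_deg`, `min_deg`, `range_deg`, `movement_time_s`.
#' @export
phase_angle_summary <- function(rec, seg, channel, cutoff_hz = NULL) {
  if (!channel %in% joint_channels()) {
    fk_stop(paste0("unknown channel: ", channel), "feedkin_schema_error")
  }
  if (is.null(seg$phases)) {
    fk_stop("segmentation has no phases (unusable cycle)",
            "feedkin_validation_error")
  }
  x <- rec$angles[, channel]
  if (!is.null(cutoff_hz)) x <- lowpass_butter(x, cutoff_hz, rec$sample_rate)
  rows <- lapply(names(seg$phases), function(ph) {
    w <- seg$phases[[ph]]
    if (window_length(w) < 2L) {
      fk_stop(paste0("phase window shorter than 2 samples: ", ph),
              "feedkin_validation_error")
    }
    v <- x[window_indices(w)]
    data.frame(channel = channel, phase = ph,
               max_deg = max(v), min_deg = min(v),
               range_deg = max(v) - min(v),
               movement_time_s = movement_time(seg, ph, rec$sample_rate))
  })
  do.call(rbind, rows)
}

#' Movement time of a phase
#'
#' Duration of a phase window in seconds: (number of samples in the
#' half-open window) / sample rate. The four phase times sum exactly to the
#' cycle time because the phases partition the cycle.
#'
#' @param seg A `cycle_segmentation`.
#' @param phase One of `"Re"`, `"Ta"`, `"Tr"`, `"Mo"`.
#' @param sample_rate Sampling rate in Hz.
#' @return Duration in seconds.
#' @export
movement_time <- function(seg, phase, sample_rate = 120) {
  phase <- match.arg(phase, c("Re", "Ta", "Tr", "Mo"))
  if (is.null(seg$phases)) {
    fk_stop("segmentation has no phases (unusable cycle)",
            "feedkin_validation_error")
  }
  window_length(seg$phases[[phase]]) / sample_rate
}

#' All-channel, all-phase joint-angle table for one cycle
#'
#' @inheritParams phase_angle_summary
#' @return Data frame: one row per (channel, phase), plus participant,
#'   sex and condition metadata columns.
#' @export
cycle_angle_table <- function(rec, seg, cutoff_hz = NULL) {
  out <- do.call(rbind, lapply(joint_channels(), function(ch) {
    phase_angle_summary(rec, seg, ch, cutoff_hz)
  }))
  cbind(data.frame(participant_id = rec$participant_id, sex = rec$sex,
                   condition = rec$condition), out, row.names = NULL)
}
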