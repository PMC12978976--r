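#' Movement-unit detection parameters
#'
#' A movement unit is one local-minimum to next-local-maximum excursion of
#' the hand speed profile exceeding the amplitude limit (20 mm/s), with
#' retained speed peaks separated by at least the minimum interval (150 ms).
#' Fewer units indicate a smoother transport.
#'
#' @param amplitude_limit Minimum trough-to-peak speed difference in m/s
#'   (default 0.020).
#' @param min_peak_interval Minimum time between retained peaks in seconds
#'   (default 0.150).
#' @return Object of class `movement_unit_params`.
#' @export
movement_unit_params <- function(amplitude_limit = 0.020,
                                 min_peak_interval = 0.150) {
  if (amplitude_limit <= 0 || min_peak_interval <= 0) {
    fk_stop("movement-unit parameters must be positive",
            "feedkin_validation_error")
  }
  structure(list(amplitude_limit = amplitude_limit,
                 min_peak_interval = min_peak_interval),
            class = "movement_unit_params")
}

#' Tangential hand speed over a window
#'
#' Speed of the hand origin: hand positions inside the window are low-pass
#' filtered (zero-phase Butterworth), differentiated by central differences
#' (one-sided at the window edges), and reduced to the Euclidean norm.
#'
#' @param rec A `motion_recording`.
#' @param window A `c(start, end)` half-open sample window, length >= 3.
#' @param cutoff_hz Low-pass cutoff in Hz (default 6).
#' @return Object of class `speed_profile`: list with `time` (s) and
#'   `speed` (m/s), one value per window sample.
#' @export
compute_speed <- function(rec, window, cutoff_hz = 6) {
  if (window_length(window) < 3L) {
    fk_stop("speed window must contain at least 3 samples",
            "feedkin_validation_error")
  }
  idx <- window_indices(window)
  p <- lowpass_butter(rec$hand_pos[idx, , drop = FALSE], cutoff_hz,
                      rec$sample_rate)
  n <- nrow(p)
  dt <- 1 / rec$sample_rate
  v <- (p[c(2:n, n), ] - p[c(1L, 1:(n - 1L)), ]) /
    c(dt, rep(2 * dt, n - 2L), dt)
  structure(list(time = rec$time[idx], speed = sqrt(rowSums(v^2))),
            class = "speed_profile")
}

#' Hand path distance metrics over a window
#'
#' Actual distance travelled (path integral of the filtered hand
#' trajectory) and relative distance travelled (actual divided by the
#' straight-line distance between the window's start and end points; 1.0 is
#' a maximally efficient path).
#'
#' @inheritParams compute_speed
#' @return List with `actual_distance_m` and `relative_distance`.
#' @export
path_metrics <- function(rec, window, cutoff_hz = 6) {
  if (window_length(window) < 2L) {
    fk_stop("path window must contain at least 2 samples",
            "feedkin_validation_error")
  }
  idx <- window_indices(window)
  p <- lowpass_butter(rec$hand_pos[idx, , drop = FALSE], cutoff_hz,
                      rec$sample_rate)
  steps <- sqrt(rowSums(diff(p)^2))
  actual <- sum(steps)
  straight <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  if (straight < 1e-3) {
    fk_stop("degenerate window: start and end positions closer than 1 mm",
            "feedkin_validation_error")
  }
  list(actual_distance_m = actual, relative_distance = actual / straight)
}

#' Velocity summary of a speed profile
#'
#' Mean velocity (path length, the time integral of speed, divided by the
#' window duration), maximum velocity, and the timing of maximum velocity
#' as a percentage of the window duration. Ties at the maximum resolve to
#' the first occurrence, so a constant-speed profile has timing 0%.
#'
#' @param sp A `speed_profile`.
#' @return List with `mean_velocity_mps`, `max_velocity_mps`,
#'   `timing_max_velocity_pct`.
#' @export
velocity_metrics <- function(sp) {
  n <- length(sp$speed)
  if (n < 2L) fk_stop("empty speed profile", "feedkin_validation_error")
  dur <- sp$time[n] - sp$time[1L]
  dt <- diff(sp$time)
  dist <- sum((sp$speed[-n] + sp$speed[-1L]) / 2 * dt)  # trapezoid
  i_max <- which.max(sp$speed)
  list(mean_velocity_mps = dist / dur,
       max_velocity_mps = sp$speed[i_max],
       timing_max_velocity_pct = 100 * (sp$time[i_max] - sp$time[1L]) / dur)
}

# interior local extrema by sign change of the first difference; plateaus
# collapse to their midpoint sample
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(), min = integer()))
  d <- sign(diff(x))
  idx <- which(d != 0)
  maxs <- mins <- integer()
  if (length(idx) >= 2L) {
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      at <- (i + 1L + j) %/% 2L  # plateau spans samples (i+1)..j
      if (d[i] > 0 && d[j] < 0) maxs <- c(maxs, at)
      if (d[i] < 0 && d[j] > 0) mins <- c(mins, at)
    }
  }
  list(max = maxs, min = mins)
}

#' Count movement units in a speed profile
#'
#' Implements the smoothness count in three steps: (1) locate local speed
#' maxima and minima by sign change of the first difference, collapsing
#' plateaus to their midpoints; (2) enforce the minimum peak interval --
#' a maximum closer than `min_peak_interval` to the previously retained
#' maximum is merged with it, the larger of the two surviving; (3) count
#' one unit for each retained maximum whose rise above the lowest speed
#' since the previous retained maximum (or since the window start, for the
#' first peak) exceeds `amplitude_limit`.
#'
#' @param sp A `speed_profile` (>= 3 samples).
#' @param params [movement_unit_params()].
#' @return Integer count of movement units.
#' @export
count_movement_units <- function(sp, params = movement_unit_params()) {
  x <- sp$speed
  if (length(x) < 3L) {
    fk_stop("speed profile must contain at least 3 samples",
            "feedkin_validation_error")
  }
  if (all(x <= .Machine$double.eps)) {
    fk_warn("all-zero speed profile: 0 movement units")
    return(0L)
  }
  mx <- local_extrema(x)$max
  if (!length(mx)) return(0L)
  retained <- mx[1L]
  for (m in mx[-1L]) {
    last <- retained[length(retained)]
    if (sp$time[m] - sp$time[last] < params$min_peak_interval) {
      if (x[m] > x[last]) retained[length(retained)] <- m
    } else {
      retained <- c(retained, m)
    }
  }
  count <- 0L
  prev <- 1L  # valley search starts at the window start
  for (m in retained) {
    trough <- min(x[prev:m])
    if (x[m] - trough > params$amplitude_limit) count <- count + 1L
    prev <- m
  }
  count
}

#' Transporting-phase hand spatiotemporal metrics
#'
#' Computes the full transport metric set for a segmented cycle: actual and
#' relative distance travelled, mean and maximum velocity, timing of
#' maximum velocity, and the movement-unit count. By default the metrics
#' are restricted to the transporting phase; any window may be supplied.
#'
#' @param rec A `motion_recording`.
#' @param seg A successful `cycle_segmentation` (ignored when `window` is
#'   given).
#' @param window Optional explicit sample window; defaults to the
#'   transporting phase of `seg`.
#' @param params [movement_unit_params()].
#' @param cutoff_hz Low-pass cutoff for positions in Hz (default 6).
#' @return One-row data frame with participant metadata and the six
#'   transport metrics.
#' @export
transport_metrics <- function(rec, seg = NULL, window = NULL,
                              params = movement_unit_params(),
                              cutoff_hz = 6) {
  if (is.null(window)) {
    if (is.null(seg$phases)) {
      fk_stop("need either a segmentation with phases or an explicit window",
              "feedkin_validation_error")
    }
    window <- seg$phases$Tr
  }
  sp <- compute_speed(rec, window, cutoff_hz)
  pm <- path_metrics(rec, window, cutoff_hz)
  vm <- velocity_metrics(sp)
  data.frame(participant_id = rec$participant_id, sex = rec$sex,
             condition = rec$condition,
             actual_distance_m = pm$actual_distance_m,
             relative_distance = pm$relative_distance,
             mean_velocity_mps = vm$mean_velocity_mps,
             max_velocity_mps = vm$max_velocity_mps,
             timing_max_velocity_pct = vm$timing_max_velocity_pct,
             n_movement_units = count_movement_units(sp, params))
}
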