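#' Run the full analysis pipeline on a directory of trials
#'
#' For every motion CSV in `motion_dir` (with optional `*_events.json`
#' annotations alongside): segment the trial into eating cycles and phases,
#' select the analysed success cycle, compute per-phase joint-angle
#' summaries and transporting-phase hand metrics, then assemble the paired
#' chopsticks-vs-spoon comparison tables per sex stratum. Participants
#' without a successful cycle in both conditions are excluded, mirroring
#' the study's selection rule. Deterministic for fixed inputs and
#' thresholds; every threshold used is recorded in the run log.
#'
#' @param motion_dir Directory of motion CSVs (`<trial>.csv`, optional
#'   `<trial>_events.json`).
#' @param out_dir Output directory; receives `segmentations/*.json`,
#'   `metrics.csv`, `comparison.csv` and `run_log.txt`.
#' @param thresholds [event_thresholds()].
#' @param mu_params [movement_unit_params()].
#' @param cutoff_hz Position low-pass cutoff in Hz (default 6).
#' @param alpha Significance level for the comparison table.
#' @param quantile_type Quantile rule for medians/IQRs (default 6).
#' @return List with `metrics` (long data frame), `comparison` (table from
#'   [compare_conditions()]), `excluded` (participant/condition pairs
#'   without a success cycle), and `out_dir`.
#' @export
run_pipeline <- function(motion_dir, out_dir = NULL,
                         thresholds = event_thresholds(),
                         mu_params = movement_unit_params(),
                         cutoff_hz = 6, alpha = 0.05, quantile_type = 6) {
  if (!dir.exists(motion_dir)) {
    fk_stop(paste0("motion directory not found: ", motion_dir),
            "feedkin_validation_error")
  }
  files <- sort(list.files(motion_dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("truth\\.csv$", files)]
  if (!length(files)) {
    fk_stop(paste0("no motion CSVs in ", motion_dir), "feedkin_validation_error")
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "segmentations"), recursive = TRUE,
               showWarnings = FALSE)
  }
  angle_rows <- list(); hand_rows <- list(); excluded <- list()
  for (f in files) {
    trial <- sub("\\.csv$", "", basename(f))
    rec <- read_motion_csv(f)
    ev_path <- file.path(motion_dir, paste0(trial, "_events.json"))
    ann <- if (file.exists(ev_path)) read_events(ev_path) else NULL
    segs <- tryCatch(
      suppressWarnings(segment_trial(rec, thresholds, ann)),
      feedkin_error = function(e) {
        fk_stop(paste0("segmentation stage failed for trial ", trial, ": ",
                       conditionMessage(e)), "feedkin_stage_error")
      })
    seg <- tryCatch(select_success_cycle(segs),
                    feedkin_participant_exclusion = function(e) NULL)
    if (is.null(seg)) {
      excluded[[trial]] <- data.frame(participant_id = rec$participant_id,
                                      condition = rec$condition)
      next
    }
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(trial = trial, cycle = as.list(seg$cycle),
             phases = lapply(seg$phases, as.list),
             pause_detected_in_reach = seg$pause_detected_in_reach),
        file.path(out_dir, "segmentations", paste0(trial, ".json")),
        auto_unbox = TRUE, pretty = TRUE)
    }
    angle_rows[[trial]] <- cycle_angle_table(rec, seg)
    hand_rows[[trial]] <- transport_metrics(rec, seg, params = mu_params,
                                            cutoff_hz = cutoff_hz)
  }
  if (!length(angle_rows)) {
    fk_stop("no analysable trials", "feedkin_stage_error")
  }
  angles <- do.call(rbind, angle_rows)
  hands <- do.call(rbind, hand_rows)
  # long metric table: angle extrema/ranges/times per phase + transport set
  long <- rbind(
    reshape_metric(angles, "max_deg"), reshape_metric(angles, "min_deg"),
    reshape_metric(angles, "range_deg"),
    movement_time_long(angles), transport_long(hands))
  # participants must have both conditions for a metric to be compared;
  # drop excluded (participant, condition) pairs entirely
  comparison <- suppressWarnings(
    compare_conditions(long, alpha = alpha, quantile_type = quantile_type))
  if (!is.null(out_dir)) {
    write.csv(long, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    writeLines(c(
      "feedkin run log",
      sprintf("motion_dir: %s", normalizePath(motion_dir)),
      sprintf("n_trials: %d (excluded: %d)", length(files), length(excluded)),
      sprintf("d_mouth_m: %g", thresholds$d_mouth),
      sprintf("d_bowl_m: %g", thresholds$d_bowl),
      sprintf("hysteresis_m: %g", thresholds$hysteresis),
      sprintf("min_dwell_s: %g", thresholds$min_dwell),
      sprintf("smoothing_cutoff_hz: %g", thresholds$smoothing_cutoff),
      sprintf("position_cutoff_hz: %g", cutoff_hz),
      sprintf("amplitude_limit_mps: %g", mu_params$amplitude_limit),
      sprintf("min_peak_interval_s: %g", mu_params$min_peak_interval),
      sprintf("alpha: %g", alpha),
      sprintf("quantile_type: %d", as.integer(quantile_type))),
      file.path(out_dir, "run_log.txt"))
  }
  list(metrics = long,
       comparison = comparison,
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
       out_dir = out_dir)
}

reshape_metric <- function(angles, col) {
  data.frame(participant_id = angles$participant_id, sex = angles$sex,
             condition = angles$condition,
             metric = paste(angles$channel, sub("_deg$", "", col), sep = "_"),
             phase = angles$phase, value = angles[[col]])
}

movement_time_long <- function(angles) {
  one <- angles[angles$channel == angles$channel[1], ]
  data.frame(participant_id = one$participant_id, sex = one$sex,
             condition = one$condition, metric = "movement_time_s",
             phase = one$phase, value = one$movement_time_s)
}

transport_long <- function(hands) {
  cols <- c("actual_distance_m", "relative_distance", "mean_velocity_mps",
            "max_velocity_mps", "timing_max_velocity_pct", "n_movement_units")
  do.call(rbind, lapply(cols, function(cl) {
    data.frame(participant_id = hands$participant_id, sex = hands$sex,
               condition = hands$condition, metric = cl, phase = "Tr",
               value = hands[[cl]])
  }))
}

#' Render a comparison table as a markdown report
#'
#' One section per sex stratum, one row per (metric, phase), shaped like a
#' standard paired-comparison table: median (IQR) per condition, z, p, r
#' and the magnitude category. Regenerating the report from the same table
#' yields identical text.
#'
#' @param comparison Data frame from [compare_conditions()] /
#'   [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
report_comparison <- function(comparison) {
  if (!nrow(comparison)) fk_stop("empty comparison table", "feedkin_validation_error")
  fmt <- function(m, q1, q3) sprintf("%.3g (%.3g to %.3g)", m, q1, q3)
  out <- character(0)
  for (st in unique(comparison$stratum)) {
    sub <- comparison[comparison$stratum == st, ]
    out <- c(out, sprintf("## Stratum: %s (n = %d pairs)", st,
                          max(sub$n_pairs)), "",
             "| Metric | Phase | Chopsticks, median (IQR) | Spoon, median (IQR) | z | P | r | Category |",
             "|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(sub))) {
      out <- c(out, sprintf(
        "| %s | %s | %s | %s | %.3f | %.3g | %.3f | %s%s |",
        sub$metric[i], sub$phase[i],
        fmt(sub$median_chopsticks[i], sub$q1_chopsticks[i], sub$q3_chopsticks[i]),
        fmt(sub$median_spoon[i], sub$q1_spoon[i], sub$q3_spoon[i]),
        sub$z[i], sub$p[i], sub$r[i], sub$category[i],
        ifelse(sub$significant[i], " *", "")))
    }
    out <- c(out, "")
  }
  out
}
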