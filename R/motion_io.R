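#' Construct a motion recording
#'
#' Container for one trial of uniformly sampled feeding-motion data: the 11
#' joint-angle channels (degrees, reported sign convention), the 3D position
#' of the hand origin (midpoint between the radial and ulnar styloid
#' processes), and the mouth and bowl reference points, all in metres.
#'
#' @param participant_id Participant label.
#' @param sex `"male"` or `"female"`.
#' @param condition `"chopsticks"` or `"spoon"`.
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing and uniform.
#' @param angles Numeric matrix, one column per [joint_channels()] name,
#'   degrees in the reported convention.
#' @param hand_pos,mouth_pos,bowl_pos n-by-3 numeric matrices of x/y/z
#'   positions in metres (mouth and bowl are typically constant).
#' @param sample_rate Declared sampling rate in Hz (default 120); checked
#'   against the time vector.
#' @param validate Run [validate_motion_recording()] (default `TRUE`).
#' @return Object of class `motion_recording`.
#' @export
motion_recording <- function(participant_id, sex, condition, time, angles,
                             hand_pos, mouth_pos, bowl_pos,
                             sample_rate = 120, validate = TRUE) {
  as3 <- function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y", "z")
    p
  }
  rec <- structure(list(
    participant_id = as.character(participant_id),
    sex = match.arg(sex, c("male", "female")),
    condition = match.arg(condition, c("chopsticks", "spoon")),
    sample_rate = as.numeric(sample_rate),
    time = as.numeric(time),
    angles = as.matrix(angles)[, joint_channels(), drop = FALSE],
    hand_pos = as3(hand_pos), mouth_pos = as3(mouth_pos),
    bowl_pos = as3(bowl_pos)
  ), class = "motion_recording")
  if (validate) validate_motion_recording(rec) else rec
}

#' Validate a motion recording
#'
#' Checks shared series length (>= 2), time uniformity (step within 1e-6 s
#' of 1/sample_rate), and finiteness. NaN runs no longer than 0.1 s are
#' linearly interpolated with a warning; longer runs are an error.
#'
#' @param rec A `motion_recording`.
#' @return The validated (possibly gap-filled) recording, invisibly usable.
#' @export
validate_motion_recording <- function(rec) {
  n <- length(rec$time)
  if (n < 2L) fk_stop("recording must contain at least 2 samples",
                      "feedkin_validation_error")
  lens <- c(nrow(rec$angles), nrow(rec$hand_pos), nrow(rec$mouth_pos),
            nrow(rec$bowl_pos))
  if (any(lens != n)) {
    fk_stop(sprintf("series length mismatch: time has %d samples, data have %s",
                    n, paste(unique(lens), collapse = "/")),
            "feedkin_validation_error")
  }
  dt <- diff(rec$time)
  dev <- max(abs(dt - 1 / rec$sample_rate))
  if (any(dt <= 0) || dev > 1e-6) {
    fk_stop(sprintf(
      "non-uniform sampling: max deviation from 1/%g s step is %.3g s",
      rec$sample_rate, dev), "feedkin_sampling_error")
  }
  max_gap <- ceiling(0.1 * rec$sample_rate)
  fill <- function(col, label) {
    bad <- !is.finite(col)
    if (!any(bad)) return(col)
    runs <- rle(bad)
    if (any(runs$lengths[runs$values] > max_gap) || all(bad)) {
      fk_stop(sprintf("NaN run longer than 0.1 s in %s", label),
              "feedkin_validation_error")
    }
    fk_warn(sprintf("interpolated %d missing sample(s) in %s",
                    sum(bad), label))
    approx(rec$time[!bad], col[!bad], xout = rec$time, rule = 2)$y
  }
  for (ch in colnames(rec$angles)) {
    rec$angles[, ch] <- fill(rec$angles[, ch], ch)
  }
  for (fld in c("hand_pos", "mouth_pos", "bowl_pos")) {
    for (ax in 1:3) {
      rec[[fld]][, ax] <- fill(rec[[fld]][, ax],
                               paste0(fld, "_", c("x", "y", "z")[ax]))
    }
  }
  rec
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf(
    "<motion_recording> %s (%s, %s): %d samples @ %g Hz (%.2f s)\n",
    x$participant_id, x$sex, x$condition, length(x$time), x$sample_rate,
    length(x$time) / x$sample_rate))
  invisible(x)
}

motion_csv_columns <- function() {
  c("time_s", paste0(joint_channels(), "_deg"),
    paste0("hand_", c("x", "y", "z"), "_m"),
    paste0("mouth_", c("x", "y", "z"), "_m"),
    paste0("bowl_", c("x", "y", "z"), "_m"))
}

#' Write a motion recording to CSV
#'
#' One row per sample in a fixed column order (`time_s`, the 11 angle
#' columns in the model sign convention, then hand/mouth/bowl x/y/z in
#' metres), preceded by `#`-comment metadata lines (participant, sex,
#' condition, sample rate). Values are written at full double precision so
#' that a read round-trips to the original recording.
#'
#' @param rec A `motion_recording` (angles in the reported convention; they
#'   are mapped back to the model convention on disk).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(rec, path) {
  validate_motion_recording(rec)
  model_angles <- apply_sign_convention(rec$angles)  # involution: back to model
  m <- cbind(rec$time, model_angles, rec$hand_pos, rec$mouth_pos, rec$bowl_pos)
  colnames(m) <- motion_csv_columns()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# participant_id=%s", rec$participant_id),
    sprintf("# sex=%s", rec$sex),
    sprintf("# condition=%s", rec$condition),
    sprintf("# sample_rate=%.10g", rec$sample_rate),
    paste(colnames(m), collapse = ",")), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a motion recording from CSV
#'
#' Parses the metadata comment block and the sample table, checks that all
#' required columns are present, applies the model-to-reported sign map to
#' the angle channels, infers the sampling rate from the time column and
#' checks it against the declared rate, and validates the result (short NaN
#' gaps interpolated, long gaps rejected).
#'
#' @param path Path to a file written by [write_motion_csv()] (or any CSV
#'   with the same schema).
#' @return A validated `motion_recording`.
#' @export
read_motion_csv <- function(path) {
  if (!file.exists(path)) {
    fk_stop(paste0("file not found: ", path), "feedkin_validation_error")
  }
  hdr <- character()
  con <- file(path, "r")
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  meta <- list()
  for (ln in hdr) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  missing <- setdiff(motion_csv_columns(), names(df))
  if (length(missing)) {
    fk_stop(paste0("motion CSV is missing column(s): ",
                   paste(missing, collapse = ", ")),
            "feedkin_schema_error")
  }
  declared <- as.numeric(meta$sample_rate %||% 120)
  tm <- df$time_s
  if (length(tm) >= 2L) {
    inferred <- 1 / median(diff(tm))
    if (abs(inferred - declared) > 0.01 * declared) {
      fk_stop(sprintf(
        "sampling rate inferred from time column (%.4g Hz) disagrees with declared rate (%.4g Hz)",
        inferred, declared), "feedkin_sampling_error")
    }
  }
  ang <- as.matrix(df[paste0(joint_channels(), "_deg")])
  colnames(ang) <- joint_channels()
  ang <- apply_sign_convention(ang)  # model convention on disk -> reported
  getp <- function(prefix) {
    as.matrix(df[paste0(prefix, "_", c("x", "y", "z"), "_m")])
  }
  motion_recording(
    participant_id = meta$participant_id %||% "unknown",
    sex = meta$sex %||% "male",
    condition = meta$condition %||% "chopsticks",
    time = tm, angles = ang,
    hand_pos = getp("hand"), mouth_pos = getp("mouth"), bowl_pos = getp("bowl"),
    sample_rate = declared)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
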