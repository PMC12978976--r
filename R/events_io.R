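exclusion_reasons <- function() {
  c("none", "excessive_elevation", "looked_away", "extraneous_head_movement",
    "separated_food", "multiple_scoops")
}

#' Construct event annotations for a trial
#'
#' Annotations carry what automatic event detection cannot know: which
#' candidate eating cycles were successes, why a failed cycle was excluded
#' (excessive arm elevation during transport, looking away from the bowl,
#' extraneous head movement, separating food, taking more than one scoop),
#' and optional manually confirmed phase boundaries that override automatic
#' segmentation.
#'
#' @param cycles Data frame with integer columns `start`, `end` (half-open
#'   `[start, end)` windows, 1-based), logical `success`, and character
#'   `exclusion_reason` (one of `"none"`, `"excessive_elevation"`,
#'   `"looked_away"`, `"extraneous_head_movement"`, `"separated_food"`,
#'   `"multiple_scoops"`).
#' @param phase_boundaries Optional list, one entry per cycle: `NULL` or a
#'   named integer vector `c(Re=, Ta=, Tr=, Mo=, end=)` of phase start
#'   indices plus the cycle end.
#' @return Object of class `event_annotations`.
#' @export
event_annotations <- function(cycles, phase_boundaries = NULL) {
  cycles <- as.data.frame(cycles)
  need <- c("start", "end", "success", "exclusion_reason")
  miss <- setdiff(need, names(cycles))
  if (length(miss)) {
    fk_stop(paste0("cycles is missing column(s): ", paste(miss, collapse = ", ")),
            "feedkin_schema_error")
  }
  cycles$start <- as.integer(cycles$start)
  cycles$end <- as.integer(cycles$end)
  cycles$success <- as.logical(cycles$success)
  bad <- setdiff(cycles$exclusion_reason, exclusion_reasons())
  if (length(bad)) {
    fk_stop(paste0("unknown exclusion_reason: ", paste(bad, collapse = ", ")),
            "feedkin_validation_error")
  }
  if (any(cycles$end <= cycles$start) || any(cycles$start < 1L)) {
    fk_stop("cycle windows must satisfy 1 <= start < end",
            "feedkin_validation_error")
  }
  if (nrow(cycles) > 1L) {
    o <- order(cycles$start)
    if (any(o != seq_len(nrow(cycles))) ||
        any(cycles$start[-1L] < cycles$end[-nrow(cycles)])) {
      fk_stop("cycles must be index-ordered and non-overlapping",
              "feedkin_validation_error")
    }
  }
  if (!is.null(phase_boundaries) && length(phase_boundaries) != nrow(cycles)) {
    fk_stop("phase_boundaries must have one entry per cycle",
            "feedkin_validation_error")
  }
  structure(list(cycles = cycles, phase_boundaries = phase_boundaries),
            class = "event_annotations")
}

#' Read event annotations from JSON
#'
#' @param path Path to a JSON file written by [write_events()].
#' @return An `event_annotations` object.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    fk_stop(paste0("file not found: ", path), "feedkin_validation_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cyc <- do.call(rbind, lapply(x$cycles, function(cc) {
    data.frame(start = cc$start, end = cc$end, success = cc$success,
               exclusion_reason = cc$exclusion_reason)
  }))
  pb <- lapply(x$cycles, function(cc) {
    if (is.null(cc$phase_boundaries)) return(NULL)
    unlist(cc$phase_boundaries)[c("Re", "Ta", "Tr", "Mo", "end")]
  })
  if (all(vapply(pb, is.null, logical(1)))) pb <- NULL
  event_annotations(cyc, pb)
}

#' Write event annotations to JSON
#'
#' @param ev An `event_annotations` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(ev, path) {
  stopifnot(inherits(ev, "event_annotations"))
  cycles <- lapply(seq_len(nrow(ev$cycles)), function(i) {
    cc <- list(start = ev$cycles$start[i], end = ev$cycles$end[i],
               success = ev$cycles$success[i],
               exclusion_reason = ev$cycles$exclusion_reason[i])
    if (!is.null(ev$phase_boundaries) && !is.null(ev$phase_boundaries[[i]])) {
      cc$phase_boundaries <- as.list(ev$phase_boundaries[[i]])
    }
    cc
  })
  jsonlite::write_json(list(cycles = cycles), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
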