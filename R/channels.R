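#' Canonical joint-motion channels
#'
#' The eleven joint-motion directions analysed by the pipeline: right
#' shoulder flexion, abduction and internal rotation; right elbow flexion and
#' forearm pronation; right wrist dorsiflexion and ulnar deviation; neck
#' flexion, right lateral flexion and right rotation; and right hip flexion.
#' All angles are in degrees.
#'
#' @return Character vector of the 11 canonical channel names, in the fixed
#'   column order used by the motion CSV format.
#' @export
joint_channels <- function() {
  c("shoulder_flexion", "shoulder_abduction", "shoulder_internal_rotation",
    "elbow_flexion", "forearm_pronation",
    "wrist_dorsiflexion", "wrist_ulnar_deviation",
    "neck_flexion", "neck_right_lateral_flexion", "neck_right_rotation",
    "hip_flexion")
}

#' Sign map from the skeletal-model convention to the reported convention
#'
#' The skeletal model expresses wrist motion as palmar flexion and radial
#' deviation and neck axial rotation as left rotation; the analysis reports
#' dorsiflexion, ulnar deviation and right rotation. Those three channels are
#' negated when mapping model output to reported directions; all other
#' channels pass through unchanged. Because every entry is +1 or -1 the map
#' is an involution: applying it twice restores the raw values.
#'
#' @return Named numeric vector of +1/-1, one entry per [joint_channels()]
#'   name.
#' @export
channel_signs <- function() {
  s <- rep(1, length(joint_channels()))
  names(s) <- joint_channels()
  s[c("wrist_dorsiflexion", "wrist_ulnar_deviation", "neck_right_rotation")] <- -1
  s
}

#' Apply the model-to-reported sign convention to an angle matrix
#'
#' @param angles Numeric matrix or data frame with columns named after
#'   [joint_channels()].
#' @return Object of the same shape with the sign map applied. Applying the
#'   function twice returns the input (the map is its own inverse).
#' @export
apply_sign_convention <- function(angles) {
  s <- channel_signs()
  missing <- setdiff(names(s), colnames(angles))
  if (length(missing)) {
    fk_stop(paste0("angle matrix is missing channel(s): ",
                   paste(missing, collapse = ", ")),
            "feedkin_schema_error")
  }
  for (ch in names(s)) angles[, ch] <- angles[, ch] * s[[ch]]
  angles
}
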