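#' Cohort specification for paired synthetic trials
#'
#' @param n_male,n_female Participants per stratum (defaults 22 and 21, the
#'   analysed study sample).
#' @param angle_shift Named vector of degrees added to chopstick-condition
#'   keyframes of the named channels (commanded condition effect).
#' @param angle_between_sd Between-participant SD of the per-channel angle
#'   offsets in degrees (default 5).
#' @param null_conditions Share pooled defaults across conditions (see
#'   [sim_config()]).
#' @param failure_rate Probability that a candidate cycle is flagged as a
#'   failure in the emitted annotations (default 0: all successes).
#' @param seed Integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 22L, n_female = 21L, angle_shift = NULL,
                        angle_between_sd = 5, null_conditions = FALSE,
                        failure_rate = 0, seed = 1L) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female >= 1,
            failure_rate >= 0, failure_rate <= 1)
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 angle_shift = angle_shift,
                 angle_between_sd = angle_between_sd,
                 null_conditions = null_conditions,
                 failure_rate = failure_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a paired chopsticks/spoon cohort with ground truth
#'
#' One trial per (participant, condition); participant-level random effects
#' (angle offsets and a duration deviate) are shared across the two
#' conditions so the design is genuinely paired. Candidate-cycle
#' success/failure annotations are drawn at `failure_rate`.
#'
#' @param spec [cohort_spec()].
#' @param cfg_male,cfg_female Base [sim_config()] per stratum; `angle_shift`
#'   and `null_conditions` from `spec` are applied on top.
#' @return Object of class `feedkin_cohort`: list of trials (each with
#'   `recording`, `truth`, `annotations`) plus the spec.
#' @export
synth_cohort <- function(spec = cohort_spec(),
                         cfg_male = sim_config("male"),
                         cfg_female = sim_config("female")) {
  set.seed(spec$seed)
  cfg_male$angle_shift <- spec$angle_shift
  cfg_female$angle_shift <- spec$angle_shift
  cfg_male$null_conditions <- spec$null_conditions
  cfg_female$null_conditions <- spec$null_conditions
  roster <- rbind(
    if (spec$n_male) data.frame(sex = "male", i = seq_len(spec$n_male)),
    if (spec$n_female) data.frame(sex = "female", i = seq_len(spec$n_female)))
  trials <- list()
  for (k in seq_len(nrow(roster))) {
    sex <- roster$sex[k]
    cfg <- if (sex == "male") cfg_male else cfg_female
    id <- sprintf("%s%02d", toupper(substr(sex, 1, 1)), roster$i[k])
    angle_offset <- rnorm(length(joint_channels()), 0, spec$angle_between_sd)
    names(angle_offset) <- joint_channels()
    participant <- list(id = id, angle_offset = angle_offset,
                        dur_z = rnorm(1))
    for (condition in c("chopsticks", "spoon")) {
      seed_k <- sample.int(.Machine$integer.max - 1L, 1L)
      tr <- synth_trial(cfg, condition, participant, seed = seed_k)
      n_cyc <- length(tr$truth$cycles)
      fail <- runif(n_cyc) < spec$failure_rate
      reasons <- rep("none", n_cyc)
      if (any(fail)) {
        reasons[fail] <- sample(setdiff(exclusion_reasons(), "none"),
                                sum(fail), replace = TRUE)
      }
      ann <- if (n_cyc > 0) {
        event_annotations(data.frame(
          start = vapply(tr$truth$cycles, `[[`, integer(1), "start"),
          end = vapply(tr$truth$cycles, `[[`, integer(1), "end"),
          success = !fail, exclusion_reason = reasons))
      } else NULL
      trials[[paste(id, condition, sep = "_")]] <-
        list(recording = tr$recording, truth = tr$truth, annotations = ann)
    }
  }
  structure(list(trials = trials, spec = spec), class = "feedkin_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits one motion CSV and one events JSON per trial, plus `truth.csv`
#' collecting the commanded and measured ground-truth transport metrics.
#'
#' @param cohort A `feedkin_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_rows <- list()
  for (nm in names(cohort$trials)) {
    tr <- cohort$trials[[nm]]
    write_motion_csv(tr$recording, file.path(dir, paste0(nm, ".csv")))
    if (!is.null(tr$annotations)) {
      write_events(tr$annotations, file.path(dir, paste0(nm, "_events.json")))
    }
    if (!is.null(tr$truth$transport) && nrow(tr$truth$transport) > 0) {
      truth_rows[[nm]] <- cbind(trial = nm,
                                cycle = seq_len(nrow(tr$truth$transport)),
                                tr$truth$transport)
    }
  }
  if (length(truth_rows)) {
    write.csv(do.call(rbind, truth_rows), file.path(dir, "truth.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Metric-level paired sample with a commanded location shift
#'
#' Fast abstraction of one cohort for calibration and power studies: each
#' participant contributes a shared random effect plus independent
#' measurement noise per condition, and the chopstick condition is shifted
#' by `shift`. Under `shift = 0` the two conditions are exchangeable.
#'
#' @param n_pairs Number of participants.
#' @param shift Location shift added to condition a (chopsticks).
#' @param between_sd Between-participant SD.
#' @param noise_sd Within-participant measurement SD.
#' @return Data frame with columns `participant_id`, `a`, `b`.
#' @export
synth_paired_metric <- function(n_pairs, shift = 0, between_sd = 5,
                                noise_sd = 2) {
  e <- rnorm(n_pairs, 0, between_sd)
  data.frame(participant_id = sprintf("P%03d", seq_len(n_pairs)),
             a = e + shift + rnorm(n_pairs, 0, noise_sd),
             b = e + rnorm(n_pairs, 0, noise_sd))
}

#' Null rejection rate of the paired comparison
#'
#' Simulates cohorts with no condition effect and reports the fraction in
#' which the Wilcoxon signed-rank test rejects at `alpha` -- the empirical
#' size of the test under the generator's null.
#'
#' @param n_rep Number of simulated cohorts.
#' @param n_pairs Participants per cohort.
#' @param alpha Significance level (default 0.05).
#' @param between_sd,noise_sd Passed to [synth_paired_metric()].
#' @param seed Optional seed.
#' @return Rejection proportion.
#' @export
null_rejection_rate <- function(n_rep = 1000L, n_pairs = 22L, alpha = 0.05,
                                between_sd = 5, noise_sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rej <- vapply(seq_len(n_rep), function(i) {
    s <- synth_paired_metric(n_pairs, 0, between_sd, noise_sd)
    wilcoxon_signed_rank_z(s$a, s$b)$p_two_sided < alpha
  }, logical(1))
  mean(rej)
}

#' Detection rate for a commanded condition shift
#'
#' Simulates cohorts with a known location shift and reports the fraction
#' declared significant at `alpha` (empirical power).
#'
#' @inheritParams null_rejection_rate
#' @param shift Commanded location shift.
#' @return Proportion of replicates with p < alpha.
#' @export
shift_detection_rate <- function(n_rep = 200L, n_pairs = 22L, shift = -14,
                                 between_sd = 5, noise_sd = 2, alpha = 0.05,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hit <- vapply(seq_len(n_rep), function(i) {
    s <- synth_paired_metric(n_pairs, shift, between_sd, noise_sd)
    wilcoxon_signed_rank_z(s$a, s$b)$p_two_sided < alpha
  }, logical(1))
  mean(hit)
}
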