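minjerk_s <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

#' Minimum-jerk point-to-point trajectory
#'
#' The smooth reach primitive used throughout the generator:
#' `x(tau) = start + (end - start) * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t/T`, which has zero velocity and acceleration at both endpoints
#' and peak speed `1.875 * D / T` at `tau = 0.5` for a straight segment of
#' length `D`.
#'
#' @param start,end 3D points (metres).
#' @param duration Segment duration `T` in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @return List with `time` (seconds, from 0) and `pos` (n-by-3 matrix).
#' @export
min_jerk_segment <- function(start, end, duration, rate = 120) {
  if (duration <= 0) fk_stop("duration must be > 0", "feedkin_validation_error")
  tm <- seq(0, duration, by = 1 / rate)
  s <- minjerk_s(tm / duration)
  pos <- outer(s, end - start) + rep(start, each = length(s))
  colnames(pos) <- c("x", "y", "z")
  list(time = tm, pos = pos)
}

# lateral bulge height giving a commanded path-length ratio over a straight
# span; the bulged path is p(s) = A + (B-A) s + perp * h * sin(pi s)^2,
# whose tangent is parallel to (B-A) at both ends (no path corner)
detour_height <- function(straight, ratio) {
  if (ratio <= 1 + 1e-9) return(0)
  arc <- function(h) {
    s <- seq(0, 1, length.out = 4001)
    dy <- h * pi * sin(2 * pi * s)
    g <- sqrt(straight^2 + dy^2)
    sum((g[-1] + g[-length(g)]) / 2) * (s[2] - s[1])
  }
  stats::uniroot(function(h) arc(h) - ratio * straight,
                 c(0, 2 * straight), tol = 1e-10)$root
}

unit3 <- function(v) v / sqrt(sum(v^2))

perp3 <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  unit3(c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1]))
}

fk_defaults <- function(name) {
  path <- system.file("extdata", name, package = "feedkin")
  if (!nzchar(path)) {  # during development, before installation
    path <- file.path("inst", "extdata", name)
  }
  read.csv(path)
}

cond_val <- function(x, condition) {
  if (is.null(names(x))) x[[1]] else x[[condition]]
}

#' Simulation configuration for synthetic feeding trials
#'
#' Defaults reproduce the study conditions the generator emulates: 120 Hz
#' sampling; a seated task with the bowl at forward reach (the simulator
#' works in a hand-origin workspace whose mouth/bowl landmark separation is
#' calibrated so that transporting-phase distances fall at the reported
#' scale); phase durations drawn from lognormal distributions with the
#' reported per-sex, per-condition medians and IQR-derived spreads;
#' per-phase joint-angle keyframes drawn around the reported condition
#' medians; mid-reach pauses with probability 0.84 (chopsticks) and 0.65
#' (spoon); per-condition transport detour ratios and submovement counts at
#' the reported medians of relative distance and movement units.
#'
#' @param sex `"male"` or `"female"`: selects the default parameter stratum.
#' @param sample_rate Hz (default 120).
#' @param n_eats Sequential eating movements per trial (default 3, giving
#'   two complete eating cycles).
#' @param thresholds [event_thresholds()] the geometry is calibrated
#'   against.
#' @param mouth 3D mouth landmark (metres).
#' @param reach_dir Unit direction from mouth towards the bowl.
#' @param mouth_offset Hand dwell distance from the mouth landmark, per
#'   condition (metres); larger for the longer utensil.
#' @param bowl_offset Hand dwell distance from the bowl landmark (metres).
#' @param pause_probability Per-condition probability of a mid-reach pause.
#' @param pause_duration_range Pause duration range in seconds.
#' @param detour_ratio Per-condition commanded transport path-length ratio;
#'   `NULL` uses the stratum defaults.
#' @param n_submovements Per-condition commanded transport submovement
#'   count; `NULL` uses the stratum defaults.
#' @param n_submovement_jitter Integer half-width of the uniform per-trial
#'   jitter on the commanded submovement count (default 1; set 0 for an
#'   exactly fixed count).
#' @param angle_noise_sd Gaussian angle noise SD in degrees.
#' @param position_noise_sd Gaussian hand-position noise SD in metres.
#' @param keyframe_jitter_sd Within-participant trial-to-trial SD of keyframe draws in degrees (unreported by motion-capture group tables; 2 degrees is typical joint-angle reproducibility).
#' @param angle_shift Named vector of degrees added to all chopstick-condition
#'   keyframes of the named channels (a commanded condition effect).
#' @param null_conditions If `TRUE` both conditions share pooled keyframe
#'   and duration medians, so the only condition difference is
#'   `angle_shift` (used for effect-recovery experiments).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(sex = "male", sample_rate = 120, n_eats = 3L,
                       thresholds = event_thresholds(),
                       mouth = c(0, 0, 0.30),
                       reach_dir = c(0.55, 0.15, -0.82),
                       mouth_offset = c(chopsticks = 0.06, spoon = 0.035),
                       bowl_offset = 0.02,
                       pause_probability = c(chopsticks = 0.84, spoon = 0.65),
                       pause_duration_range = c(0.3, 1.0),
                       detour_ratio = NULL, n_submovements = NULL,
                       n_submovement_jitter = 1L,
                       angle_noise_sd = 1.0, position_noise_sd = 0.001,
                       keyframe_jitter_sd = 2.0,
                       angle_shift = NULL, null_conditions = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(all(pause_probability >= 0 & pause_probability <= 1))
  hand <- fk_defaults("hand_metric_defaults.csv")
  hand <- hand[hand$sex == sex, ]
  pick <- function(metric, col) hand[hand$metric == metric, col]
  if (is.null(detour_ratio)) {
    detour_ratio <- c(chopsticks = pick("relative_distance", "chop_med"),
                      spoon = pick("relative_distance", "spoon_med"))
  }
  if (is.null(n_submovements)) {
    n_submovements <- c(chopsticks = round(pick("n_movement_units", "chop_med")),
                        spoon = round(pick("n_movement_units", "spoon_med")))
  }
  # landmark separation calibrated so the transporting window (bowl-exit to
  # mouth-entry crossing) has the reported straight-line span
  straight <- c(
    chopsticks = pick("actual_distance_m", "chop_med") /
      pick("relative_distance", "chop_med"),
    spoon = pick("actual_distance_m", "spoon_med") /
      pick("relative_distance", "spoon_med"))
  sep <- straight + thresholds$d_mouth + thresholds$d_bowl + thresholds$hysteresis
  durations <- fk_defaults("phase_duration_defaults.csv")
  durations <- durations[durations$sex == sex, ]
  angles <- fk_defaults("angle_keyframe_defaults.csv")
  angles <- angles[angles$sex == sex, ]
  structure(list(
    sex = sex, sample_rate = sample_rate, n_eats = as.integer(n_eats),
    thresholds = thresholds, mouth = mouth, reach_dir = unit3(reach_dir),
    landmark_separation = sep, mouth_offset = mouth_offset,
    bowl_offset = bowl_offset, pause_probability = pause_probability,
    pause_duration_range = pause_duration_range,
    detour_ratio = detour_ratio, n_submovements = n_submovements,
    n_submovement_jitter = as.integer(n_submovement_jitter),
    angle_noise_sd = angle_noise_sd, position_noise_sd = position_noise_sd,
    keyframe_jitter_sd = keyframe_jitter_sd,
    angle_shift = angle_shift, null_conditions = null_conditions,
    duration_table = durations, angle_table = angles
  ), class = "sim_config")
}

# lognormal parameters for one phase duration
duration_params <- function(cfg, condition, phase) {
  row <- cfg$duration_table[cfg$duration_table$phase == phase, ]
  if (cfg$null_conditions) {
    med <- sqrt(row$chop_med * row$spoon_med)
    q1 <- sqrt(row$chop_q1 * row$spoon_q1); q3 <- sqrt(row$chop_q3 * row$spoon_q3)
  } else if (condition == "chopsticks") {
    med <- row$chop_med; q1 <- row$chop_q1; q3 <- row$chop_q3
  } else {
    med <- row$spoon_med; q1 <- row$spoon_q1; q3 <- row$spoon_q3
  }
  list(meanlog = log(med), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# commanded per-phase keyframe extrema for every channel
draw_keyframes <- function(cfg, condition, participant) {
  tab <- cfg$angle_table
  if (cfg$null_conditions) {
    med <- (tab$chop_med + tab$spoon_med) / 2
  } else if (condition == "chopsticks") med <- tab$chop_med else med <- tab$spoon_med
  val <- med + rnorm(nrow(tab), 0, cfg$keyframe_jitter_sd)
  if (!is.null(participant$angle_offset)) {
    off <- participant$angle_offset[tab$channel]
    off[is.na(off)] <- 0
    val <- val + off
  }
  if (condition == "chopsticks" && !is.null(cfg$angle_shift)) {
    hit <- tab$channel %in% names(cfg$angle_shift)
    val[hit] <- val[hit] + cfg$angle_shift[tab$channel[hit]]
  }
  kf <- data.frame(channel = tab$channel, phase = tab$phase, stat = tab$stat,
                   value = val)
  # enforce min <= max - 0.5 within each (channel, phase)
  wide <- split(kf, paste(kf$channel, kf$phase))
  for (g in wide) {
    mx <- g$value[g$stat == "max"]; mn <- g$value[g$stat == "min"]
    if (mn > mx - 0.5) {
      kf$value[kf$channel == g$channel[1] & kf$phase == g$phase[1] &
                 kf$stat == "min"] <- mx - 0.5
    }
  }
  kf
}

#' Generate one synthetic feeding trial with ground truth
#'
#' Builds the hand trajectory from minimum-jerk primitives -- for each of
#' `n_eats` eating movements: a reach from the mouth dwell point to the
#' bowl (with an optional mid-reach pause), a table dwell with a small
#' picking oscillation, a bowl-to-mouth transport composed of the commanded
#' number of sequential submovements along a path bulged to the commanded
#' detour ratio, and a mouth dwell -- then overlays keyframed joint-angle
#' channels (monotone cubic interpolation through per-phase extrema) and
#' Gaussian angle/position noise. Ground truth (event boundaries, per-phase
#' angle extrema, transport metrics) is computed from the clean, unfiltered
#' trajectory with the same proximity-event rules the segmentation module
#' uses.
#'
#' @param cfg [sim_config()].
#' @param condition `"chopsticks"` or `"spoon"`.
#' @param participant Optional list of participant-level effects:
#'   `id`, `angle_offset` (named degrees), `dur_z` (standard-normal duration
#'   deviate shared across phases).
#' @param seed Optional integer; same seed, config and participant give a
#'   bit-identical trial.
#' @return List with `recording` (a `motion_recording`), and `truth`
#'   (cycle/phase windows, per-phase angle extrema, transport metrics,
#'   commanded parameters).
#' @export
synth_trial <- function(cfg, condition = c("chopsticks", "spoon"),
                        participant = NULL, seed = NULL) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  rate <- cfg$sample_rate
  thr <- cfg$thresholds
  sep <- cond_val(cfg$landmark_separation, condition)
  M <- cfg$mouth
  B <- M + cfg$reach_dir * sep
  if (sep < 1e-6) fk_stop("degenerate geometry: mouth equals bowl",
                          "feedkin_validation_error")
  u <- unit3(B - M)
  Pm <- M + u * cond_val(cfg$mouth_offset, condition)
  Pb <- B - u * cfg$bowl_offset
  n_sub <- as.integer(cond_val(cfg$n_submovements, condition))
  if (cfg$n_submovement_jitter > 0L) {
    j <- cfg$n_submovement_jitter
    n_sub <- max(2L, n_sub + sample(seq.int(-j, j), 1L))
  }
  ratio <- cond_val(cfg$detour_ratio, condition)
  dur_z <- if (is.null(participant)) rnorm(1) else participant$dur_z

  draw_dur <- function(phase, lo, hi) {
    p <- duration_params(cfg, condition, phase)
    min(hi, max(lo, exp(p$meanlog + dur_z * p$sdlog + rnorm(1, 0, 0.05))))
  }

  # --- schedule of motion segments ---------------------------------------
  segments <- list()   # each: t0, T, fun(tau) -> n x 3 positions
  spans <- list()      # phase spans for angle keyframing
  t_cur <- 0
  add_seg <- function(T, fun) {
    segments[[length(segments) + 1L]] <<- list(t0 = t_cur, T = T, fun = fun)
    t_cur <<- t_cur + T
  }
  add_span <- function(phase, t0, t1, eat) {
    spans[[length(spans) + 1L]] <<- list(phase = phase, t0 = t0, t1 = t1,
                                         eat = eat)
  }
  dwell_fun <- function(point, bob = 0, hz = 1.3, T = 1) {
    force(point); force(bob); force(hz); force(T)
    function(tau) {
      n <- length(tau)
      p <- matrix(point, n, 3, byrow = TRUE)
      if (bob > 0) p[, 3] <- p[, 3] + bob * sin(pi * tau)^2 * sin(2 * pi * hz * tau * T)
      p
    }
  }
  mj_fun <- function(from, to) {
    force(from); force(to)
    function(tau) outer(minjerk_s(tau), to - from) + rep(from, each = length(tau))
  }

  # transport structure: a slow approach segment from the bowl dwell point
  # up to just past the bowl-exit radius (its speed peak falls before the
  # bowl-exit crossing, outside the transporting window), the commanded
  # submovements along the bulged span between the two event radii, and a
  # slow final approach into the mouth dwell point. The crossings that
  # bound the measured transporting phase then occur at low speed near the
  # zero-velocity segment junctions, so boundary samples cost little path.
  delta <- 0.0015
  W1 <- B - u * (thr$d_bowl + thr$hysteresis + delta)
  W2 <- M + u * (thr$d_mouth + delta)
  span_vec <- W2 - W1
  straight_w <- sqrt(sum(span_vec^2))
  # solve the bulge for the ratio measured over the window, which includes
  # ~2*delta of straight travel beyond the bulged span
  extra <- 2 * delta
  ratio_eff <- (ratio * (straight_w + extra) - extra) / straight_w
  h <- detour_height(straight_w, ratio_eff)
  pv <- perp3(u)
  path_fun <- function(s) {
    outer(s, span_vec) + rep(W1, each = length(s)) +
      outer(h * sin(pi * s)^2, pv)
  }
  transport_fun <- function(nsub, w) {
    # w: normalized submovement duration weights (later ones faster)
    cw <- c(0, cumsum(w))
    function(tau) {
      k <- findInterval(tau, cw, rightmost.closed = TRUE)
      k <- pmin(pmax(k, 1L), nsub)
      local_tau <- (tau - cw[k]) / w[k]
      s <- (k - 1 + minjerk_s(pmin(pmax(local_tau, 0), 1))) / nsub
      path_fun(s)
    }
  }

  commanded <- list(condition = condition, n_submovements = n_sub,
                    detour_ratio = ratio, durations = list(), pauses = logical(0))

  # quick mouth-depart target: well outside the mouth radius so the
  # mouth-exit crossing happens early and briskly in each reach
  r1_dist <- min(0.14, thr$d_mouth + 0.4 * (sep - thr$d_mouth - thr$d_bowl))
  R1 <- M + u * r1_dist
  T_depart <- 0.4; T_pre <- 0.7; T_post <- 0.45

  add_seg(0.5, dwell_fun(Pm))
  add_span("Mo", 0, 0.5, 0L)
  for (eat in seq_len(cfg$n_eats)) {
    T_re <- draw_dur("Re", 1.4, 12)
    T_ta <- draw_dur("Ta", 0.4, 4)
    T_tr <- draw_dur("Tr", 0.3, 2.5)
    T_tr <- max(T_tr, 0.185 * n_sub)   # keep submovement peaks separable
    T_mo <- draw_dur("Mo", 0.3, 2.5)
    pause <- runif(1) < cond_val(cfg$pause_probability, condition)
    T_pause <- 0
    re_start <- t_cur
    add_seg(T_depart, mj_fun(Pm, R1))
    T_main <- T_re - T_depart
    if (pause) {
      T_pause <- runif(1, cfg$pause_duration_range[1], cfg$pause_duration_range[2])
      if (T_main - T_pause < 0.6) T_pause <- max(0, T_main - 0.6)
      pause <- T_pause >= 0.3
    }
    if (pause) {
      Pp <- R1 + 0.4 * (Pb - R1) + pv * 0.02
      T_move <- T_main - T_pause
      add_seg(0.45 * T_move, mj_fun(R1, Pp))
      add_seg(T_pause, dwell_fun(Pp))
      add_seg(0.55 * T_move, mj_fun(Pp, Pb))
    } else {
      # a reach without a pause is brisk; the long reported reach times come
      # from hesitation, which the pause branch models. Any leftover time is
      # spent hovering at the bowl rim before bowl entry would register, so
      # it is simply dropped from the movement.
      T_main <- min(T_main, 1.6)
      add_seg(T_main, mj_fun(R1, Pb))
    }
    add_span("Re", re_start, t_cur, eat)
    add_seg(T_ta, dwell_fun(Pb, bob = 0.003, T = T_ta))
    add_seg(T_pre, mj_fun(Pb, W1))
    add_span("Ta", t_cur - T_ta - T_pre, t_cur, eat)
    tr_start <- t_cur
    w <- 1.1 - 0.2 * (seq_len(n_sub) - 1) / max(1, n_sub - 1)
    w <- w / sum(w)
    add_seg(T_tr, transport_fun(n_sub, w))
    add_span("Tr", tr_start, t_cur, eat)
    add_seg(T_post, mj_fun(W2, Pm))
    add_seg(T_mo, dwell_fun(Pm))
    add_span("Mo", t_cur - T_mo - T_post, t_cur, eat)
    commanded$durations[[eat]] <- c(Re = T_re, Ta = T_ta, Tr = T_tr, Mo = T_mo)
    commanded$pauses <- c(commanded$pauses, pause)
  }

  n <- floor(t_cur * rate)
  tm <- (seq_len(n) - 1) / rate
  hand <- matrix(NA_real_, n, 3)
  for (sg in segments) {
    sel <- which(tm >= sg$t0 - 1e-12 & tm < sg$t0 + sg$T - 1e-12)
    if (!length(sel)) next
    hand[sel, ] <- sg$fun((tm[sel] - sg$t0) / sg$T)
  }
  # any samples at exact segment joints fall through to the next segment
  if (anyNA(hand[, 1])) {
    ok <- which(!is.na(hand[, 1]))
    for (ax in 1:3) hand[, ax] <- approx(tm[ok], hand[ok, ax], tm, rule = 2)$y
  }

  # --- joint-angle channels ----------------------------------------------
  kf <- draw_keyframes(cfg, condition, participant)
  angles <- matrix(NA_real_, n, length(joint_channels()),
                   dimnames = list(NULL, joint_channels()))
  span_df <- do.call(rbind, lapply(spans, as.data.frame))
  for (ch in joint_channels()) {
    kch <- kf[kf$channel == ch, ]
    get_kv <- function(phase, stat) kch$value[kch$phase == phase & kch$stat == stat]
    mids <- vapply(span_df$phase, function(p) {
      (get_kv(p, "max") + get_kv(p, "min")) / 2
    }, numeric(1))
    tk <- vk <- numeric(0)
    for (i in seq_len(nrow(span_df))) {
      t0 <- span_df$t0[i]; t1 <- span_df$t1[i]; T <- t1 - t0
      vb <- if (i == 1L) mids[i] else {
        v <- (mids[i - 1L] + mids[i]) / 2
        v <- min(max(v, get_kv(span_df$phase[i - 1L], "min")),
                 get_kv(span_df$phase[i - 1L], "max"))
        min(max(v, get_kv(span_df$phase[i], "min")),
            get_kv(span_df$phase[i], "max"))
      }
      tk <- c(tk, t0, t0 + 0.3 * T, t0 + 0.7 * T)
      vk <- c(vk, vb, get_kv(span_df$phase[i], "max"),
              get_kv(span_df$phase[i], "min"))
    }
    tk <- c(tk, t_cur); vk <- c(vk, mids[length(mids)])
    angles[, ch] <- splinefun(tk, vk, method = "monoH.FC")(tm)
  }

  id <- if (is.null(participant)) "synthetic" else participant$id
  mk_rec <- function(hand_m, ang_m) {
    motion_recording(
      participant_id = id, sex = cfg$sex, condition = condition,
      time = tm, angles = ang_m, hand_pos = hand_m,
      mouth_pos = matrix(M, n, 3, byrow = TRUE),
      bowl_pos = matrix(B, n, 3, byrow = TRUE),
      sample_rate = rate)
  }
  rec_clean <- mk_rec(hand, angles)
  noisy_hand <- hand + matrix(rnorm(3 * n, 0, cfg$position_noise_sd), n, 3)
  noisy_ang <- angles + matrix(rnorm(length(angles), 0, cfg$angle_noise_sd),
                               n, ncol(angles))
  rec <- mk_rec(noisy_hand, noisy_ang)

  truth <- trial_ground_truth(rec_clean, thr, commanded)
  list(recording = rec, truth = truth, clean = rec_clean)
}

# ground truth from the clean trajectory: event boundaries from the same
# proximity rules as the segmentation module applied to the unfiltered
# noise-free positions; transport metrics evaluated on the noise-free
# trajectory with the analysis definition's 6 Hz smoothing
trial_ground_truth <- function(rec_clean, thr, commanded,
                               metric_cutoff_hz = 6) {
  thr0 <- thr
  thr0$smoothing_cutoff <- rec_clean$sample_rate  # >= Nyquist: no filtering
  thr0 <- structure(thr0, class = "event_thresholds")
  cycles <- suppressWarnings(detect_cycles(rec_clean, thr0))
  segs <- lapply(cycles, function(cy) {
    tryCatch(segment_phases(rec_clean, cy, thr0), feedkin_error = function(e) NULL)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  transport <- do.call(rbind, lapply(segs, function(sg) {
    transport_metrics(rec_clean, sg, cutoff_hz = metric_cutoff_hz)
  }))
  angles <- do.call(rbind, lapply(seq_along(segs), function(i) {
    cbind(cycle = i, cycle_angle_table(rec_clean, segs[[i]]))
  }))
  list(cycles = cycles, segmentations = segs, transport = transport,
       angle_summaries = angles, commanded = commanded)
}
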