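# shared builders and independent oracles for the test suite

# minimal recording with a prescribed hand path; angles constant unless given
make_recording <- function(hand_pos, rate = 120, angles = NULL,
                           mouth = c(0, 0, 0), bowl = c(1, 1, 1),
                           condition = "chopsticks", sex = "male") {
  n <- nrow(hand_pos)
  if (is.null(angles)) {
    angles <- matrix(30, n, length(joint_channels()),
                     dimnames = list(NULL, joint_channels()))
  }
  motion_recording(
    participant_id = "test", sex = sex, condition = condition,
    time = (seq_len(n) - 1) / rate, angles = angles, hand_pos = hand_pos,
    mouth_pos = matrix(mouth, n, 3, byrow = TRUE),
    bowl_pos = matrix(bowl, n, 3, byrow = TRUE), sample_rate = rate)
}

# random short recording for round-trip property tests
random_recording <- function(n = 6) {
  ang <- matrix(rnorm(n * 11, 20, 30), n, 11,
                dimnames = list(NULL, joint_channels()))
  make_recording(matrix(rnorm(n * 3, 0, 0.2), n, 3), angles = ang,
                 condition = sample(c("chopsticks", "spoon"), 1),
                 sex = sample(c("male", "female"), 1))
}

# speed profile object from raw numbers (bypasses position differentiation)
make_profile <- function(speed, rate = 120) {
  structure(list(time = (seq_along(speed) - 1) / rate, speed = speed),
            class = "speed_profile")
}

# naive O(n^2)-style movement-unit oracle: explicit loops, brute-force
# extrema with plateau collapse, pairwise interval pruning
oracle_movement_units <- function(time, speed, amp = 0.020, interval = 0.150) {
  n <- length(speed)
  if (all(speed <= .Machine$double.eps)) return(0L)
  maxima <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i - 1L
    while (j >= 1L && speed[j] == speed[i]) j <- j - 1L
    k <- i
    while (k < n && speed[k + 1L] == speed[i]) k <- k + 1L
    if (j >= 1L && k < n && speed[j] < speed[i] && speed[k + 1L] < speed[i]) {
      maxima <- c(maxima, (i + k) %/% 2L)  # plateau midpoint
    }
    i <- k + 1L
  }
  if (!length(maxima)) return(0L)
  kept <- maxima[1L]
  for (m in maxima[-1L]) {
    last <- kept[length(kept)]
    if (time[m] - time[last] < interval) {
      if (speed[m] > speed[last]) kept[length(kept)] <- m
    } else kept <- c(kept, m)
  }
  count <- 0L
  prev <- 1L
  for (m in kept) {
    trough <- Inf
    for (q in prev:m) trough <- min(trough, speed[q])
    if (speed[m] - trough > amp) count <- count + 1L
    prev <- m
  }
  count
}

# full 2^n sign enumeration of the signed-rank null; returns W+ and the
# exact mid-p (discreteness-halved two-sided tail)
exact_signed_rank <- function(d) {
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  dev <- abs(w_all - mu); obs <- abs(w_obs - mu)
  list(w_plus = w_obs,
       p_mid = mean(dev > obs + 1e-9) + 0.5 * mean(abs(dev - obs) <= 1e-9),
       p_plain = mean(dev >= obs - 1e-9))
}

# smooth nonnegative random speed profile (occasionally quantised so that
# plateaus occur)
random_speed_profile <- function(n = 240, rate = 120) {
  x <- stats::filter(rnorm(n + 60), rep(1 / 15, 15), sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  sp <- abs(x) * 0.2
  if (runif(1) < 0.3) sp <- round(sp, 2)
  make_profile(sp, rate)
}

noise_free_config <- function(sex = "male", ...) {
  sim_config(sex, angle_noise_sd = 0, position_noise_sd = 0, ...)
}
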