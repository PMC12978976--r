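#' Median and interquartile range
#'
#' Quantiles use the weighted-average-at-(n+1)p definition (R quantile type
#' 6, the SPSS HAVERAGE rule) by default so that summaries match
#' SPSS-style reporting; the rule is switchable.
#'
#' @param x Numeric vector, length >= 1.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 6).
#' @return Named list with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x, type = 6) {
  if (!length(x)) fk_stop("empty input", "feedkin_validation_error")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Wilcoxon signed-rank test, asymptotic z (SPSS convention)
#'
#' Paired two-sided test on differences `a - b`. Zero differences are
#' dropped; ties on |d| receive midranks with the tie-corrected variance;
#' no continuity correction is applied. The statistic is
#' `z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`
#' where `W+` is the sum of positive ranks, so z is negative when condition
#' `a` tends to be smaller than condition `b`.
#'
#' @param a,b Paired numeric vectors of equal length (e.g. chopsticks and
#'   spoon values, one per participant).
#' @param min_n Warn when fewer than this many nonzero differences remain
#'   (default 5); the normal approximation is poor below that.
#' @return List with `z`, `p_two_sided`, `w_plus`, `n_nonzero`.
#' @export
wilcoxon_signed_rank_z <- function(a, b, min_n = 5L) {
  if (length(a) != length(b)) {
    fk_stop("paired samples must have equal length", "feedkin_validation_error")
  }
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    fk_stop("all paired differences are zero: test undefined",
            "feedkin_undefined_test")
  }
  if (n < min_n) {
    fk_warn(sprintf("only %d nonzero difference(s); asymptotic z is unreliable", n))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_plus - mu) / sqrt(sigma2)
  list(z = z, p_two_sided = 2 * pnorm(-abs(z)), w_plus = w_plus,
       n_nonzero = n)
}

#' Effect size r for a Wilcoxon signed-rank comparison
#'
#' `r = z / sqrt(N)` with `N = 2 * n_pairs`, the total observation count of
#' the paired design. The sign of r follows the sign of z.
#'
#' @param z Standard-normal deviate from [wilcoxon_signed_rank_z()].
#' @param n_pairs Number of participant pairs.
#' @return Effect size r in \[-1, 1\].
#' @export
effect_size_r <- function(z, n_pairs) {
  if (any(n_pairs < 1)) fk_stop("n_pairs must be >= 1", "feedkin_validation_error")
  z / sqrt(2 * n_pairs)
}

#' Magnitude category of an effect size
#'
#' Bins |r| at 0.3 (small), 0.5 (medium) and 0.6 (large); values below 0.3
#' are `below_small`.
#'
#' @param r Numeric vector of effect sizes.
#' @return Character vector of categories.
#' @export
categorize_r <- function(r) {
  if (any(!is.finite(r))) fk_stop("r must be finite", "feedkin_validation_error")
  a <- abs(r)
  ifelse(a >= 0.6, "large",
         ifelse(a >= 0.5, "medium",
                ifelse(a >= 0.3, "small", "below_small")))
}

#' Paired utensil comparison table
#'
#' Assembles one Wilcoxon signed-rank comparison per (metric, phase,
#' stratum): condition medians and IQR bounds, z, two-sided p, effect size
#' r with magnitude category, and a significance flag at `alpha`.
#' Participants lacking one of the two conditions are listed and dropped
#' with a warning. When every paired difference is zero the row reports
#' z = 0, p = 1, r = 0 (no evidence of a difference).
#'
#' @param metrics Long data frame with columns `participant_id`, `sex`,
#'   `condition` (`"chopsticks"`/`"spoon"`), `metric`, `value`, and
#'   optionally `phase`.
#' @param alpha Per-test significance level (default 0.05, uncorrected; set
#'   `p_adjust = "holm"` for a Holm correction across the table's rows).
#' @param quantile_type Quantile rule for [median_iqr()] (default 6).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`, matching per-test reporting).
#' @return Data frame with one row per (stratum, metric, phase).
#' @export
compare_conditions <- function(metrics, alpha = 0.05, quantile_type = 6,
                               p_adjust = "none") {
  need <- c("participant_id", "sex", "condition", "metric", "value")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    fk_stop(paste0("metrics table is missing column(s): ",
                   paste(miss, collapse = ", ")), "feedkin_schema_error")
  }
  if (!"phase" %in% names(metrics)) metrics$phase <- NA_character_
  key <- unique(metrics[c("sex", "metric", "phase")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- metrics[metrics$sex == key$sex[i] &
                     metrics$metric == key$metric[i] &
                     (metrics$phase %in% key$phase[i]), ]
    a <- sub[sub$condition == "chopsticks", c("participant_id", "value")]
    b <- sub[sub$condition == "spoon", c("participant_id", "value")]
    both <- intersect(a$participant_id, b$participant_id)
    unpaired <- setdiff(union(a$participant_id, b$participant_id), both)
    if (length(unpaired)) {
      fk_warn(paste0("dropping unpaired participant(s) for ", key$metric[i],
                     "/", key$phase[i], ": ", paste(unpaired, collapse = ", ")))
    }
    va <- a$value[match(both, a$participant_id)]
    vb <- b$value[match(both, b$participant_id)]
    w <- tryCatch(wilcoxon_signed_rank_z(va, vb),
                  feedkin_undefined_test = function(e) {
                    list(z = 0, p_two_sided = 1, w_plus = NA_real_,
                         n_nonzero = 0L)
                  })
    qa <- median_iqr(va, quantile_type); qb <- median_iqr(vb, quantile_type)
    r <- effect_size_r(w$z, length(both))
    data.frame(stratum = key$sex[i], metric = key$metric[i],
               phase = key$phase[i], n_pairs = length(both),
               n_nonzero = w$n_nonzero,
               median_chopsticks = qa$median, q1_chopsticks = qa$q1,
               q3_chopsticks = qa$q3,
               median_spoon = qb$median, q1_spoon = qb$q1, q3_spoon = qb$q3,
               z = w$z, p = w$p_two_sided, r = r,
               category = categorize_r(r))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = p_adjust)
  out$significant <- out$p_adjusted < alpha
  out
}

#' @importFrom stats p.adjust
NULL
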