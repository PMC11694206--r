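#' Magnitude bands for Cohen's d
#'
#' Absolute effect sizes are banded as trivial (< 0.2), small (0.2-0.6),
#' moderate (0.6-1.2), large (1.2-2.0), very large (2.0-4.0) and extremely
#' large (> 4.0). An effect whose confidence interval spans zero - touching
#' zero counts as spanning, the conservative reading - is "unclear"
#' regardless of its point value.
#'
#' @format Named numeric vector of lower band edges.
#' @export
MAGNITUDE_THRESHOLDS <- c(trivial = 0, small = 0.2, moderate = 0.6,
                          large = 1.2, `very large` = 2.0,
                          `extremely large` = 4.0)

#' Classify an effect size into a magnitude band
#'
#' @param d Cohen's d (sign is ignored for banding).
#' @param ci Length-2 numeric, the 95% CI for `d` (lower, upper).
#' @return One of `"unclear"`, `"trivial"`, `"small"`, `"moderate"`,
#'   `"large"`, `"very large"`, `"extremely large"`.
#' @export
#' @examples
#' classify_effect_size(0.68, c(0.64, 0.73))   # "moderate"
#' classify_effect_size(0.03, c(-0.02, 0.07))  # "unclear"
classify_effect_size <- function(d, ci) {
  stopifnot(length(ci) == 2L, ci[1] <= ci[2])
  if (ci[1] <= 0 && ci[2] >= 0) return("unclear")
  band <- findInterval(abs(d), MAGNITUDE_THRESHOLDS)
  names(MAGNITUDE_THRESHOLDS)[max(band, 1L)]
}

# Normal-approximation CI for a paired-design d standardized by s_av.
# Variance follows the common paired-design approximation
#   var(d) = (1/n + d^2/(2 n)) * 2 (1 - r),
# r the correlation between conditions (taken 0 when undefined because a
# condition is constant; the degenerate shift case then still yields a
# zero-width interval through the (1 - r) factor only when r is defined).
paired_d_ci <- function(d, n, r, level = 0.95) {
  if (is.na(r)) r <- 0
  se <- sqrt(pmax((1 / n + d^2 / (2 * n)) * 2 * (1 - r), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(d - z * se, d + z * se)
}

#' Paired mean difference with effect size
#'
#' Estimation-statistics summary of a within-subject contrast: the mean of
#' the paired differences `b - a` with a t-based 95% CI, Cohen's d
#' standardized by the average condition SD
#' `s_av = sqrt((SD(a)^2 + SD(b)^2) / 2)` (not the SD of the differences),
#' a normal-approximation CI for d, and the magnitude label. Pairs with a
#' missing member are dropped.
#'
#' @param a,b Numeric vectors of equal length; `b` is paired with `a` and
#'   the difference reported is `b - a`.
#' @param label Optional interval-pair label (e.g. `"4-3"`).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `pair`, `n`, `mean_diff`, `diff_lo`,
#'   `diff_hi`, `d`, `d_lo`, `d_hi`, `magnitude`.
#' @export
#' @examples
#' paired_mean_diff(c(1, 2, 3), c(2, 3, 4))  # shift of exactly 1, d = 1
paired_mean_diff <- function(a, b, label = NA_character_, level = 0.95) {
  if (length(a) != length(b))
    stop("`a` and `b` must be paired (equal length)", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L)
    stop("insufficient data: need at least 2 complete pairs", call. = FALSE)
  dif <- b - a
  md <- mean(dif)
  sd_d <- sd(dif)
  tcrit <- qt(1 - (1 - level) / 2, df = n - 1)
  ci <- md + c(-1, 1) * tcrit * sd_d / sqrt(n)
  s_av <- sqrt((var(a) + var(b)) / 2)
  d <- if (s_av > 0) md / s_av else 0
  r <- if (sd(a) > 0 && sd(b) > 0) stats::cor(a, b) else NA_real_
  dci <- paired_d_ci(d, n, r, level)
  tibble::tibble(pair = label, n = n, mean_diff = md,
                 diff_lo = ci[1], diff_hi = ci[2],
                 d = d, d_lo = dci[1], d_hi = dci[2],
                 magnitude = classify_effect_size(d, dci))
}

#' Independent-groups mean difference with effect size
#'
#' Between-group contrast `mean(y) - mean(x)` with a t-based 95% CI
#' (equal-variance pooled t by default, Welch optionally), Cohen's d
#' standardized by the pooled SD, a normal-approximation d CI, and the
#' magnitude label.
#'
#' @param x,y Numeric vectors (group 1 and group 2); the difference
#'   reported is `mean(y) - mean(x)`.
#' @param welch Use Welch's unequal-variance interval for the mean
#'   difference instead of the pooled-t interval.
#' @param label Optional comparison label.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `pair`, `n1`, `n2`, `mean_diff`, `diff_lo`,
#'   `diff_hi`, `d`, `d_lo`, `d_hi`, `magnitude`.
#' @export
independent_mean_diff <- function(x, y, welch = FALSE,
                                  label = NA_character_, level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("insufficient data: each group needs at least 2 values",
         call. = FALSE)
  md <- mean(y) - mean(x)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  sp <- sqrt(sp2)
  if (welch) {
    se <- sqrt(var(x) / n1 + var(y) / n2)
    df <- se^4 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  } else {
    se <- sp * sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tcrit <- qt(1 - (1 - level) / 2, df = df)
  ci <- md + c(-1, 1) * tcrit * se
  d <- if (sp > 0) md / sp else 0
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  dci <- c(d - z * se_d, d + z * se_d)
  tibble::tibble(pair = label, n1 = n1, n2 = n2, mean_diff = md,
                 diff_lo = ci[1], diff_hi = ci[2],
                 d = d, d_lo = dci[1], d_hi = dci[2],
                 magnitude = classify_effect_size(d, dci))
}

#' Paired differences between consecutive one-second intervals
#'
#' For each consecutive offset pair of the peri-peak timeline (10-9 s
#' before down to 2-1 s before, then - the peak itself excluded - 1-2 s
#' after up to 9-10 s after: 18 contrasts), matches the two per-second
#' values within each player-match window and summarises them with
#' [paired_mean_diff()]. Each contrast uses only the windows where both
#' offsets are available, so its `n` can differ across contrasts.
#'
#' Pair labels follow the convention `"4-3"` = speed at 3 s before minus
#' speed at 4 s before (pre-peak: later minus earlier, typically positive)
#' and `"1-2"` = speed at 2 s after minus speed at 1 s after (post-peak,
#' typically negative).
#'
#' @param profiles A long tibble of per-second profiles with columns
#'   `window_id`, `offset_s`, `v_kmh`, `available` - one row per window and
#'   integer offset, as produced by stacking [per_second_profile()] outputs.
#' @return A tibble of 18 [paired_mean_diff()] rows plus a `phase` column
#'   (`"pre"` / `"post"`).
#' @export
consecutive_interval_diffs <- function(profiles) {
  need <- c("window_id", "offset_s", "v_kmh", "available")
  if (!all(need %in% names(profiles)))
    stop("`profiles` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(unique(profiles$window_id)) < 2L)
    stop("insufficient data: need at least 2 windows", call. = FALSE)
  wide <- profiles |>
    dplyr::mutate(v_kmh = ifelse(.data$available, .data$v_kmh, NA_real_)) |>
    dplyr::select("window_id", "offset_s", "v_kmh") |>
    tidyr::pivot_wider(names_from = "offset_s", values_from = "v_kmh")
  one <- function(from, to, label, phase) {
    res <- paired_mean_diff(wide[[as.character(from)]],
                            wide[[as.character(to)]], label = label)
    res$phase <- phase
    res
  }
  pre <- lapply(10:2, function(k) one(-k, -(k - 1L),
                                      sprintf("%d-%d", k, k - 1L), "pre"))
  post <- lapply(1:9, function(k) one(k, k + 1L,
                                      sprintf("%d-%d", k, k + 1L), "post"))
  dplyr::bind_rows(c(pre, post))
}

#' n-weighted pooled mean across positions
#'
#' Pools position-level mean speeds at one timeline offset into the overall
#' mean, weighting by the number of windows behind each position mean:
#' `sum(n_i * mean_i) / sum(n_i)`. Used to reconcile position-stratified
#' summary tables with the pooled consecutive-interval differences.
#'
#' @param summary A position summary tibble with columns `position`,
#'   `offset_s`, `mean_kmh`, `n` (see [build_position_summary()]).
#' @param offset Integer timeline offset (-10..10; 0 = peak).
#' @return The pooled mean speed (km/h).
#' @export
pooled_position_means <- function(summary, offset) {
  rows <- summary[summary$offset_s == offset, , drop = FALSE]
  missing_pos <- setdiff(POSITIONS, rows$position)
  if (length(missing_pos))
    stop("missing position(s) at offset ", offset, ": ",
         paste(missing_pos, collapse = ", "), call. = FALSE)
  sum(rows$n * rows$mean_kmh) / sum(rows$n)
}
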