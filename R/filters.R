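#' Noise-filter and peak-validity configuration
#'
#' Collects every threshold the filtering and peak-validation stages use.
#' Defaults follow common practice for elite soccer GNSS monitoring: speeds
#' above 44.45 km/h are physically implausible and excluded; sprinting is
#' speed above 25.2 km/h; high-speed running (HSR) is the 19.8-25.2 km/h
#' band; a match peak speed is only valid if another effort came within
#' 1 km/h of it; sprint typing looks back 0.5 s.
#'
#' @param v_cap_kmh Implausible-speed cap (km/h). Samples above it are
#'   marked missing by [filter_speeds()].
#' @param sprint_threshold_kmh Lower bound of sprinting (km/h, exclusive).
#' @param hsr_band_kmh Length-2 numeric, the high-speed-running band
#'   (km/h, inclusive at both ends).
#' @param corroboration_margin_kmh A candidate peak `v` is valid only if a
#'   second effort reached at least `v - corroboration_margin_kmh`.
#' @param lookback_s Lookback horizon (seconds) for explosive/leading
#'   sprint typing.
#' @return An object of class `filter_config`.
#' @export
#' @examples
#' filter_config()
filter_config <- function(v_cap_kmh = 44.45,
                          sprint_threshold_kmh = 25.2,
                          hsr_band_kmh = c(19.8, 25.2),
                          corroboration_margin_kmh = 1.0,
                          lookback_s = 0.5) {
  stopifnot(length(hsr_band_kmh) == 2L, hsr_band_kmh[1] < hsr_band_kmh[2])
  if (!(v_cap_kmh > sprint_threshold_kmh &&
        sprint_threshold_kmh > hsr_band_kmh[1] && hsr_band_kmh[1] > 0))
    stop("config error: need v_cap > sprint threshold > HSR lower bound > 0",
         call. = FALSE)
  if (corroboration_margin_kmh <= 0)
    stop("config error: corroboration margin must be positive", call. = FALSE)
  if (lookback_s <= 0)
    stop("config error: lookback must be positive", call. = FALSE)
  structure(
    list(v_cap_kmh = v_cap_kmh,
         sprint_threshold_kmh = sprint_threshold_kmh,
         hsr_band_kmh = hsr_band_kmh,
         corroboration_margin_kmh = corroboration_margin_kmh,
         lookback_s = lookback_s),
    class = "filter_config"
  )
}

#' Exclude implausible speed spikes
#'
#' Marks every sample faster than the plausibility cap as missing. Nothing
#' is interpolated: a fabricated value could fabricate a peak. The number of
#' newly excluded samples is accumulated in the trace's `n_filtered` field.
#'
#' @param trace A [speed_trace()].
#' @param cfg A [filter_config()].
#' @return The trace with offending samples marked missing.
#' @export
filter_speeds <- function(trace, cfg = filter_config()) {
  stopifnot(inherits(trace, "speed_trace"))
  hit <- !trace$samples$missing & trace$samples$v_kmh > cfg$v_cap_kmh
  trace$samples$missing[hit] <- TRUE
  trace$n_filtered <- trace$n_filtered + sum(hit)
  trace
}

#' Segment super-threshold bouts
#'
#' A bout is a maximal contiguous run of non-missing samples at or above
#' `threshold`. Bouts operationalise a distinct "effort": two efforts are
#' distinct when speed drops below the threshold (or data are missing)
#' between them.
#'
#' @param trace A [speed_trace()].
#' @param threshold Segmentation threshold (km/h).
#' @return A tibble with one row per bout: `start_idx`, `end_idx` (sample
#'   indices into the trace), `max_kmh`, `t_max_ms`. Zero rows if no sample
#'   reaches the threshold.
#' @export
segment_bouts <- function(trace, threshold) {
  stopifnot(inherits(trace, "speed_trace"))
  s <- trace$samples
  above <- !s$missing & s$v_kmh >= threshold
  if (!any(above))
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          max_kmh = numeric(), t_max_ms = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  max_kmh <- numeric(length(starts)); t_max_ms <- numeric(length(starts))
  for (b in seq_along(starts)) {
    idx <- starts[b]:ends[b]
    j <- idx[which.max(s$v_kmh[idx])]
    max_kmh[b] <- s$v_kmh[j]
    t_max_ms[b] <- s$t_ms[j]
  }
  tibble::tibble(start_idx = starts, end_idx = ends,
                 max_kmh = max_kmh, t_max_ms = t_max_ms)
}

# Bounds (index range) of the contiguous super-(v_ref) run containing idx.
# Missing samples do not close the run: only an *observed* speed below the
# reference does, so a dropped sample cannot manufacture a second "effort".
super_run_bounds <- function(samples, idx, v_ref) {
  below <- !samples$missing & samples$v_kmh < v_ref
  lo <- idx
  while (lo > 1L && !below[lo - 1L]) lo <- lo - 1L
  hi <- idx
  n <- nrow(samples)
  while (hi < n && !below[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}

#' Identify the valid match peak speed
#'
#' The match peak speed is the highest speed a player reached that (a)
#' exceeds the sprint threshold and (b) is corroborated: some other
#' observed sample reached at least `candidate - margin`, with speed
#' observed below `candidate - margin` somewhere between the two, so the
#' corroborating sample belongs to a different effort. Candidates (bout
#' maxima) are examined in descending order of speed, so a single spurious
#' but uncorroborated spike demotes to the next-highest genuine effort
#' instead of voiding the whole match.
#'
#' @param trace A [speed_trace()], already passed through [filter_speeds()].
#' @param cfg A [filter_config()].
#' @return A `peak_event` (list with `peak_kmh`, `t_peak_ms`, `idx`,
#'   `corroborating` `(t_ms, v_kmh)`, `rank` among candidates, validity
#'   flags, and the trace identifiers), or `NULL` when no candidate
#'   qualifies. Absence is a value, not an error.
#' @export
#' @examples
#' tr <- speed_trace(seq(0, 2000, 100),
#'                   c(5, 8, 20, 30, 20, 8, 5, 20, 29.5, 20, 5,
#'                     rep(5, 10)),
#'                   "P01", "M1", "CM")
#' find_match_peak(tr)$peak_kmh  # 30, corroborated by 29.5 >= 29
find_match_peak <- function(trace, cfg = filter_config()) {
  stopifnot(inherits(trace, "speed_trace"))
  s <- trace$samples
  bouts <- segment_bouts(trace, cfg$sprint_threshold_kmh)
  bouts <- bouts[bouts$max_kmh > cfg$sprint_threshold_kmh, , drop = FALSE]
  if (nrow(bouts) == 0L) return(NULL)
  ord <- order(bouts$max_kmh, decreasing = TRUE)
  for (rank in seq_along(ord)) {
    b <- bouts[ord[rank], ]
    idx <- b$start_idx:b$end_idx
    pk_idx <- idx[which.max(s$v_kmh[idx])]
    v_c <- s$v_kmh[pk_idx]
    v_ref <- v_c - cfg$corroboration_margin_kmh
    run <- super_run_bounds(s, pk_idx, v_ref)
    outside <- seq_len(nrow(s)) < run[1] | seq_len(nrow(s)) > run[2]
    cand <- outside & !s$missing & s$v_kmh >= v_ref
    if (any(cand)) {
      j <- which(cand)[which.max(s$v_kmh[cand])]
      return(structure(
        list(peak_kmh = v_c, t_peak_ms = s$t_ms[pk_idx], idx = pk_idx,
             corroborating = list(t_ms = s$t_ms[j], v_kmh = s$v_kmh[j]),
             rank = rank,
             above_threshold = TRUE, corroborated = TRUE,
             player_id = trace$player_id, match_id = trace$match_id,
             position = trace$position),
        class = "peak_event"))
    }
  }
  NULL
}

#' @export
print.peak_event <- function(x, ...) {
  cat(sprintf(
    "<peak_event> %.2f km/h at t = %.1f s (player %s, match %s, %s)\n  corroborated by %.2f km/h at t = %.1f s; candidate rank %d\n",
    x$peak_kmh, x$t_peak_ms / 1000, x$player_id, x$match_id, x$position,
    x$corroborating$v_kmh, x$corroborating$t_ms / 1000, x$rank))
  invisible(x)
}

#' Classify a sprint as explosive or leading
#'
#' Explosive sprints reach the sprint threshold without passing through the
#' high-speed-running band in the preceding 0.5 s; leading sprints arrive
#' via the HSR band. The lookback is taken over the samples immediately
#' before the bout's first super-threshold sample.
#'
#' @param trace A [speed_trace()].
#' @param bout One row of [segment_bouts()] output whose `max_kmh` exceeds
#'   the sprint threshold.
#' @param cfg A [filter_config()].
#' @return `"explosive"` or `"leading"`.
#' @export
classify_sprint <- function(trace, bout, cfg = filter_config()) {
  stopifnot(inherits(trace, "speed_trace"))
  s <- trace$samples
  if (bout$max_kmh <= cfg$sprint_threshold_kmh)
    stop("precondition error: bout does not reach the sprint threshold",
         call. = FALSE)
  idx <- bout$start_idx:bout$end_idx
  over <- idx[!s$missing[idx] & s$v_kmh[idx] > cfg$sprint_threshold_kmh]
  first <- over[1]
  k <- round(cfg$lookback_s * trace$nominal_rate_hz)
  look <- seq.int(max(1L, first - k), first - 1L)
  look <- look[look >= 1L & look < first]
  in_band <- !s$missing[look] &
    s$v_kmh[look] >= cfg$hsr_band_kmh[1] & s$v_kmh[look] <= cfg$hsr_band_kmh[2]
  if (length(look) && any(in_band)) "leading" else "explosive"
}
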