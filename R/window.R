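#' Extract the 20-second peri-peak window
#'
#' Pulls the 201 grid slots from 10 s before to 10 s after the match peak
#' speed, at the trace's own 100 ms grid anchored on the peak sample (no
#' resampling). Slot `k` holds the sample nearest `t_peak + 100 k` ms
#' within +/- 10 ms; slots beyond the trace boundaries, at grid gaps, or at
#' filtered samples are missing. The window always has exactly 201 slots.
#' Any slot faster than the validated peak (possible only when the global
#' maximum failed corroboration and was rejected as noise) is masked.
#'
#' @param trace A filtered [speed_trace()].
#' @param peak A `peak_event` from [find_match_peak()] on this trace.
#' @return A `peak_window`: tibble with columns `offset_ds` (-100..100,
#'   deciseconds from the peak), `v_kmh`, `missing`; the peak event is
#'   attached as attribute `peak`.
#' @export
extract_window <- function(trace, peak) {
  stopifnot(inherits(trace, "speed_trace"), inherits(peak, "peak_event"))
  s <- trace$samples
  offsets <- -100:100
  target <- peak$t_peak_ms + 100 * offsets
  # nearest sample within +/- 10 ms of each slot's nominal time; since the
  # tolerance is well under half the grid spacing, at most one sample fits
  pos <- findInterval(target, s$t_ms)
  slot_idx <- rep(NA_integer_, length(target))
  for (cand in list(pos, pos + 1L)) {
    ok <- which(cand >= 1L & cand <= nrow(s))
    ok <- ok[abs(s$t_ms[cand[ok]] - target[ok]) <= 10]
    slot_idx[ok] <- cand[ok]
  }
  v <- ifelse(is.na(slot_idx), NA_real_, s$v_kmh[slot_idx])
  miss <- is.na(slot_idx) |
    ifelse(is.na(slot_idx), TRUE, s$missing[pmax(slot_idx, 1L)])
  over <- !miss & !is.na(v) & v > peak$peak_kmh
  miss[over] <- TRUE
  v[miss] <- NA_real_
  w <- tibble::tibble(offset_ds = offsets, v_kmh = v, missing = miss)
  structure(w, peak = peak, class = c("peak_window", class(w)))
}

#' Reduce a window to per-second values
#'
#' Produces the 21 values at integer-second offsets -10..+10 (0 = the peak
#' itself). The default `"instant"` mode takes the instantaneous sample at
#' each integer-second slot; `"block_mean"` averages the ten 0.1 s slots of
#' the second-long block ending at (positive offsets) or starting at
#' (negative offsets) that integer second, i.e. blocks are mirrored about
#' the peak. In instant mode a value is unavailable when its slot is
#' missing; in block-mean mode only when all ten slots are.
#'
#' @param window A `peak_window` from [extract_window()].
#' @param mode `"instant"` (default) or `"block_mean"`.
#' @return A tibble with columns `offset_s` (-10..10), `v_kmh`,
#'   `available`.
#' @export
per_second_profile <- function(window, mode = c("instant", "block_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(window, "peak_window"))
  offsets <- -10:10
  if (mode == "instant") {
    slot <- match(offsets * 10L, window$offset_ds)
    v <- window$v_kmh[slot]
    avail <- !window$missing[slot]
  } else {
    v <- numeric(21); avail <- logical(21)
    for (i in seq_along(offsets)) {
      k <- offsets[i]
      ds <- if (k == 0L) 0L
            else if (k > 0L) (10L * (k - 1L) + 1L):(10L * k)
            else (10L * k):(10L * (k + 1L) - 1L)
      slot <- match(ds, window$offset_ds)
      vv <- window$v_kmh[slot][!window$missing[slot]]
      avail[i] <- length(vv) > 0L
      v[i] <- if (avail[i]) mean(vv) else NA_real_
    }
  }
  tibble::tibble(offset_s = offsets, v_kmh = v, available = avail)
}

#' Per-0.1 s speed changes across a window
#'
#' The 200 consecutive deltas `speed(slot j+1) - speed(slot j)` across the
#' 20-second window; a delta is missing when either endpoint is. On a
#' gap-free window the deltas telescope: they sum to
#' `speed(+10 s) - speed(-10 s)`.
#'
#' @param window A `peak_window` from [extract_window()].
#' @return A tibble with columns `from_ds` (-100..99, the left slot of each
#'   delta), `delta_kmh`, `missing`.
#' @export
speed_changes_01s <- function(window) {
  stopifnot(inherits(window, "peak_window"))
  v <- window$v_kmh
  d <- diff(v)
  miss <- window$missing[-length(v)] | window$missing[-1]
  tibble::tibble(from_ds = window$offset_ds[-length(v)],
                 delta_kmh = ifelse(miss, NA_real_, d),
                 missing = miss)
}
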