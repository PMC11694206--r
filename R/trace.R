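#' Construct a speed trace
#'
#' A `speed_trace` holds one player-match speed time series sampled at a
#' nominal 10 Hz: integer milliseconds since session start and speed in km/h,
#' together with the session metadata every downstream stage needs. Samples
#' excluded by filtering (or absent at a grid slot) carry `missing = TRUE`
#' rather than being dropped, so the time grid stays intact.
#'
#' @param t_ms Integer vector, milliseconds since session start. Must be
#'   non-negative and strictly increasing; out-of-order input is an error,
#'   never silently sorted.
#' @param v_kmh Numeric vector of speeds (km/h), same length as `t_ms`.
#'   Must be finite and non-negative.
#' @param player_id,match_id Opaque identifiers (coerced to character).
#' @param position One of `r paste(POSITIONS, collapse = ", ")`.
#' @param missing Logical vector marking samples excluded by filtering.
#' @param nominal_rate_hz Nominal sampling rate; the package assumes 10.
#'
#' @return An object of class `speed_trace`: a list with fields `player_id`,
#'   `match_id`, `position`, `nominal_rate_hz`, `n_filtered` and `samples`
#'   (a tibble with columns `t_ms`, `v_kmh`, `missing`).
#' @export
#' @examples
#' tr <- speed_trace(t_ms = c(0, 100, 200), v_kmh = c(5, 5.2, 5.1),
#'                   player_id = "P01", match_id = "M1", position = "CM")
#' tr
speed_trace <- function(t_ms, v_kmh, player_id, match_id, position,
                        missing = rep(FALSE, length(t_ms)),
                        nominal_rate_hz = 10) {
  t_ms <- as.numeric(t_ms)
  v_kmh <- as.numeric(v_kmh)
  if (length(t_ms) != length(v_kmh))
    stop("`t_ms` and `v_kmh` must have equal length", call. = FALSE)
  if (length(t_ms) == 0L)
    stop("a speed trace needs at least one sample", call. = FALSE)
  if (anyNA(t_ms) || any(t_ms < 0) || any(t_ms != floor(t_ms)))
    stop("`t_ms` must be non-negative integer milliseconds", call. = FALSE)
  if (any(diff(t_ms) <= 0))
    stop("integrity error: `t_ms` must be strictly increasing", call. = FALSE)
  if (anyNA(v_kmh) || any(!is.finite(v_kmh)) || any(v_kmh < 0))
    stop("`v_kmh` must be finite and non-negative", call. = FALSE)
  position <- as.character(position)
  if (length(position) != 1L || !position %in% POSITIONS)
    stop("metadata error: unknown position code '", position,
         "' (expected one of ", paste(POSITIONS, collapse = ", "), ")",
         call. = FALSE)
  structure(
    list(
      player_id = as.character(player_id),
      match_id = as.character(match_id),
      position = position,
      nominal_rate_hz = nominal_rate_hz,
      n_filtered = 0L,
      samples = tibble::tibble(t_ms = t_ms, v_kmh = v_kmh,
                               missing = as.logical(missing))
    ),
    class = "speed_trace"
  )
}

#' @export
print.speed_trace <- function(x, ...) {
  n <- nrow(x$samples)
  span <- (x$samples$t_ms[n] - x$samples$t_ms[1]) / 1000
  cat(sprintf(
    "<speed_trace> player %s, match %s, position %s\n  %d samples over %.1f s (nominal %g Hz), %d filtered\n",
    x$player_id, x$match_id, x$position, n, span, x$nominal_rate_hz,
    x$n_filtered))
  invisible(x)
}

#' Read a speed trace from CSV
#'
#' Reads one player-match trace in the package's fixed dialect: a UTF-8,
#' comma-separated file with header `t_ms,v_kmh`. Rows out of time order are
#' rejected rather than sorted, so upstream export problems surface
#' immediately.
#'
#' @param path Path to the trace CSV.
#' @param metadata A one-row data frame (or list) with `player_id`,
#'   `match_id` and `position` for this trace.
#' @return A [speed_trace()].
#' @seealso [write_trace()], [read_metadata()]
#' @export
read_trace <- function(path, metadata) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # base parser: correctly-rounded doubles, so write -> read is bit-exact
  df <- utils::read.csv(path)
  if (!all(c("t_ms", "v_kmh") %in% names(df)))
    stop("format error: ", path, " must have columns `t_ms` and `v_kmh`",
         call. = FALSE)
  missing <- if ("missing" %in% names(df)) as.logical(df$missing)
             else rep(FALSE, nrow(df))
  speed_trace(df$t_ms, df$v_kmh,
              player_id = metadata$player_id,
              match_id = metadata$match_id,
              position = metadata$position,
              missing = missing)
}

#' Write a speed trace to CSV
#'
#' Inverse of [read_trace()]: emits `t_ms,v_kmh` (plus a `missing` column
#' when any sample is filtered) so that write followed by read round-trips
#' field-for-field.
#'
#' @param trace A [speed_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "speed_trace"))
  df <- trace$samples
  if (!any(df$missing)) df <- df[c("t_ms", "v_kmh")]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read or write a session metadata table
#'
#' Session metadata maps each trace to its player, match and playing
#' position, in a CSV with header `player_id,match_id,position`.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble with character columns `player_id`, `match_id`,
#'   `position`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("player_id", "match_id", "position")
  if (!all(need %in% names(df)))
    stop("format error: metadata must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$position), POSITIONS)
  if (length(bad))
    stop("metadata error: unknown position code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df[need]
}

#' @rdname read_metadata
#' @param metadata Metadata tibble to write.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata[c("player_id", "match_id", "position")], path,
                   progress = FALSE)
  invisible(path)
}

#' Report sampling-grid regularity of a trace
#'
#' The whole pipeline assumes a 100 ms sampling grid (10 Hz). Device jitter
#' up to +/- 10 ms is tolerated; any larger inter-sample interval is counted
#' as a gap. This is a report, not a repair: gaps are never interpolated at
#' the I/O layer.
#'
#' @param trace A [speed_trace()].
#' @param expected_ms Nominal inter-sample interval (default 100 ms).
#' @param jitter_ms Tolerated deviation from `expected_ms` (default 10 ms).
#' @return A list with `n_gaps`, `gaps` (tibble of offending intervals:
#'   `after_t_ms`, `dt_ms`), `max_jitter_ms` (largest deviation among
#'   within-tolerance intervals, 0 if none) and `effective_rate_hz`
#'   (`(n - 1)` divided by the trace time span in seconds).
#' @export
validate_grid <- function(trace, expected_ms = 100, jitter_ms = 10) {
  stopifnot(inherits(trace, "speed_trace"))
  t <- trace$samples$t_ms
  n <- length(t)
  if (n < 2L)
    return(list(n_gaps = 0L,
                gaps = tibble::tibble(after_t_ms = numeric(), dt_ms = numeric()),
                max_jitter_ms = 0, effective_rate_hz = NA_real_))
  dt <- diff(t)
  off <- abs(dt - expected_ms) > jitter_ms
  within <- dt[!off]
  list(
    n_gaps = sum(off),
    gaps = tibble::tibble(after_t_ms = t[-n][off], dt_ms = dt[off]),
    max_jitter_ms = if (length(within)) max(abs(within - expected_ms)) else 0,
    effective_rate_hz = (n - 1) / ((t[n] - t[1]) / 1000)
  )
}
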