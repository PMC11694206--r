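#' Position-stratified per-second summary
#'
#' The per-position table of mean +/- SD speed at each integer-second
#' timeline offset (-10..+10, 0 = the match peak), computed over all
#' retained windows of each position. Each cell's `n` counts the windows
#' where that offset was available, so late- or early-match truncated
#' windows contribute wherever they have data.
#'
#' @param windows Named list of `peak_window` objects (see
#'   [extract_window()]).
#' @param mode Per-second reduction mode, see [per_second_profile()].
#' @return A tibble: `position`, `offset_s`, `mean_kmh`, `sd_kmh`, `n`.
#' @export
build_position_summary <- function(windows, mode = "instant") {
  stopifnot(length(windows) >= 1L)
  long <- window_profiles(windows, mode)
  long |>
    dplyr::filter(.data$available) |>
    dplyr::group_by(.data$position, .data$offset_s) |>
    dplyr::summarise(mean_kmh = mean(.data$v_kmh),
                     sd_kmh = if (dplyr::n() > 1) sd(.data$v_kmh) else 0,
                     n = dplyr::n(), .groups = "drop")
}

# stack per-second profiles of a list of windows into long format,
# carrying window id and position
window_profiles <- function(windows, mode = "instant") {
  dplyr::bind_rows(lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    pk <- attr(w, "peak")
    prof <- per_second_profile(w, mode)
    prof$window_id <- nm
    prof$position <- pk$position
    prof
  }))
}

#' Pairwise between-position peak-speed comparisons
#'
#' All 10 unordered position pairs (in CD, FB, CM, WM, FW order), each
#' summarised with [independent_mean_diff()]. Sign convention:
#' `mean_diff = mean(pos2) - mean(pos1)`, so a negative difference means
#' the first-listed position is faster. Pairs where either group has fewer
#' than 2 peaks are returned with `NA` estimates rather than dropped.
#'
#' @param peaks A tibble with columns `position` and `peak_kmh`, one row
#'   per validated match peak (e.g. the `peaks` element of
#'   [run_pipeline()]'s report).
#' @param welch Use Welch intervals (default pooled-t).
#' @return A tibble with `pos1`, `pos2` and the [independent_mean_diff()]
#'   columns.
#' @export
build_position_comparisons <- function(peaks, welch = FALSE) {
  pairs <- utils::combn(POSITIONS, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    x <- peaks$peak_kmh[peaks$position == p1]
    y <- peaks$peak_kmh[peaks$position == p2]
    base <- tibble::tibble(pos1 = p1, pos2 = p2)
    if (length(x) < 2L || length(y) < 2L)
      return(dplyr::bind_cols(base, tibble::tibble(
        n1 = length(x), n2 = length(y), mean_diff = NA_real_,
        diff_lo = NA_real_, diff_hi = NA_real_, d = NA_real_,
        d_lo = NA_real_, d_hi = NA_real_, magnitude = NA_character_)))
    res <- independent_mean_diff(x, y, welch = welch,
                                 label = paste(p1, p2, sep = "-"))
    dplyr::bind_cols(base, res[setdiff(names(res), "pair")])
  })
  dplyr::bind_rows(rows)
}

#' Run the full peri-peak analysis pipeline
#'
#' End to end: filter implausible speeds, find each trace's valid match
#' peak, extract the 20-second peri-peak windows, and assemble the
#' analysis report - the position summary, the consecutive-interval paired
#' differences, the between-position comparison table, long-format window
#' and 0.1 s delta exports, and run metadata (exclusion and truncation
#' counters). Traces with no valid peak are logged and omitted from every
#' table; a cohort with no valid peak at all yields an empty report with a
#' warning, not an error.
#'
#' @param traces Either a directory of trace CSVs plus `metadata`, or a
#'   named list of [speed_trace()] objects (names are window ids).
#' @param metadata Metadata tibble or path to `metadata.csv`; required
#'   when `traces` is a directory (files are matched as
#'   `<player_id>_<match_id>.csv`). Ignored for in-memory traces.
#' @param cfg A [filter_config()].
#' @param per_second_mode `"instant"` or `"block_mean"`.
#' @return An `analysis_report`: list with `position_summary`,
#'   `interval_diffs`, `position_comparisons`, `peaks`, `windows_long`,
#'   `deltas_long`, `windows` (the `peak_window` objects) and `meta`.
#' @export
run_pipeline <- function(traces, metadata = NULL, cfg = filter_config(),
                         per_second_mode = "instant") {
  if (is.character(traces) && length(traces) == 1L) {
    if (is.character(metadata)) metadata <- read_metadata(metadata)
    if (is.null(metadata))
      stop("metadata is required when reading traces from a directory",
           call. = FALSE)
    paths <- file.path(traces, paste0(metadata$player_id, "_",
                                      metadata$match_id, ".csv"))
    traces <- lapply(seq_len(nrow(metadata)), function(i)
      read_trace(paths[i], metadata[i, ]))
    names(traces) <- paste(metadata$player_id, metadata$match_id, sep = "_")
  }
  stopifnot(is.list(traces))
  if (is.null(names(traces)))
    names(traces) <- vapply(traces, function(tr)
      paste(tr$player_id, tr$match_id, sep = "_"), character(1))

  n_filtered <- 0L
  no_peak <- character(0)
  windows <- list()
  peaks <- list()
  for (nm in names(traces)) {
    tr <- filter_speeds(traces[[nm]], cfg)
    n_filtered <- n_filtered + tr$n_filtered
    pk <- find_match_peak(tr, cfg)
    if (is.null(pk)) {
      no_peak <- c(no_peak, nm)
      next
    }
    peaks[[nm]] <- tibble::tibble(window_id = nm, player_id = pk$player_id,
                                  match_id = pk$match_id,
                                  position = pk$position,
                                  peak_kmh = pk$peak_kmh,
                                  t_peak_ms = pk$t_peak_ms,
                                  candidate_rank = pk$rank)
    windows[[nm]] <- extract_window(tr, pk)
  }

  meta <- list(config = unclass(cfg), per_second_mode = per_second_mode,
               n_traces = length(traces),
               n_windows = length(windows),
               n_samples_filtered = n_filtered,
               traces_without_valid_peak = no_peak,
               n_truncated_windows = sum(vapply(windows, function(w)
                 any(w$missing), logical(1))))

  if (length(windows) == 0L) {
    warning("no trace yielded a valid match peak; returning an empty report")
    return(structure(list(position_summary = NULL, interval_diffs = NULL,
                          position_comparisons = NULL, peaks = NULL,
                          windows_long = NULL, deltas_long = NULL,
                          windows = windows, meta = meta),
                     class = "analysis_report"))
  }

  peaks <- dplyr::bind_rows(peaks)
  long <- window_profiles(windows, per_second_mode)
  windows_long <- dplyr::bind_rows(lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    tibble::tibble(window_id = nm,
                   player_id = attr(w, "peak")$player_id,
                   match_id = attr(w, "peak")$match_id,
                   offset_ds = w$offset_ds, v_kmh = w$v_kmh,
                   missing = w$missing)
  }))
  deltas_long <- dplyr::bind_rows(lapply(names(windows), function(nm) {
    d <- speed_changes_01s(windows[[nm]])
    d$window_id <- nm
    d
  }))
  interval_diffs <- if (length(windows) >= 2L)
    consecutive_interval_diffs(long) else NULL

  structure(list(
    position_summary = build_position_summary(windows, per_second_mode),
    interval_diffs = interval_diffs,
    position_comparisons = build_position_comparisons(peaks),
    peaks = peaks,
    windows_long = windows_long,
    deltas_long = deltas_long,
    windows = windows,
    meta = meta), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "<analysis_report> %d/%d traces with a valid match peak; %d samples filtered\n",
    x$meta$n_windows, x$meta$n_traces, x$meta$n_samples_filtered))
  if (!is.null(x$peaks))
    cat(sprintf("  mean peak %.2f km/h across %d windows (%d truncated)\n",
                mean(x$peaks$peak_kmh), x$meta$n_windows,
                x$meta$n_truncated_windows))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the report as diff-able plain files: one CSV per table (full
#' precision) and a JSON run-metadata sidecar. Identical inputs and config
#' produce byte-identical outputs.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("position_summary", "interval_diffs", "position_comparisons",
              "peaks", "windows_long", "deltas_long")
  for (tb in tables)
    if (!is.null(report[[tb]]))
      readr::write_csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                       progress = FALSE)
  jsonlite::write_json(report$meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
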