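#' Published reference summaries of elite match peak-speed dynamics
#'
#' Bundled summary tables from published monitoring of one elite soccer
#' squad over six first-division matches (90 player-match observations),
#' used as reconciliation oracles for the pipeline's own tables:
#'
#' * `interval_speeds`: per playing position, mean +/- SD speed (km/h) at
#'   each integer-second timeline offset -10..+10 around the match peak
#'   (offset 0 is the peak itself), with the number of windows `n`.
#' * `paired_diffs`: pooled paired mean differences between consecutive
#'   one-second intervals, with 95% CIs, Cohen's d and magnitude labels.
#' * `position_diffs`: pairwise independent mean differences of match peak
#'   speeds between positions, with 95% CIs, d and magnitude labels
#'   (`mean_diff = mean(pos2) - mean(pos1)`).
#'
#' The published summaries are rounded to 2 decimals; reconciliations
#' against them inherit that input precision.
#'
#' @return A list of three tibbles: `interval_speeds`, `paired_diffs`,
#'   `position_diffs`.
#' @export
#' @examples
#' ref <- reference_tables()
#' head(ref$interval_speeds)
reference_tables <- function() {
  dir <- system.file("extdata", "reference", package = "peripeak",
                     mustWork = TRUE)
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE,
                                       progress = FALSE)
  list(interval_speeds = read1("interval_speeds.csv"),
       paired_diffs = read1("paired_diffs.csv"),
       position_diffs = read1("position_diffs.csv"))
}
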