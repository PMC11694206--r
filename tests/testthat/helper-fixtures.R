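# fixtures and independent brute-force oracles used across test files

make_trace <- function(v, position = "CM", player = "P01", match = "M1",
                       missing = rep(FALSE, length(v))) {
  speed_trace(t_ms = (seq_along(v) - 1) * 100, v_kmh = v,
              player_id = player, match_id = match, position = position,
              missing = missing)
}

# a synthetic 201-slot peri-peak window built directly (bypasses detection)
make_window <- function(v, position = "CM", peak_kmh = max(v, na.rm = TRUE),
                        player = "P01", match = "M1") {
  stopifnot(length(v) == 201)
  w <- tibble::tibble(offset_ds = -100:100, v_kmh = v, missing = is.na(v))
  pk <- structure(
    list(peak_kmh = peak_kmh, t_peak_ms = 10000, idx = NA_integer_,
         corroborating = list(t_ms = NA_real_, v_kmh = NA_real_),
         rank = 1L, above_threshold = TRUE, corroborated = TRUE,
         player_id = player, match_id = match, position = position),
    class = "peak_event")
  structure(w, peak = pk, class = c("peak_window", class(w)))
}

# brute-force bout scan: explicit loop over samples
oracle_bouts <- function(trace, threshold) {
  s <- trace$samples
  above <- !s$missing & s$v_kmh >= threshold
  out <- list()
  i <- 1L
  while (i <= nrow(s)) {
    if (above[i]) {
      j <- i
      while (j < nrow(s) && above[j + 1L]) j <- j + 1L
      seg <- i:j
      m <- seg[which.max(s$v_kmh[seg])]
      out[[length(out) + 1L]] <- tibble::tibble(
        start_idx = i, end_idx = j, max_kmh = s$v_kmh[m], t_max_ms = s$t_ms[m])
      i <- j + 1L
    } else i <- i + 1L
  }
  dplyr::bind_rows(out)
}

# brute-force peak rule: candidates are bout maxima in descending order; a
# candidate at index i is corroborated by any observed sample j with
# v[j] >= v[i] - margin such that some observed sample strictly between i
# and j lies below v[i] - margin
oracle_find_peak <- function(trace, cfg = filter_config()) {
  s <- trace$samples
  bouts <- oracle_bouts(trace, cfg$sprint_threshold_kmh)
  bouts <- bouts[bouts$max_kmh > cfg$sprint_threshold_kmh, , drop = FALSE]
  if (nrow(bouts) == 0L) return(NULL)
  for (b in order(bouts$max_kmh, decreasing = TRUE)) {
    seg <- bouts$start_idx[b]:bouts$end_idx[b]
    i <- seg[which.max(s$v_kmh[seg])]
    vref <- s$v_kmh[i] - cfg$corroboration_margin_kmh
    for (j in seq_len(nrow(s))) {
      if (j == i || s$missing[j] || s$v_kmh[j] < vref) next
      lohi <- sort(c(i, j))
      between <- if (lohi[2] - lohi[1] >= 2L) (lohi[1] + 1L):(lohi[2] - 1L)
                 else integer(0)
      sep <- any(!s$missing[between] & s$v_kmh[between] < vref)
      if (sep) return(list(peak_kmh = s$v_kmh[i], t_peak_ms = s$t_ms[i]))
    }
  }
  NULL
}

# brute-force explosive/leading check of the 5-sample lookback
oracle_classify <- function(trace, bout, cfg = filter_config()) {
  s <- trace$samples
  first <- NA_integer_
  for (i in bout$start_idx:bout$end_idx)
    if (!s$missing[i] && s$v_kmh[i] > cfg$sprint_threshold_kmh) {
      first <- i; break
    }
  lead <- FALSE
  for (i in seq(first - 5L, first - 1L))
    if (i >= 1L && !s$missing[i] &&
        s$v_kmh[i] >= cfg$hsr_band_kmh[1] && s$v_kmh[i] <= cfg$hsr_band_kmh[2])
      lead <- TRUE
  if (lead) "leading" else "explosive"
}

# random short trace with plenty of threshold crossings for property tests
random_trace <- function(n = 60, p_missing = 0.05) {
  v <- runif(n, 0, 34)
  miss <- runif(n) < p_missing
  make_trace(v, missing = miss)
}

# small simulated cohort shared by windowing / reporting tests
small_cohort <- function(n = 8, duration_s = 600, seed = 424242, ...) {
  roster <- tibble::tibble(
    player_id = sprintf("P%02d", seq_len(n)),
    match_id = "M1",
    position = rep(peripeak::POSITIONS, length.out = n))
  simulate_cohort(sim_config(duration_s = duration_s, ...), roster, seed)
}
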