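# run code under a temporary RNG state so simulation never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit seed from a master seed and string identifiers, so a
# cohort regenerates stably when the roster is edited
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(paste(..., sep = "\r")))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Synthetic match-trace configuration
#'
#' Parameterizes the simulator that stands in for proprietary club GNSS
#' data. A trace is a ~90-minute 10 Hz speed series: an intermittent
#' locomotor baseline (semi-Markov walk/jog states), a handful of sprint
#' events reached from flying starts, Gaussian observation noise, and
#' optional implausible-spike and gap artifacts.
#'
#' Defaults emulate elite match play: per-position target peak speeds of
#' roughly 29-32 km/h, flying-start speeds around 9 km/h ten seconds before
#' the peak, an effective acceleration lasting several seconds, and
#' deceleration faster than acceleration (`tau_dec_s < tau_acc_s`) to a
#' non-zero post-sprint floor (~7 km/h) - players slow down quickly but do
#' not stop. Each trace draws one target match peak from the position's
#' normal distribution; a second effort is always generated within the
#' corroboration margin of it, and remaining sprints sit lower, so the
#' validity rule the detector applies has a well-defined ground truth.
#'
#' @param duration_s Session length in seconds (default 5400 = 90 min).
#' @param rate_hz Sampling rate (default 10).
#' @param states Locomotor baseline states: tibble with `state`,
#'   `mean_kmh`, `dwell_mean_s` (geometric dwell in 0.1 s steps).
#' @param sprints_per_trace Number of sprint events injected per trace.
#' @param peak_mean_kmh,peak_sd_kmh Named per-position normal parameters of
#'   the target match peak speed (km/h).
#' @param peak_min_kmh Resampling floor for the target peak draw: targets
#'   below it are redrawn so every trace's peak is comfortably above the
#'   sprint threshold plus the corroboration margin. The target peak
#'   distribution is therefore normal truncated at this floor;
#'   [expected_peak_mean()] gives its exact mean.
#' @param start_mean_kmh,start_sd_kmh Flying-start speed distribution.
#' @param tau_acc_s,tau_dec_s Acceleration / deceleration time constants of
#'   the mono-exponential sprint shape; `tau_dec_s < tau_acc_s` enforced.
#' @param rise_s,fall_s Durations of the rising and falling sprint phases.
#' @param floor_kmh Mean post-sprint floor speed.
#' @param floor_sd_kmh Between-sprint SD of the post-sprint floor. Players
#'   settle to different speeds after different sprints; without this
#'   heterogeneity the post-peak timeline would be implausibly uniform
#'   across windows.
#' @param shape_jitter_sd SD of the log-normal multiplier applied per
#'   sprint to both time constants (each sprint accelerates and
#'   decelerates on its own timescale; the multiplier is common to both,
#'   preserving `tau_dec_s < tau_acc_s`).
#' @param noise_sd_kmh Gaussian observation-noise SD.
#' @param n_spikes Implausible spike artifacts per trace (speed above the
#'   44.45 km/h plausibility cap).
#' @param spike_range_kmh Range spikes are drawn from.
#' @param n_gaps Grid gaps injected per trace (runs of dropped samples).
#' @param gap_len_samples Range of dropped-run lengths.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 5400,
                       rate_hz = 10,
                       states = tibble::tibble(
                         state = c("stand", "walk", "jog", "run"),
                         mean_kmh = c(0.3, 5, 9, 14),
                         dwell_mean_s = c(5, 8, 6, 3)),
                       sprints_per_trace = 6,
                       peak_mean_kmh = c(CD = 29.11, FB = 31.64, CM = 30.26,
                                         WM = 30.68, FW = 29.83),
                       peak_sd_kmh = c(CD = 1.64, FB = 1.94, CM = 2.23,
                                       WM = 2.61, FW = 1.88),
                       peak_min_kmh = 26.5,
                       start_mean_kmh = 9, start_sd_kmh = 2,
                       tau_acc_s = 2.5, tau_dec_s = 2.0,
                       rise_s = 6, fall_s = 8,
                       floor_kmh = 7, floor_sd_kmh = 2.5,
                       shape_jitter_sd = 0.25,
                       noise_sd_kmh = 0.15,
                       n_spikes = 2, spike_range_kmh = c(45.5, 60),
                       n_gaps = 0, gap_len_samples = c(2, 10)) {
  if (!(tau_dec_s < tau_acc_s))
    stop("config error: deceleration must be faster than acceleration (tau_dec_s < tau_acc_s)",
         call. = FALSE)
  if (noise_sd_kmh < 0 || start_sd_kmh < 0 || any(peak_sd_kmh < 0))
    stop("config error: SDs must be non-negative", call. = FALSE)
  if (!all(POSITIONS %in% names(peak_mean_kmh)))
    stop("config error: peak_mean_kmh must name all positions", call. = FALSE)
  if (any(peak_mean_kmh <= 25.2))
    stop("config error: peak targets must exceed the 25.2 km/h sprint threshold",
         call. = FALSE)
  if (sprints_per_trace < 2)
    stop("config error: need at least 2 sprints for a corroborated peak",
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# locomotor baseline: semi-Markov state process with geometric dwell times,
# smoothed toward each state's target speed with a ~1 s time constant
simulate_baseline <- function(cfg, n) {
  st <- cfg$states
  target <- numeric(0)
  cur <- sample(nrow(st), 1L)
  while (length(target) < n) {
    dwell <- stats::rgeom(1, 1 / (st$dwell_mean_s[cur] * cfg$rate_hz)) + 1L
    target <- c(target, rep(st$mean_kmh[cur], dwell))
    cur <- sample(setdiff(seq_len(nrow(st)), cur), 1L)
  }
  target <- target[seq_len(n)]
  a <- exp(-1 / (1 * cfg$rate_hz))  # 1 s smoothing time constant
  as.numeric(stats::filter((1 - a) * target, a, method = "recursive",
                           init = target[1]))
}

# exponential sprint profile: v(start) -> exact v_peak over rise_s, then
# decay to the floor over fall_s; both phases normalized so the endpoints
# are hit exactly (the apex sample equals the drawn peak)
sprint_profile <- function(cfg, v_start, v_peak, floor = cfg$floor_kmh,
                           tau_mult = 1) {
  n_up <- round(cfg$rise_s * cfg$rate_hz)
  n_dn <- round(cfg$fall_s * cfg$rate_hz)
  tau_a <- cfg$tau_acc_s * tau_mult
  tau_d <- cfg$tau_dec_s * tau_mult
  tu <- seq_len(n_up) / cfg$rate_hz
  eu <- (1 - exp(-tu / tau_a)) / (1 - exp(-cfg$rise_s / tau_a))
  up <- v_start + (v_peak - v_start) * eu
  td <- seq_len(n_dn) / cfg$rate_hz
  ed <- (exp(-td / tau_d) - exp(-cfg$fall_s / tau_d)) /
    (1 - exp(-cfg$fall_s / tau_d))
  dn <- floor + (v_peak - floor) * ed
  c(up, dn)  # apex is up[n_up] == v_peak
}

#' Simulate one player-match speed trace with ground truth
#'
#' @param cfg A [sim_config()].
#' @param position Playing position (determines the target peak-speed
#'   distribution).
#' @param seed Integer seed; the same seed reproduces the trace bit for
#'   bit.
#' @param player_id,match_id Identifiers stamped on the trace.
#' @return A list with `trace` (a [speed_trace()]) and `truth`: the drawn
#'   target match peak (`true_peak_kmh`), per-sprint apex times and
#'   noise-free peaks (`sprints`), spike times (`spike_t_ms`) and injected
#'   gaps (`gaps`).
#' @export
#' @examples
#' sim <- simulate_trace(sim_config(duration_s = 600), "CM", seed = 7)
#' sim$truth$true_peak_kmh
simulate_trace <- function(cfg, position, seed,
                           player_id = "P01", match_id = "M1") {
  stopifnot(inherits(cfg, "sim_config"))
  position <- match.arg(position, POSITIONS)
  with_local_seed(seed, {
    n <- cfg$duration_s * cfg$rate_hz
    v <- simulate_baseline(cfg, n)

    # sprint apexes: one per equal segment of the match, jittered, kept
    # clear of the edges so full peri-peak windows exist
    k <- cfg$sprints_per_trace
    margin_n <- 15 * cfg$rate_hz
    seg <- seq(margin_n, n - margin_n, length.out = k + 1L)
    apex <- round(runif(k, seg[-(k + 1L)] + 0.15 * diff(seg),
                        seg[-1L] - 0.15 * diff(seg)))

    # target match peak for this trace, plus a guaranteed corroborating
    # second effort within half the validity margin; other sprints lower
    repeat {
      v_star <- rnorm(1, cfg$peak_mean_kmh[[position]],
                      cfg$peak_sd_kmh[[position]])
      if (v_star > cfg$peak_min_kmh) break
    }
    peaks <- numeric(k)
    slots <- sample.int(k, k)
    peaks[slots[1]] <- v_star
    peaks[slots[2]] <- v_star - runif(1, 0.1, 0.5)
    if (k > 2)
      peaks[slots[-(1:2)]] <- runif(k - 2, 25.6, max(25.7, v_star - 0.6))

    n_up <- round(cfg$rise_s * cfg$rate_hz)
    n_lead <- 3 * cfg$rate_hz  # 3 s blend into / out of the baseline
    for (i in seq_len(k)) {
      v_start <- max(2, rnorm(1, cfg$start_mean_kmh, cfg$start_sd_kmh))
      floor_i <- min(max(rnorm(1, cfg$floor_kmh, cfg$floor_sd_kmh), 0.5),
                     peaks[i] - 10)
      prof <- sprint_profile(cfg, v_start, peaks[i], floor = floor_i,
                             tau_mult = exp(rnorm(1, 0, cfg$shape_jitter_sd)))
      i_rise <- apex[i] - n_up + 1L
      # linear lead-in from the current baseline to the flying start, and
      # lead-out from the post-sprint floor back to the baseline, so sprint
      # insertion introduces no speed discontinuities
      li <- (i_rise - n_lead):(i_rise - 1L)
      v[li] <- seq(v[li[1]], prof[1], length.out = n_lead + 1L)[-(n_lead + 1L)]
      idx <- i_rise:(i_rise + length(prof) - 1L)
      v[idx] <- prof
      i_end <- idx[length(idx)]
      lo <- (i_end + 1L):(i_end + n_lead)
      v[lo] <- seq(prof[length(prof)], v[lo[n_lead] + 1L],
                   length.out = n_lead + 2L)[2:(n_lead + 1L)]
    }

    if (cfg$noise_sd_kmh > 0) v <- v + rnorm(n, 0, cfg$noise_sd_kmh)
    v <- pmax(v, 0)

    # implausible spikes, kept clear of sprint neighbourhoods so windows
    # and ground truth stay interpretable
    spike_idx <- integer(0)
    if (cfg$n_spikes > 0) {
      near_sprint <- unlist(lapply(apex, function(a)
        (a - 12 * cfg$rate_hz):(a + 12 * cfg$rate_hz)))
      pool <- setdiff(seq_len(n), near_sprint)
      spike_idx <- sort(sample(pool, cfg$n_spikes))
      v[spike_idx] <- runif(cfg$n_spikes, cfg$spike_range_kmh[1],
                            cfg$spike_range_kmh[2])
    }

    t_ms <- (seq_len(n) - 1L) * (1000 / cfg$rate_hz)

    # gap injection: drop short runs of samples (never at sprints/spikes)
    gaps <- tibble::tibble(after_t_ms = numeric(), n_dropped = integer())
    drop <- integer(0)
    if (cfg$n_gaps > 0) {
      near_sprint <- unlist(lapply(apex, function(a)
        (a - 12 * cfg$rate_hz):(a + 12 * cfg$rate_hz)))
      pool <- setdiff(seq(2L, n - 1L), c(near_sprint, spike_idx,
                                         spike_idx + 1L, spike_idx - 1L))
      starts <- sort(sample(pool, cfg$n_gaps))
      # enforce separation so injected gaps never merge
      while (any(diff(starts) < 2 * max(cfg$gap_len_samples) + 2)) {
        starts <- sort(sample(pool, cfg$n_gaps))
      }
      for (g in starts) {
        len <- sample(seq(cfg$gap_len_samples[1], cfg$gap_len_samples[2]), 1L)
        run <- g:min(g + len - 1L, n - 1L)
        drop <- c(drop, run)
        gaps <- dplyr::bind_rows(gaps, tibble::tibble(
          after_t_ms = t_ms[g - 1L], n_dropped = length(run)))
      }
    }
    keep <- setdiff(seq_len(n), drop)

    trace <- speed_trace(t_ms[keep], v[keep], player_id, match_id, position)
    truth <- list(
      true_peak_kmh = v_star,
      sprints = tibble::tibble(t_apex_ms = t_ms[apex],
                               v_peak_kmh = peaks),
      spike_t_ms = t_ms[spike_idx],
      gaps = gaps)
    list(trace = trace, truth = truth)
  })
}

#' Expected target match peak under a simulator configuration
#'
#' The simulator draws each trace's target match peak from a normal
#' distribution truncated below at `peak_min_kmh` (targets too close to the
#' sprint threshold are redrawn, since an uncorroborated or sub-threshold
#' peak is not a match peak at all). This returns the exact mean of that
#' truncated normal - the quantity detection should recover on average.
#'
#' @param cfg A [sim_config()].
#' @param position Playing position.
#' @return Expected target peak speed (km/h).
#' @export
expected_peak_mean <- function(cfg, position) {
  mu <- cfg$peak_mean_kmh[[position]]
  s <- cfg$peak_sd_kmh[[position]]
  a <- (cfg$peak_min_kmh - mu) / s
  mu + s * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Simulate a cohort of player-matches
#'
#' One trace per roster row, with per-trace seeds derived deterministically
#' from the master seed and the player/match identifiers, so regenerating
#' with the same master seed gives an identical cohort (and roster edits do
#' not reshuffle unrelated traces).
#'
#' @param cfg A [sim_config()].
#' @param roster Tibble with `player_id`, `match_id`, `position` (one row
#'   per player-match to simulate), e.g. [default_roster()].
#' @param seed Master integer seed.
#' @param dir Optional output directory; when given, writes one trace CSV
#'   per row (`<player>_<match>.csv`), `metadata.csv`, and
#'   `ground_truth.json`, all in the package's CSV dialect.
#' @return Invisibly when `dir` is given, otherwise a list with `traces`
#'   (named list of [speed_trace()]), `metadata` and `truth`.
#' @export
simulate_cohort <- function(cfg, roster, seed, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(roster) == 0L) {
    out <- list(traces = list(), metadata = roster, truth = list())
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_metadata(roster, file.path(dir, "metadata.csv"))
      return(invisible(out))
    }
    return(out)
  }
  bad <- setdiff(unique(roster$position), POSITIONS)
  if (length(bad))
    stop("metadata error: unknown position code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  sims <- vector("list", nrow(roster))
  names(sims) <- paste(roster$player_id, roster$match_id, sep = "_")
  for (i in seq_len(nrow(roster))) {
    sims[[i]] <- simulate_trace(
      cfg, roster$position[i],
      seed = derive_seed(seed, roster$player_id[i], roster$match_id[i]),
      player_id = roster$player_id[i], match_id = roster$match_id[i])
  }
  out <- list(traces = lapply(sims, `[[`, "trace"),
              metadata = tibble::as_tibble(roster),
              truth = lapply(sims, `[[`, "truth"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out$traces))
      write_trace(out$traces[[nm]], file.path(dir, paste0(nm, ".csv")))
    write_metadata(out$metadata, file.path(dir, "metadata.csv"))
    jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Default 20-player, 6-match roster
#'
#' A squad of 4 central defenders, 3 fullbacks, 5 central midfielders,
#' 5 wide midfielders and 3 forwards over six matches, with a fixed
#' absence pattern thinning the 120 player-matches to 90 observations
#' (per-position window counts 20/10/19/24/17 for CD/FB/CM/WM/FW) - the
#' cohort geometry typical of one elite squad over six fixtures.
#'
#' @return A roster tibble (`player_id`, `match_id`, `position`), 90 rows.
#' @export
default_roster <- function() {
  squad <- tibble::tibble(
    player_id = sprintf("P%02d", 1:20),
    position = rep(POSITIONS, times = c(4, 3, 5, 5, 3)))
  full <- tidyr::crossing(squad, match_id = sprintf("M%d", 1:6))
  absences <- c(CD = 4L, FB = 8L, CM = 11L, WM = 6L, FW = 1L)
  keep <- unlist(lapply(POSITIONS, function(p) {
    rows <- which(full$position == p)
    # drop a fixed evenly spread subset of this position's player-matches
    drop <- rows[round(seq(1, length(rows), length.out = absences[[p]] + 2))[
      seq_len(absences[[p]]) + 1L]]
    setdiff(rows, drop)
  }))
  full[sort(keep), c("player_id", "match_id", "position")]
}
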