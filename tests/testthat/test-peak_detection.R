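test_that("implausible speed spikes are marked missing, nothing else", {
  v <- c(5, 10, 50, 12, 5)
  tr <- filter_speeds(make_trace(v))
  expect_equal(tr$samples$missing, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(tr$n_filtered, 1L)
  expect_equal(tr$samples$v_kmh, v)  # values untouched, only masked

  tr2 <- filter_speeds(make_trace(c(5, 44.45, 30)))
  expect_equal(tr2$n_filtered, 0L)
  expect_false(any(tr2$samples$missing))
})

test_that("seeded simulator spikes are filtered exactly", {
  for (k in c(1L, 4L)) {
    sim <- simulate_trace(sim_config(duration_s = 900, n_spikes = k),
                          "FW", seed = 300 + k)
    tr <- filter_speeds(sim$trace)
    expect_equal(tr$n_filtered, k)
    expect_setequal(tr$samples$t_ms[tr$samples$missing],
                    sim$truth$spike_t_ms)
  }
})

test_that("bout segmentation finds maximal contiguous super-threshold runs", {
  expect_equal(nrow(segment_bouts(make_trace(rep(10, 20)), 25.2)), 0L)

  tr <- make_trace(c(20, 26, 27, 26, 20, 26, 20))
  b <- segment_bouts(tr, 25.2)
  expect_equal(nrow(b), 2L)
  expect_equal(b$max_kmh, c(27, 26))
  expect_equal(b$start_idx, c(2L, 6L))
  expect_equal(b$end_idx, c(4L, 6L))
})

test_that("bout segmentation matches a brute-force scan on random traces", {
  set.seed(901)
  for (i in 1:200) {
    tr <- random_trace()
    thr <- runif(1, 5, 30)
    expect_equal(segment_bouts(tr, thr), oracle_bouts(tr, thr))
  }
})

test_that("the corroborating-effort rule validates match peaks", {
  # two separated efforts: 30.0 corroborated by 29.5 (>= 29.0)
  v <- c(rep(5, 5), 26, 30, 26, rep(5, 5), 26, 29.5, 26, rep(5, 5))
  pk <- find_match_peak(make_trace(v))
  expect_equal(pk$peak_kmh, 30)
  expect_equal(pk$corroborating$v_kmh, 29.5)
  expect_equal(pk$rank, 1L)

  # single effort, nothing else within 1 km/h: no valid peak
  v1 <- c(rep(5, 5), 28.9, 30, 28.9, rep(5, 10))
  expect_null(find_match_peak(make_trace(v1)))

  # demote past an uncorroborated maximum: 30 invalid, 28 valid (both the
  # rejected 30 and the 27.5 effort lie within 1 km/h-relaxed reach of 28)
  v2 <- c(rep(5, 4), 30, rep(5, 4), 28, rep(5, 4), 27.5, rep(5, 4))
  pk2 <- find_match_peak(make_trace(v2))
  expect_equal(pk2$peak_kmh, 28)
  expect_gte(pk2$corroborating$v_kmh, 27)
  expect_equal(pk2$rank, 2L)
})

test_that("a corroborating sample inside the peak's own run does not count", {
  # plateau 30, 29.6, 30 never drops below 29: one effort, invalid
  v <- c(rep(5, 5), 30, 29.6, 30, rep(5, 10))
  expect_null(find_match_peak(make_trace(v)))
  # same shape but with an observed dip below 29 between: two efforts
  v2 <- c(rep(5, 5), 30, 28.5, 29.6, rep(5, 10))
  expect_equal(find_match_peak(make_trace(v2))$peak_kmh, 30)
})

test_that("peak detection matches the brute-force oracle on random traces", {
  set.seed(902)
  for (i in 1:300) {
    tr <- random_trace()
    got <- find_match_peak(tr)
    want <- oracle_find_peak(tr)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$peak_kmh, want$peak_kmh)
      expect_equal(got$t_peak_ms, want$t_peak_ms)
    }
  }
})

test_that("a detected peak always exceeds the sprint threshold and never the
           post-filter maximum", {
  set.seed(903)
  for (i in 1:100) {
    tr <- random_trace()
    pk <- find_match_peak(tr)
    if (is.null(pk)) next
    expect_gt(pk$peak_kmh, 25.2)
    expect_lte(pk$peak_kmh,
               max(tr$samples$v_kmh[!tr$samples$missing]))
  }
})

test_that("widening the corroboration margin relaxes validity for separated
           efforts", {
  # efforts at 30 and 28.5, fully separated: at margin 1 the 30 km/h
  # maximum is uncorroborated and detection demotes to 28.5; once the
  # margin covers the 1.5 km/h gap the maximum itself is valid
  v <- c(rep(5, 4), 30, rep(5, 4), 28.5, rep(5, 4))
  tr <- make_trace(v)
  pk1 <- find_match_peak(tr, filter_config(corroboration_margin_kmh = 1))
  expect_equal(pk1$peak_kmh, 28.5)
  expect_equal(pk1$rank, 2L)
  pk2 <- find_match_peak(tr, filter_config(corroboration_margin_kmh = 2))
  expect_equal(pk2$peak_kmh, 30)
  expect_equal(pk2$rank, 1L)
})

test_that("sprints are typed explosive or leading by the 0.5 s lookback", {
  cfg <- filter_config()
  tr_ex <- make_trace(c(rep(15, 5), 26, 26, rep(15, 5)))
  b_ex <- segment_bouts(tr_ex, cfg$sprint_threshold_kmh)[1, ]
  expect_equal(classify_sprint(tr_ex, b_ex, cfg), "explosive")

  tr_ld <- make_trace(c(rep(15, 4), 20, 22, 24, 26, rep(15, 5)))
  b_ld <- segment_bouts(tr_ld, cfg$sprint_threshold_kmh)[1, ]
  expect_equal(classify_sprint(tr_ld, b_ld, cfg), "leading")

  b_low <- tibble::tibble(start_idx = 1L, end_idx = 2L, max_kmh = 20,
                          t_max_ms = 0)
  expect_error(classify_sprint(tr_ld, b_low, cfg), "precondition")
})

test_that("sprint typing matches a brute-force lookback on random ramps", {
  set.seed(904)
  cfg <- filter_config()
  for (i in 1:200) {
    ramp <- cumsum(runif(10, 0, 6))
    v <- c(runif(5, 0, 26), pmin(ramp + runif(1, 10, 22), 33), rep(10, 3))
    tr <- make_trace(v)
    bouts <- segment_bouts(tr, cfg$sprint_threshold_kmh)
    bouts <- bouts[bouts$max_kmh > cfg$sprint_threshold_kmh, ]
    if (nrow(bouts) == 0L) next
    expect_equal(classify_sprint(tr, bouts[1, ], cfg),
                 oracle_classify(tr, bouts[1, ], cfg))
  }
})

test_that("filter configuration rejects inconsistent thresholds", {
  expect_error(filter_config(v_cap_kmh = 20), "config error")
  expect_error(filter_config(corroboration_margin_kmh = 0), "config error")
  expect_error(filter_config(hsr_band_kmh = c(26, 30)), "config error")
})
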