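test_that("paired mean differences handle identity and pure-shift cases", {
  x <- c(3, 7, 11, 2)
  same <- paired_mean_diff(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$d, 0)
  expect_equal(same$magnitude, "unclear")  # zero-width CI touching zero

  shift <- paired_mean_diff(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shift$mean_diff, 1)
  expect_equal(c(shift$diff_lo, shift$diff_hi), c(1, 1))  # SD of diffs is 0
  expect_equal(shift$d, 1)  # s_av = sqrt((1 + 1)/2) = 1
  expect_equal(shift$magnitude, "moderate")

  expect_error(paired_mean_diff(1, 2), "insufficient")
  expect_error(paired_mean_diff(c(1, NA, 2), c(2, 3, NA)), "insufficient")
})

test_that("the paired mean-difference CI matches the paired t interval", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    a <- rnorm(n, 20, 6)
    b <- a + rnorm(n, 2, 3)
    got <- paired_mean_diff(a, b)
    tt <- stats::t.test(b, a, paired = TRUE)
    expect_equal(got$mean_diff, unname(tt$estimate), tolerance = 1e-12)
    expect_equal(c(got$diff_lo, got$diff_hi), as.numeric(tt$conf.int),
                 tolerance = 1e-12)
    # mean of paired differences equals difference of column means
    expect_equal(got$mean_diff, mean(b) - mean(a), tolerance = 1e-12)
    # d standardized by the average condition SD, not the difference SD
    expect_equal(got$d, (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2),
                 tolerance = 1e-12)
  }
})

test_that("magnitude bands reproduce published label examples", {
  expect_equal(classify_effect_size(0.68, c(0.64, 0.73)), "moderate")
  expect_equal(classify_effect_size(0.03, c(-0.02, 0.07)), "unclear")
  expect_equal(classify_effect_size(-0.73, c(-0.78, -0.68)), "moderate")
})

test_that("magnitude classification is total, monotone, and conservative at
           zero", {
  # band edges belong to the larger band
  expect_equal(classify_effect_size(0.19, c(0.1, 0.25)), "trivial")
  expect_equal(classify_effect_size(0.2, c(0.1, 0.3)), "small")
  expect_equal(classify_effect_size(4.5, c(4.1, 4.9)), "extremely large")
  # CI touching zero counts as spanning it
  expect_equal(classify_effect_size(0.4, c(0, 0.8)), "unclear")
  expect_equal(classify_effect_size(-0.4, c(-0.8, 0)), "unclear")
  # monotone in |d| with a fixed non-spanning CI
  bands <- vapply(c(0.1, 0.4, 0.9, 1.5, 3, 5),
                  function(d) classify_effect_size(d, c(0.01, 0.02)),
                  character(1))
  ranks <- match(bands, names(peripeak::MAGNITUDE_THRESHOLDS))
  expect_true(all(diff(ranks) >= 0))
})

test_that("independent mean differences match closed-form pooled-t results", {
  ident <- independent_mean_diff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$magnitude, "unclear")

  # degenerate zero-variance groups: difference is exact
  degen <- independent_mean_diff(rep(29.11, 5), rep(31.64, 5))
  expect_equal(degen$mean_diff, 2.53)

  set.seed(55)
  x <- rnorm(10, 29, 2); y <- rnorm(19, 31, 2)
  got <- independent_mean_diff(x, y)
  # textbook pooled-variance formulas, written out independently
  n1 <- 10; n2 <- 19
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  md <- mean(y) - mean(x)
  half <- qt(0.975, n1 + n2 - 2) * sp * sqrt(1 / n1 + 1 / n2)
  expect_equal(got$mean_diff, md, tolerance = 1e-10)
  expect_equal(got$diff_lo, md - half, tolerance = 1e-10)
  expect_equal(got$diff_hi, md + half, tolerance = 1e-10)
  expect_equal(got$d, md / sp, tolerance = 1e-10)
  # and against base R's equal-variance t interval
  tt <- stats::t.test(y, x, var.equal = TRUE)
  expect_equal(c(got$diff_lo, got$diff_hi), as.numeric(tt$conf.int),
               tolerance = 1e-12)
  # Welch option reproduces base R's default interval
  gw <- independent_mean_diff(x, y, welch = TRUE)
  tw <- stats::t.test(y, x)
  expect_equal(c(gw$diff_lo, gw$diff_hi), as.numeric(tw$conf.int),
               tolerance = 1e-12)

  expect_error(independent_mean_diff(1, c(2, 3)), "insufficient")
})

test_that("consecutive-interval contrasts decompose into paired contrasts", {
  profs <- dplyr::bind_rows(lapply(1:5, function(i) {
    p <- per_second_profile(make_window(rep(20, 201)))
    p$window_id <- paste0("w", i)
    p
  }))
  res <- consecutive_interval_diffs(profs)
  expect_equal(nrow(res), 18L)
  expect_equal(res$pair[1], "10-9")
  expect_equal(res$pair[9], "2-1")
  expect_equal(res$pair[10], "1-2")
  expect_equal(res$pair[18], "9-10")
  expect_true(all(res$mean_diff == 0))
  expect_true(all(res$n == 5L))

  # two hand-built windows: each record equals paired_mean_diff on columns
  set.seed(66)
  w1 <- make_window(c(sort(runif(100, 0, 28)), 30,
                      rev(sort(runif(100, 5, 29)))), peak_kmh = 30)
  w2 <- make_window(c(sort(runif(100, 2, 27)), 31,
                      rev(sort(runif(100, 6, 30)))), peak_kmh = 31)
  profs2 <- dplyr::bind_rows(
    dplyr::mutate(per_second_profile(w1), window_id = "a"),
    dplyr::mutate(per_second_profile(w2), window_id = "b"))
  res2 <- consecutive_interval_diffs(profs2)
  p1 <- per_second_profile(w1); p2 <- per_second_profile(w2)
  manual <- paired_mean_diff(
    c(p1$v_kmh[p1$offset_s == -4], p2$v_kmh[p2$offset_s == -4]),
    c(p1$v_kmh[p1$offset_s == -3], p2$v_kmh[p2$offset_s == -3]))
  row <- res2[res2$pair == "4-3", ]
  expect_equal(row$mean_diff, manual$mean_diff)
  expect_equal(row$d, manual$d)
  expect_equal(c(row$diff_lo, row$diff_hi),
               c(manual$diff_lo, manual$diff_hi))
})

test_that("simulated cohorts rise before the peak and fall after it", {
  cohort <- small_cohort(n = 10)
  rep <- run_pipeline(cohort$traces)
  d <- rep$interval_diffs
  pre <- d$mean_diff[d$phase == "pre"]
  post <- d$mean_diff[d$phase == "post"]
  # the approach to the peak is a net rise, the recovery a net fall
  expect_gt(sum(pre), 0)
  expect_lt(sum(post), 0)
  expect_true(all(tail(pre, 4) > 0))   # final seconds of the approach rise
  expect_true(all(head(post, 4) < 0))  # first seconds after the peak fall
})

test_that("pooled position means are n-weighted", {
  s <- tidyr::crossing(position = peripeak::POSITIONS, offset_s = -1L)
  s$mean_kmh <- 22.5
  s$n <- c(5L, 10L, 2L, 8L, 3L)
  expect_equal(pooled_position_means(s, -1L), 22.5)

  s$mean_kmh <- c(10, 20, 30, 40, 50)
  expect_equal(pooled_position_means(s, -1L),
               sum(s$n * s$mean_kmh) / sum(s$n))
  expect_error(pooled_position_means(s[-1, ], -1L), "missing position")
})
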