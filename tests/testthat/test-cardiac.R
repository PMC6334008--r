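# trace -> heart rate -> Arrhenius -> broken-stick estimation

test_that("beat detection counts a clean and a noisy pulse train exactly", {
  p <- cardiacSimParams(abt_true = 20.05, temp_range = c(20, 20.1),
                        slope_pre = 0, slope_post = 0, hr_at_20C = 60,
                        noise_sd = 0, arrhythmia_prob = 0, seed = 1L)
  tr <- simulatePulseTrace(p, sampling_hz = 50)
  expect_length(detectBeats(tr, 0.5, 0.3), 60)
  # additive noise at 10 percent of the pulse amplitude
  p2 <- cardiacSimParams(abt_true = 20.05, temp_range = c(20, 20.1),
                         slope_pre = 0, slope_post = 0, hr_at_20C = 60,
                         noise_sd = 0.1, arrhythmia_prob = 0, seed = 8L)
  tr2 <- simulatePulseTrace(p2, sampling_hz = 50)
  expect_length(detectBeats(tr2, 0.5, 0.3), 60)
})

test_that("detected beat times match the generator within a sample period", {
  p <- cardiacSimParams(abt_true = 21, temp_range = c(20, 22),
                        hr_at_20C = 40, noise_sd = 0, arrhythmia_prob = 0,
                        ramp_rate = 0.5, seed = 3L)
  tr <- simulatePulseTrace(p, sampling_hz = 25)
  beats <- detectBeats(tr, 0.5, 0.3)
  truth <- tr@metadata$beat_times
  expect_length(beats, length(truth))
  expect_lt(max(abs(beats - truth)), 1 / 25 + 1e-9)
})

test_that("flat or sub-threshold signals give zero beats with a warning", {
  tr <- new("CardiacTrace", time_s = seq(0, 10, 0.1),
            temp_C = rep(20, 101), signal = rep(0, 101),
            window_flag = rep(FALSE, 101))
  expect_warning(b <- detectBeats(tr), "flat")
  expect_length(b, 0)
})

test_that("windowed heart rate recovers a constant rate exactly", {
  p <- cardiacSimParams(abt_true = 20.05, temp_range = c(20, 20.1),
                        slope_pre = 0, slope_post = 0, hr_at_20C = 60,
                        noise_sd = 0, arrhythmia_prob = 0, seed = 1L)
  tr <- simulatePulseTrace(p, sampling_hz = 50)
  s <- heartRateByTemperature(detectBeats(tr, 0.5, 0.3), tr, window_C = 0.5)
  expect_length(s@hr_bpm, 1)
  expect_equal(s@hr_bpm, 60, tolerance = 1e-6)
})

test_that("arrhythmic windows are excluded and tallied", {
  p <- cardiacSimParams(abt_true = 21, temp_range = c(20, 22),
                        hr_at_20C = 40, noise_sd = 0,
                        arrhythmia_prob = 0.4, ramp_rate = 0.5, seed = 9L)
  tr <- simulatePulseTrace(p, sampling_hz = 25)
  s <- heartRateByTemperature(detectBeats(tr, 0.5, 0.3), tr,
                              window_C = 0.25)
  expect_gt(s@diagnostics$n_excluded_arrhythmic, 0)
  # excluded windows are absent, not flagged
  expect_false(any(s@flagged))
})

test_that("windowed estimates track a linearly doubling rate", {
  # rate r(t) = (1 + t/600) Hz over 600 s; beats from the exact inverse of
  # the cumulative rate R(t) = t + t^2/1200
  k <- 1:900
  beats <- 600 * (sqrt(1 + k / 300) - 1)
  beats <- beats[beats <= 600]
  time_s <- seq(0, 600, 0.5)
  tr <- new("CardiacTrace", time_s = time_s,
            temp_C = 20 + time_s / 120, signal = rep(0, length(time_s)),
            window_flag = rep(FALSE, length(time_s)))
  s <- heartRateByTemperature(beats, tr, window_C = 0.5)
  # midpoint truth: r at the window's centre time, in bpm
  mid_t <- (s@temp_C - 20) * 120
  truth <- 60 * (1 + mid_t / 600)
  expect_true(all(abs(s@hr_bpm - truth) / truth < 0.05))
})

test_that("Arrhenius transform is exact arithmetic and order-reversing", {
  s <- new("HeartRateSeries", temp_C = c(20, 28.5), hr_bpm = c(60, 60),
           n_beats = c(NA_real_, NA_real_), flagged = c(FALSE, FALSE))
  a <- arrheniusTransform(s)
  expect_equal(a@x[1], 3.41122, tolerance = 1e-5)
  expect_equal(a@y[1], 4.09434, tolerance = 1e-5)
  expect_equal(a@x[2], 3.31510, tolerance = 1e-5)
  expect_true(all(diff(a@x) < 0))  # x strictly decreasing in temperature
  bad <- new("HeartRateSeries", temp_C = 20, hr_bpm = 1, n_beats = NA_real_,
             flagged = FALSE)
  bad@hr_bpm <- 0  # bypass constructor validity to exercise the error path
  expect_error(arrheniusTransform(bad), "non-positive")
  expect_error(arrheniusTransform(data.frame(temp_C = 20, hr_bpm = 0)),
               "non-positive")
})

test_that("exact two-segment data is recovered with zero residual", {
  df <- makeTwoSegment(x_break = 3.30, slope_pre = -3, slope_post = 15)
  fit <- fitBrokenStick(df)
  expect_equal(xBreak(fit), 3.30, tolerance = 1e-10)
  expect_lt(rssTotal(fit), 1e-20)
  expect_equal(fit@slope_pre, -3, tolerance = 1e-8)
  expect_equal(fit@slope_post, 15, tolerance = 1e-8)
  expect_equal(abt(fit), 1000 / 3.30 - 273.15, tolerance = 1e-8)
  expect_false(fit@no_distinct_break)
})

test_that("selected split matches a brute-force enumeration oracle", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(8:40, 1)
    x <- sort(runif(n, 3.2, 3.45))
    y <- rnorm(n)
    fit <- fitBrokenStick(data.frame(x = x, y = y))
    expect_equal(rssTotal(fit), bruteForceSplitRSS(x, y), tolerance = 1e-9)
  }
})

test_that("a single straight line is flagged as having no distinct break", {
  # exactly collinear data: every split has RSS 0; the tie-break takes the
  # largest pre-breakpoint segment and the fit is flagged
  x <- seq(3.25, 3.40, length.out = 30)
  y <- 10 - 5 * x
  fit <- fitBrokenStick(data.frame(x = x, y = y))
  expect_true(fit@no_distinct_break)
  expect_equal(fit@n_pre, 30L - 4L)
  # with noise, the two-line RSS never exceeds the single-line RSS
  set.seed(2)
  y2 <- y + rnorm(30, 0, 0.01)
  fit2 <- fitBrokenStick(data.frame(x = x, y = y2))
  single_rss <- sum(resid(lm(y2 ~ x))^2)
  expect_equal(fit2@rss_single, single_rss, tolerance = 1e-10)
  expect_lte(fit2@rss_total, single_rss)
})

test_that("fit preconditions are enforced", {
  expect_error(fitBrokenStick(data.frame(x = 1:7 / 2, y = rnorm(7))),
               "at least 8")
  x <- c(3.2, 3.2, 3.25, 3.3, 3.31, 3.32, 3.35, 3.4)
  expect_error(fitBrokenStick(data.frame(x = x, y = rnorm(8))), "distinct")
})

test_that("estimated ABT always lies inside the observed temperature range", {
  set.seed(21)
  for (i in 1:25) {
    p <- cardiacSimParams(abt_true = runif(1, 24, 31),
                          temp_range = c(20, 34), noise_sd = 0.15,
                          arrhythmia_prob = 0, n_points = 30L)
    s <- simulateHeartRateSeries(p)
    fit <- fitBrokenStick(arrheniusTransform(s))
    expect_gte(abt(fit), min(s@temp_C) - 1e-9)
    expect_lte(abt(fit), max(s@temp_C) + 1e-9)
  }
})

test_that("split-midpoint convention stays between the bracketing points", {
  set.seed(31)
  x <- sort(runif(24, 3.2, 3.45))
  y <- rnorm(24)
  fit <- fitBrokenStick(data.frame(x = x, y = y),
                        convention = "split_midpoint")
  xs <- sort(x)
  k <- fit@n_post
  expect_equal(xBreak(fit), (xs[k] + xs[k + 1]) / 2, tolerance = 1e-12)
})

test_that("maximum heart rate reports the peak and its temperature", {
  s <- new("HeartRateSeries", temp_C = c(29, 31, 33),
           hr_bpm = c(60, 75.14, 50), n_beats = rep(NA_real_, 3),
           flagged = rep(FALSE, 3))
  mx <- maxHeartRate(s)
  expect_equal(mx$hr_bpm, 75.14)
  expect_equal(mx$temp_C, 31)
  ties <- new("HeartRateSeries", temp_C = c(25, 26, 27),
              hr_bpm = c(50, 50, 50), n_beats = rep(NA_real_, 3),
              flagged = rep(FALSE, 3))
  expect_equal(maxHeartRate(ties)$temp_C, 25)  # first on ties
  empty <- new("HeartRateSeries", temp_C = 25, hr_bpm = 50,
               n_beats = NA_real_, flagged = TRUE)
  expect_error(maxHeartRate(empty), "retained")
})

test_that("the simulated peak rate sits at or just below the breakpoint", {
  hits <- vapply(1:20, function(i) {
    p <- cardiacSimParams(abt_true = 30, noise_sd = 0.05,
                          arrhythmia_prob = 0, seed = 400L + i)
    s <- simulateHeartRateSeries(p)
    maxHeartRate(s)$temp_C
  }, numeric(1))
  expect_true(all(hits <= 30 + 1))
  expect_true(all(hits >= 30 - 2.5))
})

test_that("cardiac CSV round-trips through both layouts", {
  p <- cardiacSimParams(abt_true = 21, temp_range = c(20, 22),
                        noise_sd = 0, arrhythmia_prob = 0,
                        ramp_rate = 0.5, seed = 2L)
  tr <- simulatePulseTrace(p, sampling_hz = 20)
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tr), f, row.names = FALSE)
  back <- readCardiacCSV(f)
  expect_s4_class(back, "CardiacTrace")
  expect_equal(back@signal, tr@signal)
  s <- simulateHeartRateSeries(cardiacSimParams(seed = 2L))
  f2 <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(s), f2, row.names = FALSE)
  back2 <- readCardiacCSV(f2)
  expect_s4_class(back2, "HeartRateSeries")
  expect_equal(back2@hr_bpm, s@hr_bpm)
  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), f3, row.names = FALSE)
  expect_error(readCardiacCSV(f3), "unrecognized")
  unlink(c(f, f2, f3))
})
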