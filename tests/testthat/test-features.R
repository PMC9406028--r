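test_that("resultant acceleration is the Euclidean norm of the axes", {
  expect_equal(resultant_acceleration(3, 4, 0), 5)
  expect_equal(resultant_acceleration(0, 0, 1), 1)
  expect_equal(resultant_acceleration(0.6, 0.8, 1.0), sqrt(2))
  expect_error(resultant_acceleration(NA, 0, 1), "non-finite")
  expect_error(resultant_acceleration(Inf, 0, 1), "non-finite")
})

test_that("epoch statistics use the population SD and flag empty epochs", {
  e <- epoch_stats(rep(1, 100))
  expect_equal(e$mu, 1)
  expect_equal(e$sigma, 0)
  e <- epoch_stats(c(1, 3))
  expect_equal(e$mu, 2)
  expect_equal(e$sigma, 1)  # population SD, not the sample SD sqrt(2)
  e <- epoch_stats(rep(c(0.9, 1.1), 50))
  expect_equal(e$mu, 1)
  expect_equal(e$sigma, 0.1)
  e <- epoch_stats(numeric(0))
  expect_true(is.na(e$mu) && is.na(e$sigma))
  expect_equal(e$n_samples, 0L)
})

test_that("minute AI sums present epoch SDs and tracks coverage", {
  expect_equal(as.numeric(minute_activity_index(rep(0, 12))), 0)
  expect_equal(as.numeric(minute_activity_index(rep(0.05, 12))), 0.6)
  ai <- minute_activity_index(c(rep(0.1, 6), rep(NA, 6)))
  expect_equal(as.numeric(ai), 0.6)
  expect_equal(attr(ai, "coverage"), 0.5)
  expect_true(is.na(minute_activity_index(rep(NA_real_, 12))))
  expect_error(minute_activity_index(rep(0, 13)), "12")
})

test_that("hourly PA sums over non-missing minutes", {
  expect_equal(hourly_pa_sum(rep(0, 60)), 0)
  expect_equal(hourly_pa_sum(rep(0.6, 60)), 36)
  expect_equal(hourly_pa_sum(c(rep(1, 30), rep(NA, 30))), 30)
  expect_true(is.na(hourly_pa_sum(rep(NA_real_, 60))))
})

test_that("regularity index is the day-pair Pearson correlation", {
  pat <- c(rep(0, 6), sin(1:18))
  expect_equal(regularity_index(pat, pat), 1)
  expect_equal(regularity_index(pat, mean(pat) - (pat - mean(pat))), -1)
  expect_equal(regularity_index(1:24, 24:1), -1)
  expect_true(is.na(regularity_index(rep(2, 24), pat)))  # zero variance
})

test_that("QoA scales the daily AI total by (1 + RI)", {
  ai <- rep(0.5, 1440)
  expect_equal(daily_qoa(ai, 0), sum(ai))
  expect_equal(daily_qoa(c(rep(10, 10), rep(0, 1430)), 1), 200)
  expect_equal(daily_qoa(ai, -1), 0)
  expect_equal(daily_qoa(ai, NA), sum(ai))  # undefined RI -> neutral 0
  expect_error(daily_qoa(rep(0, 1441), 0), "1440")
})

test_that("wear validity implements the 16-hour cumulative coverage rule", {
  day0 <- as.POSIXct("2016-04-07", tz = "UTC")
  full <- data.frame(timestamp = day0 + seq(0, 86395, by = 5))
  v <- wear_validity(full)
  expect_true(v$wear_valid)
  expect_equal(v$wear_seconds, 86400)
  ten <- data.frame(timestamp = day0 + seq(0, 10 * 3600 - 5, by = 5))
  v <- wear_validity(ten)
  expect_false(v$wear_valid)
  expect_equal(v$wear_seconds, 36000)
  # 16 h in two 8-h blocks separated by an 8-h gap: cumulative rule accepts
  two <- data.frame(timestamp = day0 + c(seq(0, 8 * 3600 - 5, by = 5),
                                         seq(16 * 3600, 86395, by = 5)))
  v <- wear_validity(two)
  expect_true(v$wear_valid)
  expect_equal(v$wear_seconds, 57600)
  # with a finite gap limit the same day is rejected
  expect_false(wear_validity(two, max_gap_hours = 4)$wear_valid)
  expect_error(wear_validity(data.frame(
    timestamp = day0 + c(0, 90000))), "calendar day")
})

test_that("pipeline minute AI equals the brute-force recomputation", {
  day0 <- as.POSIXct("2016-04-07", tz = "UTC")
  set.seed(101)
  for (case in 1:4) {
    minutes <- sort(sample(0:119, 40))  # a sparse 2-hour stream
    n <- length(minutes) * 12 * 5
    tt <- as.numeric(day0) +
      rep(minutes * 60, each = 60) + rep(seq(0, 59, length.out = 60),
                                         length(minutes))
    stream <- data.frame(
      timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
      ax = rnorm(n, 0, 0.1), ay = rnorm(n, 0, 0.1),
      az = 1 + rnorm(n, 0, 0.1)
    )
    got <- attr(extract_daily_features(stream, "P"), "minute_ai")[1, ]
    want <- brute_minute_ai(stream)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("epoch SD is invariant to a constant offset within the epoch", {
  set.seed(7)
  for (i in 1:100) {
    a <- runif(sample(2:100, 1), 0.5, 1.5)
    off <- runif(1, -2, 2)
    expect_equal(epoch_stats(a + off)$sigma, epoch_stats(a)$sigma,
                 tolerance = 1e-9)
  }
})

test_that("scaling a day scales AI and QoA by c and leaves RI unchanged", {
  day0 <- as.POSIXct("2016-04-07", tz = "UTC")
  amp <- 0.02 * (1 + abs(sin(2 * pi * (0:1439) / 1440)))
  s1 <- deterministic_stream(day0, 0:1439, amp)
  s2 <- deterministic_stream(day0 + 86400, 0:1439, amp * 3)
  f <- extract_daily_features(rbind(s1, s2), "P")
  expect_equal(f$ai_sum[2], 3 * f$ai_sum[1], tolerance = 1e-9)
  # identical shape, scaled: RI = 1, and QoA scales with the AI total
  expect_equal(f$ri[2], 1, tolerance = 1e-9)
  expect_equal(f$qoa[2] / f$qoa[1], 3 * (1 + f$ri[2]) / (1 + 0),
               tolerance = 1e-9)
})

test_that("RI stays in [-1, 1] and QoA is nonnegative on random days", {
  cfg <- cohort_config(n_patients = 5, days_per_patient = 20,
                       nonwear_rate = 1, seed = 17)
  co <- simulate_cohort(cfg, output = "daily")
  ri <- co$daily$ri[!is.na(co$daily$ri)]
  expect_true(all(ri >= -1 & ri <= 1))
  expect_true(all(co$daily$qoa >= 0))
  expect_true(all(co$daily$ai_sum >= 0))
})

test_that("daily extraction composes the feature chain per calendar day", {
  day0 <- as.POSIXct("2016-04-07", tz = "UTC")
  # gravity-only day: zero AI everywhere, zero QoA
  still <- data.frame(timestamp = day0 + seq(0, 86395, by = 5),
                      ax = 0, ay = 0, az = 1)
  f <- extract_daily_features(still, "P")
  expect_equal(f$ai_sum, 0)
  expect_equal(f$qoa, 0)
  expect_true(f$wear_valid)

  # two identical active days: RI of day 2 is exactly 1
  amp <- 0.05 * (1 + pmax(0, sin(2 * pi * (0:1439) / 1440)))
  s1 <- deterministic_stream(day0, 0:1439, amp)
  s2 <- deterministic_stream(day0 + 86400, 0:1439, amp)
  f <- extract_daily_features(rbind(s1, s2), "P")
  expect_true(is.na(f$ri[1]))  # first observed day has no d-1
  expect_equal(f$ri[2], 1, tolerance = 1e-9)
  expect_equal(f$ai_sum[1], sum(12 * amp), tolerance = 1e-9)

  # a day following a non-valid day gets an undefined RI
  short <- deterministic_stream(day0 + 86400, 0:599, amp[1:600])
  f <- extract_daily_features(rbind(s1[s1$timestamp < day0 + 36000, ],
                                    short,
                                    deterministic_stream(day0 + 2 * 86400,
                                                         0:1439, amp)),
                              "P")
  expect_false(f$wear_valid[1])
  expect_false(f$wear_valid[2])
  expect_true(is.na(f$ri[3]))

  # out-of-order timestamps are rejected
  bad <- still[c(2, 1, 3), ]
  expect_error(extract_daily_features(bad, "P"), "non-decreasing")
})
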