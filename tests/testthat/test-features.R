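# Per-minute activity / jerk / entropy features, average day, window means.

rate <- 50
minute_n <- 60 * rate

test_that("activity is the mean absolute magnitude, with closed-form
           checks", {
  m0 <- bench_magnitude(rep(0, minute_n))
  expect_equal(minute_features(m0)$activity_mg, 0)

  sq <- bench_magnitude(rep(c(100, -100), minute_n / 2))
  expect_equal(minute_features(sq)$activity_mg, 100)

  # folded-normal: mean |N(0, s)| = s * sqrt(2/pi)
  set.seed(30)
  g <- bench_magnitude(rnorm(minute_n, 0, 80))
  expect_equal(minute_features(g)$activity_mg, 80 * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("activity of a fully simulated active minute approximates the
           folded-normal expectation of the planted intensity", {
  cfg <- tiny_config(seed = 61, calib_offset_sd_mg = 0, calib_gain_sd = 0)
  tb <- simulate_truths(cfg)
  tr <- tb$truths[[1]]
  tr$lambda_min[] <- 80
  tr$nonwear_intervals <- matrix(numeric(0), ncol = 2)
  rec <- simulate_recording(tr, cfg, seed = 5)
  r50 <- resample_to_50hz(rec)
  mag <- bandpass_magnitude(r50)
  mf <- minute_features(mag, features = "activity")
  mid <- mf$activity_mg[!is.na(mf$activity_mg)]
  expect_lt(abs(mean(mid) - 80 * sqrt(2 / pi)) / (80 * sqrt(2 / pi)), 0.15)
})

test_that("jerk recovers constant slopes exactly and sinusoid slopes via
           a direct numerical oracle", {
  expect_equal(minute_features(bench_magnitude(rep(5, minute_n)))$jerk_mg_s,
               0)

  s <- 40  # mg/s ramp
  ramp <- bench_magnitude(s * (0:(minute_n - 1)) / rate)
  expect_equal(minute_features(ramp)$jerk_mg_s, s, tolerance = 1e-9)

  # analytic signal: the estimator applied by brute force is the oracle
  tt <- (0:(minute_n - 1)) / rate
  sig <- 100 * sin(2 * pi * 1 * tt)
  i <- 3:(minute_n - 2)
  d_ref <- (2 * sig[i + 2] + sig[i + 1] - sig[i - 1] - 2 * sig[i - 2]) /
    (10 / rate)
  expect_equal(minute_features(bench_magnitude(sig))$jerk_mg_s,
               mean(abs(d_ref)), tolerance = 1e-9)
  # and the 5-point regression gain at 1 Hz keeps it near 2A*omega/pi
  expect_equal(mean(abs(d_ref)), (2 / pi) * 2 * pi * 1 * 100,
               tolerance = 0.05)
})

test_that("entropy hits its closed-form anchors and matches an
           independent histogram oracle", {
  expect_equal(minute_features(bench_magnitude(rep(42, minute_n)))$entropy_bits,
               0)

  # equal occupation of all 64 bins needs a sample count divisible by
  # 64; 2944 samples still exceed the half-minute validity threshold
  centers <- rep(seq(-500 + 15.625 / 2, by = 15.625, length.out = 64),
                 times = 46)
  expect_equal(minute_features(bench_magnitude(centers))$entropy_bits[1], 6)

  set.seed(31)
  x <- rnorm(minute_n, 0, 50)
  got <- minute_features(bench_magnitude(x))$entropy_bits
  counts <- table(cut(pmin(pmax(x, -500), 500 - 1e-9),
                      breaks = seq(-500, 500, by = 15.625),
                      right = FALSE))
  p <- counts[counts > 0] / sum(counts)
  expect_equal(got, -sum(p * log2(p)), tolerance = 1e-12)
  expect_gte(got, 0); expect_lte(got, 6)
})

test_that("minutes with under half their samples, or non-wear minutes,
           are missing", {
  x <- c(rnorm(1400, 0, 30), rep(NA, minute_n - 1400), rnorm(minute_n, 0, 30))
  mf <- minute_features(bench_magnitude(x))
  expect_true(is.na(mf$activity_mg[1]))
  expect_equal(mf$n_samples[1], 1400L)
  expect_false(is.na(mf$activity_mg[2]))

  mask <- data.frame(date = as.Date("2024-01-08"), seg_of_day = 0L,
                     sd_mg = 20, n_samples = 90000L, frac_present = 1,
                     worn = FALSE, flagged = FALSE)
  class(mask) <- c("wear_mask", "data.frame")
  attr(mask, "segment_min") <- 30
  mf2 <- minute_features(bench_magnitude(rnorm(minute_n, 0, 30)), mask)
  expect_true(all(is.na(mf2$activity_mg)))
  expect_false(mf2$worn[1])
})

test_that("scaling the magnitude scales activity and jerk linearly and
           keeps entropy within bounds", {
  set.seed(32)
  x <- rnorm(minute_n, 0, 40)
  f1 <- minute_features(bench_magnitude(x))
  f2 <- minute_features(bench_magnitude(2.5 * x))
  expect_equal(f2$activity_mg, 2.5 * f1$activity_mg, tolerance = 1e-12)
  expect_equal(f2$jerk_mg_s, 2.5 * f1$jerk_mg_s, tolerance = 1e-12)
  expect_true(f2$entropy_bits >= 0 && f2$entropy_bits <= 6)
})

test_that("average day pools minutes of day across included days only", {
  mk_minutes <- function(dates, val) {
    n <- 1440 * length(dates)
    out <- data.frame(
      date = rep(as.Date(dates), each = 1440),
      minute_of_day = rep(0:1439, length(dates)),
      activity_mg = val, jerk_mg_s = val / 10, entropy_bits = 3,
      n_samples = 3000L, worn = TRUE)
    class(out) <- c("minute_features", "data.frame")
    out
  }
  mk_days <- function(dates, included) {
    d <- data.frame(date = as.Date(dates), minutes_worn = 1440,
                    minutes_covered = 1440, included = included,
                    exclusion_reason = ifelse(included, "none",
                                              "short_wear"))
    class(d) <- c("day_record", "data.frame")
    d
  }
  one <- average_day(mk_minutes("2024-01-08", 7),
                     mk_days("2024-01-08", TRUE))
  expect_equal(nrow(one), 1440)
  expect_true(all(one$activity_mg == 7))
  expect_true(all(one$n_days == 1))

  two_vals <- c(rep(4, 1440), rep(10, 1440))
  two <- average_day(mk_minutes(c("2024-01-08", "2024-01-09"), two_vals),
                     mk_days(c("2024-01-08", "2024-01-09"), c(TRUE, TRUE)))
  expect_true(all(two$activity_mg == 7))

  # the excluded day must not contribute
  skip1 <- average_day(mk_minutes(c("2024-01-08", "2024-01-09"), two_vals),
                       mk_days(c("2024-01-08", "2024-01-09"),
                               c(FALSE, TRUE)))
  expect_true(all(skip1$activity_mg == 10))

  expect_error(average_day(mk_minutes("2024-01-08", 1),
                           mk_days("2024-01-08", FALSE)),
               "no included days")

  # weighted-mean conservation against direct summation
  set.seed(33)
  vals <- rnorm(2 * 1440, 20, 5)
  mf <- mk_minutes(c("2024-01-08", "2024-01-09"), vals)
  mf$activity_mg[sample(2880, 200)] <- NA
  prof <- average_day(mf, mk_days(c("2024-01-08", "2024-01-09"),
                                  c(TRUE, TRUE)))
  lhs <- sum(prof$activity_mg * prof$n_days, na.rm = TRUE)
  expect_equal(lhs, sum(mf$activity_mg, na.rm = TRUE))
})

test_that("per-minute activity tracks the true intensity profile across
           a full simulated day", {
  cfg <- tiny_config(seed = 71,
                     nonwear = list(prob_per_day = 0, dur_mean_min = 60,
                                    dur_sd_min = 0,
                                    dur_range_min = c(60, 60),
                                    start_range_min = c(600, 601)))
  tb <- simulate_truths(cfg)
  tr <- tb$truths[[1]]
  res <- process_participant(simulate_participant_recordings(tr, cfg),
                             params = list(features = "activity"))
  expect_equal(res$status, "ok")
  prof <- res$profile
  lam <- tr$lambda_min
  sel <- !is.na(prof$activity_mg) & lam > 10
  expect_gt(sum(sel), 600)
  expect_gt(stats::cor(prof$activity_mg[sel], lam[sel]), 0.95)
})

test_that("window means follow the minute-of-day windows", {
  prof <- data.frame(minute_of_day = 0:1439, activity_mg = 5,
                     jerk_mg_s = 5, entropy_bits = 5, n_days = 1L)
  class(prof) <- c("avg_day_profile", "data.frame")
  for (w in c("night", "daytime", "morning", "day24"))
    expect_equal(unname(segment_mean(prof, w)["activity_mg"]), 5)

  ind <- prof
  ind$activity_mg <- as.numeric(ind$minute_of_day >= 360 &
                                  ind$minute_of_day < 720)
  expect_equal(unname(segment_mean(ind, "morning")["activity_mg"]), 1)
  expect_equal(unname(segment_mean(ind, "night")["activity_mg"]), 0)
  expect_equal(unname(segment_mean(ind, "daytime")["activity_mg"]), 1 / 3)

  set.seed(34)
  rnd <- prof
  rnd$activity_mg <- rnorm(1440)
  expect_equal(unname(segment_mean(rnd, "night")["activity_mg"]),
               mean(rnd$activity_mg[1:360]))
  expect_equal(unname(segment_mean(rnd, "daytime")["activity_mg"]),
               mean(rnd$activity_mg[361:1440]))
})
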