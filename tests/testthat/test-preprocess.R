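# Autocalibration, resampling, band-pass filtering, changeover merging.

test_that("still-window detection returns exactly the quiet poses", {
  rec <- gravity_recording(duration_s = 120, g_vec = c(0, 0.6, 0.8),
                           noise_sd_g = 0.002)
  sw <- find_still_windows(rec)
  expect_equal(nrow(sw), 12)
  expect_equal(colMeans(sw), c(0, 0.6, 0.8), tolerance = 5e-3)

  # sustained high activity is never "still"
  set.seed(4)
  noisy <- gravity_recording(duration_s = 120, noise_sd_g = 0.05)
  expect_equal(nrow(find_still_windows(noisy)), 0)

  # scripted poses (22 s still + 2 s move): every still phase contains
  # at least one aligned 10 s window, and only still windows come back
  rec2 <- posed_recording(n_poses = 30)
  sw2 <- find_still_windows(rec2)
  expect_gte(nrow(sw2), 29)
  r <- sqrt(rowSums(sw2^2))
  expect_lt(max(abs(r - 1)), 0.02)
})

test_that("autocalibration is an identity fixed point on calibrated data
           and recovers planted gain/offset", {
  rec <- posed_recording(n_poses = 120, noise_sd_g = 0.0015)
  cal <- autocalibrate(rec, min_hours = 0.1)
  expect_true(cal$success)
  expect_lt(max(abs(cal$gain - 1)), 1e-3)
  expect_lt(max(abs(cal$offset_mg)), 1)
  expect_lt(cal$post_error_mg, cal$pre_error_mg + 1e-9)

  gain <- c(1.02, 0.98, 1.01); off <- c(20, -15, 10)
  rec2 <- posed_recording(n_poses = 150, gain = gain, offset_mg = off,
                          noise_sd_g = 0.0015, seed = 8)
  cal2 <- autocalibrate(rec2, min_hours = 0.1)
  expect_true(cal2$success)
  expect_lt(max(abs(cal2$gain - gain)), 0.005)
  expect_lt(max(abs(cal2$offset_mg - off)), 2)

  # round trip: corrected still windows sit on the unit sphere
  corr <- apply_calibration(rec2, cal2)
  swc <- find_still_windows(corr)
  expect_lt(mean(abs(sqrt(rowSums(swc^2)) - 1)) * 1000, 5)
})

test_that("degenerate geometry (single orientation) fails calibration and
           the failure is refused downstream", {
  rec <- gravity_recording(duration_s = 600, noise_sd_g = 0.002)
  cal <- autocalibrate(rec, min_hours = 0.1)
  expect_false(cal$success)
  expect_equal(cal$gain, rep(1, 3))
  expect_error(apply_calibration(rec, cal), "calibration failure")
})

test_that("apply_calibration inverts the sensor model arithmetically", {
  rec <- gravity_recording(duration_s = 30)
  ident <- structure(list(gain = rep(1, 3), offset_mg = rep(0, 3),
                          pre_error_mg = 0, post_error_mg = 0,
                          n_still = 10, success = TRUE, message = "ok"),
                     class = "calibration_model")
  expect_equal(apply_calibration(rec, ident)$xyz, rec$xyz)
  shift <- ident; shift$offset_mg <- c(10, 0, 0)
  out <- apply_calibration(rec, shift)
  expect_equal(out$xyz[, 1], rec$xyz[, 1] - 0.010)
})

test_that("50 Hz resampling reproduces uniform input, exact cubics, and
           jittered sinusoids", {
  t <- seq(0, 20, by = 1 / 50)
  xyz <- cbind(sin(t), cos(t), t / 20)
  rec <- raw_recording("A", "D1", T0, t, xyz)
  out <- resample_to_50hz(rec)
  expect_equal(out$t, t, tolerance = 1e-12)
  expect_lt(max(abs(out$xyz - xyz)), 1e-9)

  set.seed(6)
  t30 <- sort(seq(0, 20, by = 1 / 30) * (1 + rnorm(601, 0, 1e-4)))
  cub <- cbind(1 + 2 * t30 - 3 * t30^2 + 0.5 * t30^3, t30, t30^2)
  r30 <- raw_recording("A", "D1", T0, t30, cub)
  o30 <- resample_to_50hz(r30)
  ref <- 1 + 2 * o30$t - 3 * o30$t^2 + 0.5 * o30$t^3
  expect_lt(max(abs(o30$xyz[, 1] - ref)), 1e-9)

  sine <- raw_recording("A", "D1", T0, t30,
                        cbind(0.1 * sin(2 * pi * 2 * t30), 0, 1))
  os <- resample_to_50hz(sine)
  rmse <- sqrt(mean((os$xyz[, 1] - 0.1 * sin(2 * pi * 2 * os$t))^2))
  expect_lt(rmse, 0.001)  # < 1% of the 0.1 g amplitude

  expect_error(resample_to_50hz(raw_recording("A", "D", T0, c(0, 1, 2),
                                              matrix(1, 3, 3))),
               "at least 4")
})

test_that("band-pass rejects DC and drift but passes body-movement
           frequencies", {
  t <- seq(0, 120, by = 1 / 50)
  const <- raw_recording("A", "D1", T0, t, cbind(0, 0, rep(1, length(t))))
  attr(const, "rate_hz") <- 50
  m0 <- bandpass_magnitude(const)
  expect_lt(max(abs(m0$m_mg), na.rm = TRUE), 1)

  mk <- function(f, amp_mg) {
    raw_recording("A", "D1", T0, t, cbind(0, 0, 1 + amp_mg / 1000 *
                                            sin(2 * pi * f * t)))
  }
  r1 <- mk(1, 100); attr(r1, "rate_hz") <- 50
  m1 <- bandpass_magnitude(r1)
  mid <- m1$m_mg[2000:4000]
  expect_gte(max(abs(mid)), 90)

  t2 <- seq(0, 600, by = 1 / 50)
  slow <- raw_recording("A", "D1", T0, t2,
                        cbind(0, 0, 1 + 0.1 * sin(2 * pi * 0.01 * t2)))
  attr(slow, "rate_hz") <- 50
  ms <- bandpass_magnitude(slow)
  expect_lt(max(abs(ms$m_mg[10000:20000])), 5)
})

test_that("band-pass is linear in the input scale", {
  set.seed(7)
  t <- seq(0, 60, by = 1 / 50)
  base <- 0.05 * sin(2 * pi * 1.3 * t) + 0.02 * sin(2 * pi * 4 * t)
  mk <- function(a) {
    r <- raw_recording("A", "D1", T0, t, cbind(0, 0, 1 + a * base))
    attr(r, "rate_hz") <- 50
    bandpass_magnitude(r)$m_mg
  }
  m1 <- mk(1); m3 <- mk(3)
  ok <- !is.na(m1)
  expect_equal(m3[ok], 3 * m1[ok], tolerance = 1e-6)
})

test_that("changeover merging keeps both parts on one clock, refuses bad
           pairs, and marks the gap missing", {
  t <- seq(0, 600, by = 1 / 30)
  xyz <- cbind(0, 0, rep(1, length(t)))
  a <- raw_recording("P1", "D1", T0, t, xyz)
  b <- raw_recording("P1", "D2", T0 + 660, t, xyz)   # 60 s gap
  m <- merge_changeover(a, b)
  expect_equal(recording_duration(m), 600 + 60 + 600)
  expect_equal(length(m$t), 2 * length(t))

  expect_error(merge_changeover(a, raw_recording("P2", "D2", T0 + 660, t,
                                                 xyz)),
               "different participants")
  expect_error(merge_changeover(a, raw_recording("P1", "D2", T0 + 300, t,
                                                 xyz)),
               "overlap")
  expect_error(merge_changeover(a, raw_recording("P1", "D2", T0 + 5000, t,
                                                 xyz)),
               "gap")

  # the gap must come out as missing samples, not interpolated values
  r50 <- resample_to_50hz(m)
  gap <- r50$t > 600.5 & r50$t < 659.5
  expect_true(all(is.na(r50$xyz[gap, 1])))
})

test_that("autocalibrating an already-corrected recording is idempotent", {
  rec <- posed_recording(n_poses = 150, gain = c(1.02, 0.98, 1.01),
                         offset_mg = c(20, -15, 10), noise_sd_g = 0.0015,
                         seed = 10)
  cal <- autocalibrate(rec, min_hours = 0.1)
  corr <- apply_calibration(rec, cal)
  cal2 <- autocalibrate(corr, min_hours = 0.1)
  expect_lt(max(abs(cal2$gain - 1)), 1e-3)
  expect_lt(max(abs(cal2$offset_mg)), 1)
})

test_that("resampling preserves the mean of a band-limited signal", {
  set.seed(15)
  t30 <- seq(0, 60, by = 1 / 30)
  sig <- 1 + 0.05 * sin(2 * pi * 1.1 * t30) + 0.02 * cos(2 * pi * 3 * t30)
  rec <- raw_recording("A", "D1", T0, t30, cbind(sig, 0, 0))
  out <- resample_to_50hz(rec)
  expect_equal(mean(out$xyz[, 1]), mean(sig), tolerance = 1e-3)
})
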