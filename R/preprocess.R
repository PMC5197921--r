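# Pre-processing: autocalibration to local gravity, changeover merging,
# cubic-spline resampling to a uniform 50 Hz grid, and Butterworth
# band-pass gravity removal of the acceleration magnitude.

#' Locate still windows in a raw recording
#'
#' Splits the recording into consecutive non-overlapping windows
#' (default 10 s) and returns the per-axis mean of every window whose
#' per-axis standard deviation is below the stillness threshold
#' (default 13 mg on each axis). Still windows sample the local gravity
#' vector at different wrist orientations and are the input to
#' [autocalibrate()].
#'
#' @param rec a [raw_recording()].
#' @param window_s window length, seconds.
#' @param sd_threshold_mg per-axis stillness threshold, mg.
#' @return Matrix (one row per still window, columns x/y/z mean in g)
#'   with attribute `window_mid_s` (window mid-times, seconds).
#' @export
find_still_windows <- function(rec, window_s = 10, sd_threshold_mg = 13) {
  stopifnot(inherits(rec, "raw_recording"))
  if (recording_duration(rec) < window_s)
    stopf("recording shorter than one still window (%g s)", window_s)
  idx <- as.integer(floor((rec$t - rec$t[1]) / window_s))
  nw <- idx[length(idx)] + 1L
  mm <- cpp_bin_moments_xyz(rec$xyz, idx, nw)
  cnt <- mm[, 1]
  means <- mm[, c(2, 4, 6), drop = FALSE] / cnt
  vars <- pmax((mm[, c(3, 5, 7), drop = FALSE] -
                  mm[, c(2, 4, 6), drop = FALSE]^2 / cnt) /
                 pmax(cnt - 1, 1), 0)
  ok <- cnt >= 2 &
    vars[, 1] < (sd_threshold_mg / 1000)^2 &
    vars[, 2] < (sd_threshold_mg / 1000)^2 &
    vars[, 3] < (sd_threshold_mg / 1000)^2
  ok[is.na(ok)] <- FALSE
  out <- means[ok, , drop = FALSE]
  attr(out, "window_mid_s") <- rec$t[1] + (which(ok) - 0.5) * window_s
  out
}

#' Sphere-fit autocalibration of per-axis gain and offset
#'
#' Estimates the device's per-axis gain and offset from still windows:
#' each still-window mean should lie on the unit-gravity sphere, so the
#' corrected means are iteratively regressed (per axis, ordinary least
#' squares) onto their projections on the unit sphere until the
#' parameters change by less than `tol` (relative) or `max_iter` is
#' reached. The fit is only attempted when every axis's still-window
#' means reach both below -`spread_mg` and above +`spread_mg`
#' (sphere-sampling requirement); otherwise, and when the residual error
#' stays at or above 10 mg, the model is flagged unsuccessful and left
#' at identity.
#'
#' @param rec a [raw_recording()] spanning at least `min_hours` hours.
#' @param window_s,sd_threshold_mg passed to [find_still_windows()].
#' @param spread_mg sphere-sampling requirement per axis, mg.
#' @param tol,max_iter iteration controls.
#' @param min_hours minimum recording span required for calibration.
#' @return A `calibration_model`: gain (3), offset_mg (3), pre_error_mg,
#'   post_error_mg, n_still, success, message.
#' @export
autocalibrate <- function(rec, window_s = 10, sd_threshold_mg = 13,
                          spread_mg = 300, tol = 1e-9, max_iter = 1000,
                          min_hours = 24) {
  stopifnot(inherits(rec, "raw_recording"))
  if (recording_duration(rec) < min_hours * 3600)
    stopf("autocalibration requires a recording of at least %g h", min_hours)
  Y <- find_still_windows(rec, window_s, sd_threshold_mg)
  fail <- function(msg, n, pre) {
    structure(list(gain = rep(1, 3), offset_mg = rep(0, 3),
                   pre_error_mg = pre, post_error_mg = NA_real_,
                   n_still = n, success = FALSE, message = msg),
              class = "calibration_model")
  }
  if (nrow(Y) < 10)
    return(fail("too few still windows", nrow(Y), NA_real_))
  pre_err <- mean(abs(sqrt(rowSums(Y^2)) - 1)) * 1000
  spread_ok <- all(apply(Y, 2, min) <= -spread_mg / 1000) &&
    all(apply(Y, 2, max) >= spread_mg / 1000)
  if (!spread_ok)
    return(fail("still orientations do not cover the sphere", nrow(Y),
                pre_err))

  intc <- rep(0, 3)  # additive term, g
  slope <- rep(1, 3) # multiplicative term
  for (it in seq_len(max_iter)) {
    C <- sweep(sweep(Y, 2, slope, `*`), 2, intc, `+`)
    r <- sqrt(rowSums(C^2))
    Tg <- C / r
    old <- c(intc, slope)
    for (j in 1:3) {
      cf <- stats::lm.fit(cbind(1, Y[, j]), Tg[, j])$coefficients
      intc[j] <- cf[1]; slope[j] <- cf[2]
    }
    if (max(abs(c(intc, slope) - old)) < tol * max(1, max(abs(old))))
      break
  }
  C <- sweep(sweep(Y, 2, slope, `*`), 2, intc, `+`)
  post_err <- mean(abs(sqrt(rowSums(C^2)) - 1)) * 1000
  # corrected = slope*measured + intc == (measured - offset)/gain
  gain <- 1 / slope
  offset_mg <- -intc / slope * 1000
  structure(list(gain = gain, offset_mg = offset_mg,
                 pre_error_mg = pre_err, post_error_mg = post_err,
                 n_still = nrow(Y), success = post_err < 10,
                 message = if (post_err < 10) "ok" else
                   "residual calibration error >= 10 mg"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> success: %s (%s)\n",
              x$success, x$message))
  cat(sprintf("  gain   %s\n  offset %s mg\n",
              paste(sprintf("%.4f", x$gain), collapse = " "),
              paste(sprintf("%+.2f", x$offset_mg), collapse = " ")))
  cat(sprintf("  error %s -> %s mg over %d still windows\n",
              format(x$pre_error_mg, digits = 3),
              format(x$post_error_mg, digits = 3), x$n_still))
  invisible(x)
}

#' Apply a calibration model to a raw recording
#'
#' Inverts the sensor model `measured = gain * a + offset`:
#' per axis, `corrected = (measured - offset) / gain`.
#'
#' @param rec a [raw_recording()].
#' @param model a successful `calibration_model` from [autocalibrate()].
#' @return The corrected [raw_recording()].
#' @export
apply_calibration <- function(rec, model) {
  stopifnot(inherits(rec, "raw_recording"),
            inherits(model, "calibration_model"))
  if (!isTRUE(model$success))
    stopf("calibration failure: refusing to apply an unsuccessful model (%s)",
          model$message)
  xyz <- cbind((rec$xyz[, 1] - model$offset_mg[1] / 1000) / model$gain[1],
               (rec$xyz[, 2] - model$offset_mg[2] / 1000) / model$gain[2],
               (rec$xyz[, 3] - model$offset_mg[3] / 1000) / model$gain[3])
  out <- rec  # already-validated fields; only xyz changes
  out$xyz <- xyz
  out
}

#' Merge two device recordings across a changeover
#'
#' Places both recordings of one participant on the clock of the first
#' and concatenates them. The changeover gap is left as missing samples
#' (no zero-filling); [resample_to_50hz()] later refuses to interpolate
#' across it, and the calendar day containing the changeover is handled
#' as a single day downstream.
#'
#' @param rec_a,rec_b [raw_recording()]s of the same participant, with
#'   `rec_a` ending before `rec_b` starts.
#' @param max_gap_s refuse to merge gaps at or above this (default 1 h);
#'   the changeover itself typically lasts under a minute.
#' @return Merged [raw_recording()] (device id `"A+B"` style).
#' @export
merge_changeover <- function(rec_a, rec_b, max_gap_s = 3600) {
  stopifnot(inherits(rec_a, "raw_recording"), inherits(rec_b, "raw_recording"))
  if (rec_a$participant_id != rec_b$participant_id)
    stopf("cannot merge recordings of different participants (%s vs %s)",
          rec_a$participant_id, rec_b$participant_id)
  shift <- as.numeric(difftime(rec_b$start_time, rec_a$start_time,
                               units = "secs"))
  tb <- rec_b$t + shift
  gap <- tb[1] - rec_a$t[length(rec_a$t)]
  if (gap <= 0)
    stopf("recordings overlap: device %s starts before device %s ends",
          rec_b$device_id, rec_a$device_id)
  if (gap >= max_gap_s)
    stopf("changeover gap of %.1f min exceeds %.1f min; analyse the days separately",
          gap / 60, max_gap_s / 60)
  raw_recording(rec_a$participant_id,
                paste(rec_a$device_id, rec_b$device_id, sep = "+"),
                rec_a$start_time, c(rec_a$t, tb), rbind(rec_a$xyz, rec_b$xyz))
}

#' Resample a recording to a uniform 50 Hz grid
#'
#' Per-axis cubic interpolating spline (not-a-knot boundary conditions;
#' reproduces cubic signals exactly) evaluated on the uniform grid
#' `t0 + k / rate` spanning the recording. Spans where consecutive
#' source samples are further apart than `gap_tol_s` are treated as
#' missing: grid samples inside them are NA rather than interpolated.
#'
#' @param rec a [raw_recording()] with at least 4 samples.
#' @param rate_hz target rate (default 50).
#' @param gap_tol_s largest source-sample spacing that is still
#'   interpolated across.
#' @return A [raw_recording()] on the uniform grid, with attribute
#'   `rate_hz`; `xyz` may contain NA rows in gaps.
#' @export
resample_to_50hz <- function(rec, rate_hz = 50, gap_tol_s = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- length(rec$t)
  if (n < 4) stopf("resampling needs at least 4 samples")
  t0 <- rec$t[1]
  tq <- t0 + seq.int(0, floor((rec$t[n] - t0) * rate_hz)) / rate_hz
  gaps <- which(diff(rec$t) > gap_tol_s)
  if (!length(gaps)) {
    out <- cpp_spline_resample_mat(rec$t, rec$xyz, tq)
  } else {
    out <- matrix(NA_real_, length(tq), 3)
    seg_start <- c(1L, gaps + 1L)
    seg_end <- c(gaps, n)
    for (s in seq_along(seg_start)) {
      i0 <- seg_start[s]; i1 <- seg_end[s]
      if (i1 - i0 + 1L < 4L) next
      q0 <- ceiling((rec$t[i0] - t0) * rate_hz - 1e-9) + 1L
      q1 <- floor((rec$t[i1] - t0) * rate_hz + 1e-9) + 1L
      if (q1 < q0) next
      qi <- q0:q1
      out[qi, ] <- cpp_spline_resample_mat(rec$t[i0:i1],
                                           rec$xyz[i0:i1, , drop = FALSE],
                                           tq[qi])
    }
  }
  res <- structure(
    list(participant_id = rec$participant_id, device_id = rec$device_id,
         start_time = rec$start_time, t = tq, xyz = out),
    class = "raw_recording")
  attr(res, "rate_hz") <- rate_hz
  res
}

#' Band-passed acceleration magnitude series
#'
#' Computes the Euclidean magnitude of the uniformly sampled signal and
#' removes gravity (DC) and high-frequency noise with a zero-phase
#' Butterworth band-pass (default 0.2-15 Hz, order 4, applied
#' forward-backward). Each contiguous non-missing span is filtered
#' separately; the first and last `edge_trim_s` seconds of every span
#' are flagged unreliable (set to NA) to discard filter edge transients,
#' and spans shorter than `2 * edge_trim_s` are dropped entirely.
#'
#' @param rec a uniformly resampled [raw_recording()] from
#'   [resample_to_50hz()].
#' @param low_hz,high_hz,order Butterworth band edges and order.
#' @param edge_trim_s seconds trimmed at each span edge.
#' @return A `magnitude_series`: participant id, `rate_hz`, `t0`
#'   (POSIXct of the first grid sample), and `m_mg`, the signed
#'   band-passed magnitude in mg with NA where missing/unreliable.
#' @export
bandpass_magnitude <- function(rec, low_hz = 0.2, high_hz = 15, order = 4,
                               edge_trim_s = 5) {
  stopifnot(inherits(rec, "raw_recording"))
  rate <- attr(rec, "rate_hz")
  if (is.null(rate)) {
    dt <- diff(rec$t)
    if (diff(range(dt)) > 1e-6)
      stopf("bandpass_magnitude() needs a uniformly resampled recording")
    rate <- 1 / stats::median(dt)
  }
  coefs <- bandpass_coefs(low_hz, high_hz, order, rate)
  mag <- cpp_magnitude(rec$xyz, 1000)
  filter_magnitude(mag, rec$participant_id, rec$start_time + rec$t[1],
                   rate, coefs, edge_trim_s)
}

# Shared tail of bandpass_magnitude: zero-phase filtering of a uniform
# magnitude signal (mg) with NA-gap awareness and edge trimming.
filter_magnitude <- function(mag, participant_id, t0, rate, coefs,
                             edge_trim_s) {
  trim <- round(edge_trim_s * rate)
  min_len <- max(2L * trim, 3L * coefs$padlen + 1L)
  if (!anyNA(mag)) {
    len <- length(mag)
    if (len <= min_len) stopf("recording too short to filter")
    m <- zerophase_bandpass(mag, coefs)
    if (trim > 0) m[c(seq_len(trim), (len - trim + 1L):len)] <- NA_real_
  } else {
    r <- rle(!is.na(mag))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    m <- rep(NA_real_, length(mag))
    for (s in which(r$values)) {
      i0 <- starts[s]; i1 <- ends[s]
      len <- i1 - i0 + 1L
      if (len <= min_len) next
      f <- zerophase_bandpass(mag[i0:i1], coefs)
      if (trim > 0) f[c(seq_len(trim), (len - trim + 1L):len)] <- NA_real_
      m[i0:i1] <- f
    }
  }
  structure(list(participant_id = participant_id,
                 rate_hz = rate,
                 t0 = t0,
                 m_mg = m),
            class = "magnitude_series")
}

# Fused resample + magnitude for the standard pipeline path: cubic
# spline per axis evaluated on the uniform grid, magnitude taken without
# materialising the per-axis 50 Hz signal. Numerically identical to
# resample_to_50hz() followed by the magnitude step.
uniform_magnitude <- function(rec, rate_hz = 50, gap_tol_s = 1) {
  n <- length(rec$t)
  if (n < 4) stopf("resampling needs at least 4 samples")
  t0 <- rec$t[1]
  tq <- t0 + seq.int(0, floor((rec$t[n] - t0) * rate_hz)) / rate_hz
  gaps <- which(diff(rec$t) > gap_tol_s)
  if (!length(gaps)) {
    mag <- cpp_spline_magnitude(rec$t, rec$xyz, tq, 1000)
  } else {
    mag <- rep(NA_real_, length(tq))
    seg_start <- c(1L, gaps + 1L)
    seg_end <- c(gaps, n)
    for (s in seq_along(seg_start)) {
      i0 <- seg_start[s]; i1 <- seg_end[s]
      if (i1 - i0 + 1L < 4L) next
      q0 <- ceiling((rec$t[i0] - t0) * rate_hz - 1e-9) + 1L
      q1 <- floor((rec$t[i1] - t0) * rate_hz + 1e-9) + 1L
      if (q1 < q0) next
      qi <- q0:q1
      mag[qi] <- cpp_spline_magnitude(rec$t[i0:i1],
                                      rec$xyz[i0:i1, , drop = FALSE],
                                      tq[qi], 1000)
    }
  }
  list(mag_mg = mag, rate_hz = rate_hz, t0 = rec$start_time + t0,
       participant_id = rec$participant_id)
}

#' Write a magnitude series as delimited text
#'
#' Two tab-separated columns `t` (seconds since `t0`) and `m_mg`, with a
#' `#key=value` header (participant id, rate, t0, schema version).
#' Mostly useful for exporting short excerpts; a week at 50 Hz is some
#' 30 million rows.
#'
#' @param mag a `magnitude_series`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_magnitude_series <- function(mag, path) {
  stopifnot(inherits(mag, "magnitude_series"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("#%s=%s",
                 c("schema_version", "participant_id", "rate_hz", "t0"),
                 c("1", mag$participant_id, format(mag$rate_hz),
                   format(mag$t0, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")))
  writeLines(c(hdr, "t\tm_mg"), con)
  tt <- (seq_along(mag$m_mg) - 1) / mag$rate_hz
  writeLines(sprintf("%.3f\t%.5g", tt, mag$m_mg), con)
  invisible(path)
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %s, %g Hz, %.2f h (%.1f%% present)\n",
              x$participant_id, x$rate_hz,
              length(x$m_mg) / x$rate_hz / 3600,
              100 * mean(!is.na(x$m_mg))))
  invisible(x)
}
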