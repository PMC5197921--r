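# Per-minute signal characteristics (activity, jerk, entropy), the
# 1440-minute average-day profile, and window means.

#' Per-minute activity, jerk and entropy features
#'
#' For every minute covered by the magnitude series, computes:
#' \describe{
#'   \item{activity (mg)}{mean absolute band-passed magnitude: how much,
#'     on average, the device was accelerated within the minute. The
#'     absolute value is taken because the band-passed magnitude is
#'     signed and its plain mean telescopes toward zero.}
#'   \item{jerk (mg/s)}{mean absolute first derivative of the magnitude,
#'     slope-estimated by a centred five-sample least-squares
#'     regression: d_t = sum(k * m_(t+k), k = -2..2) / (10 * dt).
#'     High jerk marks sudden, "quick" movements.}
#'   \item{entropy (bits)}{Shannon entropy of the minute's magnitude
#'     histogram over 64 fixed bins of width 15.625 mg spanning
#'     \[-500, 500) mg (values outside clamp to the edge bins). Low
#'     entropy: stationary or repetitive movement; high entropy:
#'     unpredictable, gesture-like movement.}
#' }
#' Minutes with fewer than `min_samples` valid samples (default half a
#' minute at 50 Hz) or falling in non-wear segments are missing.
#'
#' @param mag a `magnitude_series` from [bandpass_magnitude()].
#' @param mask the `wear_mask` from [classify_wear()]; when omitted all
#'   minutes count as worn (useful for bench signals).
#' @param min_samples minimum valid samples per minute.
#' @param features which of `"activity"`, `"jerk"`, `"entropy"` to
#'   compute (the others are returned as NA).
#' @param entropy_bins,entropy_range_mg number of fixed histogram bins
#'   and the magnitude range they span; values outside clamp to the
#'   edge bins. The defaults (64 bins over \[-500, 500) mg) bound the
#'   entropy at 6 bits and make it comparable across minutes and
#'   participants.
#' @return A `minute_features` data frame: `date`, `minute_of_day`
#'   (0-1439), `activity_mg`, `jerk_mg_s`, `entropy_bits`, `worn`,
#'   `n_samples`.
#' @export
minute_features <- function(mag, mask = NULL, min_samples = 1500,
                            features = c("activity", "jerk", "entropy"),
                            entropy_bins = 64,
                            entropy_range_mg = c(-500, 500)) {
  stopifnot(inherits(mag, "magnitude_series"))
  features <- match.arg(features, several.ok = TRUE)
  rate <- mag$rate_hz
  off0 <- sec_of_day(mag$t0)
  m <- mag$m_mg
  idx <- cpp_seq_bins(length(m), off0, rate, 60)
  min0 <- floor(off0 / 60)
  nmin <- idx[length(idx)] + 1L

  mm <- bin_moments(m, idx, nmin)
  n_valid <- mm[, "n"]
  act <- jrk <- ent <- rep(NA_real_, nmin)

  if ("activity" %in% features)
    act <- ifelse(n_valid > 0, mm[, "sumabs"] / n_valid, NA_real_)
  if ("jerk" %in% features) {
    md <- cpp_jerk_bins(m, idx, nmin, rate / 10)
    jrk <- ifelse(md[, 1] > 0, md[, 2] / md[, 1], NA_real_)
  }
  if ("entropy" %in% features) {
    nb <- as.integer(entropy_bins)
    width <- diff(entropy_range_mg) / nb
    cm <- cpp_entropy_counts(m, idx, nmin, nb, entropy_range_mg[1], width)
    tot <- colSums(cm)
    p <- sweep(cm, 2, pmax(tot, 1), `/`)
    plogp <- p * log2(p)
    plogp[p == 0] <- 0
    ent <- ifelse(tot > 0, -colSums(plogp) + 0, NA_real_)  # + 0 avoids -0
  }

  min_abs <- min0 + seq_len(nmin) - 1
  day0 <- as.Date(midnight_of(mag$t0))
  mod <- as.integer(min_abs %% 1440)
  out <- data.frame(date = day0 + floor(min_abs / 1440),
                    minute_of_day = mod,
                    activity_mg = act, jerk_mg_s = jrk, entropy_bits = ent,
                    n_samples = as.integer(n_valid),
                    stringsAsFactors = FALSE)
  worn <- rep(TRUE, nmin)
  if (!is.null(mask)) {
    seg_min <- attr(mask, "segment_min") %||% 30
    key <- paste(out$date, (out$minute_of_day %/% seg_min))
    mkey <- paste(mask$date, mask$seg_of_day)
    wz <- mask$worn[match(key, mkey)]
    worn <- !is.na(wz) & wz
  }
  out$worn <- worn
  bad <- !worn | n_valid < min_samples
  out$activity_mg[bad] <- NA_real_
  out$jerk_mg_s[bad] <- NA_real_
  out$entropy_bits[bad] <- NA_real_
  attr(out, "participant_id") <- mag$participant_id
  class(out) <- c("minute_features", "data.frame")
  out
}

#' Single-minute feature accessors
#'
#' Convenience accessors returning one feature for one minute of the
#' series (`minute` indexes minutes from the midnight preceding the
#' series start, 0-based). They evaluate the same estimators as
#' [minute_features()].
#'
#' @param mag a `magnitude_series`.
#' @param minute 0-based absolute minute index.
#' @param mask optional `wear_mask`.
#' @return The feature value (mg, mg/s or bits), NA when the minute is
#'   missing or unworn.
#' @export
minute_activity <- function(mag, minute, mask = NULL) {
  .minute_lookup(mag, minute, mask, "activity_mg", "activity")
}

#' @rdname minute_activity
#' @export
minute_jerk <- function(mag, minute, mask = NULL) {
  .minute_lookup(mag, minute, mask, "jerk_mg_s", "jerk")
}

#' @rdname minute_activity
#' @export
minute_entropy <- function(mag, minute, mask = NULL) {
  .minute_lookup(mag, minute, mask, "entropy_bits", "entropy")
}

.minute_lookup <- function(mag, minute, mask, col, feat) {
  mf <- minute_features(mag, mask, features = feat)
  abs_min <- as.integer(as.numeric(mf$date - mf$date[1]) * 1440 +
                          mf$minute_of_day)
  mf[[col]][match(minute, abs_min)]
}

#' Average-day profile of a participant
#'
#' Averages each feature per minute of day across all included days;
#' non-wear and missing minutes are excluded from each minute's mean.
#'
#' @param features a `minute_features` data frame.
#' @param days the `day_record` from [qualify_days()]; only included
#'   days contribute.
#' @return An `avg_day_profile` data frame with exactly 1440 rows:
#'   `minute_of_day`, `activity_mg`, `jerk_mg_s`, `entropy_bits`,
#'   `n_days` (days contributing to that minute).
#' @export
average_day <- function(features, days) {
  stopifnot(inherits(features, "minute_features"),
            inherits(days, "day_record"))
  inc <- days$date[days$included]
  if (!length(inc))
    stopf("participant has no included days; excluded from analysis")
  f <- features[features$date %in% inc, ]
  idx <- f$minute_of_day
  out <- data.frame(minute_of_day = 0:1439)
  cnts <- list()
  for (col in c("activity_mg", "jerk_mg_s", "entropy_bits")) {
    s <- group_sums(f[[col]], idx, 1440L)
    out[[col]] <- ifelse(s$n > 0, s$sum / s$n, NA_real_)
    cnts[[col]] <- s$n
  }
  # n_days follows the activity column when computed (the features share
  # their missingness gates: worn status and sample count); otherwise
  # the widest computed feature
  nd <- if (sum(cnts$activity_mg) > 0) cnts$activity_mg else
    do.call(pmax, cnts)
  out$n_days <- as.integer(nd)
  class(out) <- c("avg_day_profile", "data.frame")
  attr(out, "participant_id") <- attr(features, "participant_id")
  out
}

#' Window means of an average-day profile
#'
#' Unweighted mean of each feature over the non-missing minutes of a
#' minute-of-day window: `night` 00:00-06:00, `daytime` 06:00-24:00,
#' `morning` 06:00-12:00, or `day24` (whole average day, the quantity
#' entering the group t tests).
#'
#' @param profile an `avg_day_profile`.
#' @param window one of `"night"`, `"daytime"`, `"morning"`, `"day24"`.
#' @return Named numeric vector (`activity_mg`, `jerk_mg_s`,
#'   `entropy_bits`); NA where the window is fully missing.
#' @export
segment_mean <- function(profile,
                         window = c("daytime", "night", "morning", "day24")) {
  stopifnot(inherits(profile, "avg_day_profile"))
  window <- match.arg(window)
  rng <- switch(window,
                night = 0:359, daytime = 360:1439,
                morning = 360:719, day24 = 0:1439)
  rows <- profile$minute_of_day %in% rng
  vapply(c("activity_mg", "jerk_mg_s", "entropy_bits"), function(col) {
    v <- profile[[col]][rows]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
}
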