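# Wear-time detection on 30-minute, midnight-aligned segments and the
# day-qualification rules (half-day wear, successful calibration, no
# malfunction).

#' Classify 30-minute segments as wear / non-wear
#'
#' For each consecutive 30-minute segment aligned to local midnight, the
#' standard deviation of the available band-passed magnitude samples is
#' computed; the segment is wear-time when that SD strictly exceeds
#' `sd_threshold_mg` (default 13 mg). Segments with fewer than half
#' their samples present are still classified from the available samples
#' but flagged.
#'
#' @param mag a `magnitude_series` from [bandpass_magnitude()].
#' @param sd_threshold_mg wear threshold, mg.
#' @param segment_min segment length in minutes (30 in the standard
#'   rule).
#' @return A `wear_mask` data frame: `date`, `seg_of_day` (0-47),
#'   `sd_mg`, `n_samples`, `frac_present`, `worn`, `flagged`.
#' @export
classify_wear <- function(mag, sd_threshold_mg = 13, segment_min = 30) {
  stopifnot(inherits(mag, "magnitude_series"))
  if (!length(mag$m_mg) || all(is.na(mag$m_mg)))
    stopf("empty magnitude series")
  seg_s <- segment_min * 60
  off0 <- sec_of_day(mag$t0)
  ns <- length(mag$m_mg)
  idx <- cpp_seq_bins(ns, off0, mag$rate_hz, seg_s)
  seg0 <- floor(off0 / seg_s)
  nseg <- idx[ns] + 1L
  mm <- bin_moments(mag$m_mg, idx, nseg)
  n <- mm[, "n"]
  sd_mg <- rep(NA_real_, nseg)
  have <- n >= 2
  sd_mg[have] <- sqrt(pmax(0, (mm[have, "sumsq"] -
                                 mm[have, "sum"]^2 / n[have]) /
                             (n[have] - 1)))
  seg_abs <- seg0 + seq_len(nseg) - 1
  day0 <- midnight_of(mag$t0)
  out <- data.frame(
    date = as.Date(day0) + floor(seg_abs * seg_s / 86400),
    seg_of_day = as.integer(seg_abs %% (86400 / seg_s)),
    sd_mg = sd_mg,
    n_samples = as.integer(n),
    frac_present = n / (seg_s * mag$rate_hz),
    stringsAsFactors = FALSE)
  out$worn <- !is.na(sd_mg) & sd_mg > sd_threshold_mg
  out$flagged <- out$frac_present < 0.5
  class(out) <- c("wear_mask", "data.frame")
  attr(out, "segment_min") <- segment_min
  out
}

#' Qualify calendar days for analysis
#'
#' A day qualifies when the device was worn for more than half the day
#' (strictly more than 720 minutes), the device calibration succeeded,
#' and malfunction is ruled out. Partial first/last days usually fail
#' the half-day rule and are excluded with reason `partial_day`.
#'
#' @param mask a `wear_mask` from [classify_wear()].
#' @param calib the device's `calibration_model` (or a list of models
#'   for multi-device participants; all must have succeeded).
#' @param malfunction logical flag from file-integrity checks; this is
#'   an input, not inferred from the signal.
#' @param min_worn_min strict lower bound on worn minutes for inclusion.
#' @return A `day_record` data frame: `date`, `minutes_worn`,
#'   `minutes_covered`, `included`, `exclusion_reason` (none /
#'   short_wear / partial_day / calibration_failure / malfunction).
#' @export
qualify_days <- function(mask, calib, malfunction = FALSE,
                         min_worn_min = 720) {
  stopifnot(inherits(mask, "wear_mask"))
  seg_min <- attr(mask, "segment_min") %||% 30
  calib_ok <- if (inherits(calib, "calibration_model")) isTRUE(calib$success)
    else all(vapply(calib, function(m) isTRUE(m$success), TRUE))
  worn_min <- rowsum(ifelse(mask$worn, seg_min, 0), as.character(mask$date))
  cover_min <- rowsum(pmin(mask$frac_present, 1) * seg_min,
                      as.character(mask$date))
  dates <- as.Date(rownames(worn_min))
  o <- order(dates)
  out <- data.frame(date = dates[o],
                    minutes_worn = as.numeric(worn_min[o, 1]),
                    minutes_covered = as.numeric(cover_min[o, 1]),
                    stringsAsFactors = FALSE)
  reason <- rep("none", nrow(out))
  reason[out$minutes_worn <= min_worn_min] <- "short_wear"
  partial <- out$minutes_covered < 1440 * 0.99 &
    out$minutes_worn <= min_worn_min
  reason[partial] <- "partial_day"
  if (isTRUE(malfunction)) reason[] <- "malfunction"
  if (!calib_ok) reason[] <- "calibration_failure"
  out$included <- reason == "none"
  out$exclusion_reason <- reason
  class(out) <- c("day_record", "data.frame")
  out
}

#' Wear compliance over included days
#'
#' Total worn minutes on included days divided by the total minutes
#' those days span (1440 each).
#'
#' @param days a `day_record` from [qualify_days()].
#' @return Fraction in \[0, 1\], or `NA` when no day is included.
#' @export
compliance <- function(days) {
  stopifnot(inherits(days, "day_record"))
  inc <- days$included
  if (!any(inc)) return(NA_real_)
  sum(days$minutes_worn[inc]) / (1440 * sum(inc))
}
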