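# Synthetic cohort generator. Ground truth is expressed per minute of day
# as lambda_min: the true dynamic-acceleration standard deviation (mg) of
# the worn device, per participant. Recordings are synthesised sample by
# sample from lambda_min, a slowly re-orienting unit gravity vector,
# sensor noise, and per-device gain/offset miscalibration.

#' True minute-of-day intensity profile of one participant
#'
#' Deterministic circadian part: night/day baseline blended by a
#' raised-cosine envelope plus three Gaussian bumps (morning bump scaled
#' by 1 - delta for cases). Stochastic part: sporadic nocturnal movement
#' bursts. The whole profile is multiplied by the subject's activity
#' scale. Called with the RNG state managed by [simulate_truths()].
#'
#' @noRd
build_lambda_profile <- function(config, group, scale) {
  m <- 0:1439
  e <- numeric(1440)
  br <- config$envelope_min
  up <- m >= br[1] & m < br[2]
  e[up] <- (1 - cos(pi * (m[up] - br[1]) / (br[2] - br[1]))) / 2
  e[m >= br[2] & m < br[3]] <- 1
  dn <- m >= br[3] & m < br[4]
  e[dn] <- (1 + cos(pi * (m[dn] - br[3]) / (br[4] - br[3]))) / 2
  lam <- config$base_night_mg + (config$base_day_mg - config$base_night_mg) * e
  bp <- config$bump_params
  att <- c(if (group == "case") 1 - config$morning_attenuation else 1, 1, 1)
  for (j in seq_len(nrow(bp))) {
    lam <- lam + att[j] * bp$height_mg[j] *
      exp(-0.5 * ((m - bp$center_min[j]) / bp$sd_min[j])^2)
  }
  # sporadic movement bursts wherever the day envelope is low: sleep
  # movements at night, fidgeting in the late-evening / early-morning
  # transitions; these keep genuinely worn low-activity segments above
  # the 13 mg wear threshold, as wrist data do in practice
  low <- e < 0.6
  bursts <- low & (stats::rbinom(1440, 1L, config$night_burst_prob) == 1L)
  lam[bursts] <- lam[bursts] + config$night_burst_mg
  lam * scale
}

#' Simulate participant-level ground truth for a cohort
#'
#' Draws, for `2 * n_per_group` participants (cases then controls),
#' the true intensity profile, non-wear schedule, per-device calibration
#' errors, covariates, and clinical outcomes generated from the target
#' partial correlations with true daytime intensity. No raw signal is
#' synthesised, so this is cheap enough for statistical calibration
#' studies with hundreds of replicates.
#'
#' @param config a [sim_config()].
#' @return List with `truths` (list of `participant_truth`) and
#'   `covariates` (data frame: participant_id, group, age, sex, bmi, iq
#'   and the four outcome scores).
#' @export
simulate_truths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_group
  groups <- rep(c("case", "control"), each = config$n_per_group)
  cd <- config$covariate_dists
  midnight1 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")

  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    age <- rnorm(1, cd$age[1], cd$age[2])
    sex <- rbinom(1, 1, cd$sex_p)
    bmi <- rnorm(1, cd$bmi[1], cd$bmi[2]) +
      if (g == "case") cd$bmi_case_shift else 0
    iq <- rnorm(1, cd$iq[1], cd$iq[2]) +
      if (g == "case") cd$iq_case_shift else 0
    scale <- exp(rnorm(1, 0, config$subject_scale_sd))
    lam <- build_lambda_profile(config, g, scale)

    nw <- config$nonwear
    ints <- matrix(numeric(0), ncol = 2)
    for (d in seq_len(config$n_days)) {
      if (runif(1) < nw$prob_per_day) {
        # whole-minute bouts: removal/re-donning happens on the minute
        # scale, and minute-aligned truth keeps the worn state constant
        # within each feature minute
        dur <- round(min(max(rnorm(1, nw$dur_mean_min, nw$dur_sd_min),
                             nw$dur_range_min[1]), nw$dur_range_min[2]))
        st <- floor(runif(1, nw$start_range_min[1], nw$start_range_min[2]))
        st <- min(st, 1440 - dur)
        ints <- rbind(ints, (d - 1) * 1440 + c(st, st + dur))
      }
    }

    truths[[i]] <- structure(list(
      participant_id = sprintf("P%03d", i),
      group = g,
      lambda_min = lam,
      scale = scale,
      device_gain = matrix(1 + rnorm(6, 0, config$calib_gain_sd), 2, 3),
      device_offset_mg = matrix(rnorm(6, 0, config$calib_offset_sd_mg), 2, 3),
      nonwear_intervals = ints,
      swing_axis = { u <- rnorm(3); u / sqrt(sum(u^2)) },
      covariates = list(age = age, sex = sex, bmi = bmi, iq = iq),
      midnight1 = midnight1,
      rec_seed = sample.int(.Machine$integer.max - 1L, 1L)
    ), class = "participant_truth")
  }

  d_true <- vapply(truths, true_daytime_mean, 0)
  cov_df <- data.frame(
    participant_id = vapply(truths, `[[`, "", "participant_id"),
    group = groups,
    age = vapply(truths, function(x) x$covariates$age, 0),
    sex = vapply(truths, function(x) x$covariates$sex, 0),
    bmi = vapply(truths, function(x) x$covariates$bmi, 0),
    iq = vapply(truths, function(x) x$covariates$iq, 0),
    stringsAsFactors = FALSE)

  # Outcomes: linear in true daytime intensity and confounds. The slope
  # on intensity is solved per group from the target partial correlation
  # rho: beta = rho / sqrt(1 - rho^2) * noise_sd / sd(D_group), so the
  # within-group partial correlation given the confounds equals rho.
  for (oname in names(config$outcome_model)) {
    om <- config$outcome_model[[oname]]
    y <- numeric(n)
    for (g in c("case", "control")) {
      gi <- which(groups == g)
      dg <- d_true[gi]
      sd_d <- if (length(dg) > 1) stats::sd(dg) else 0
      beta <- if (om$rho == 0 || sd_d == 0) 0 else
        om$rho / sqrt(1 - om$rho^2) * om$noise_sd / sd_d
      mu <- if (g == "case") om$mean_case else om$mean_control
      y[gi] <- mu + beta * (dg - mean(dg)) +
        om$conf["age"] * (cov_df$age[gi] - cd$age[1]) +
        om$conf["sex"] * cov_df$sex[gi] +
        om$conf["bmi"] * (cov_df$bmi[gi] - cd$bmi[1]) +
        om$conf["iq"] * (cov_df$iq[gi] - cd$iq[1]) +
        rnorm(length(gi), 0, om$noise_sd)
    }
    cov_df[[oname]] <- y
  }
  for (i in seq_len(n)) truths[[i]]$outcomes <-
    as.list(cov_df[i, names(config$outcome_model)])

  list(truths = truths, covariates = cov_df)
}

#' @export
print.participant_truth <- function(x, ...) {
  cat(sprintf(
    "<participant_truth> %s (%s), daytime intensity %.1f mg, %d non-wear bouts\n",
    x$participant_id, x$group, true_daytime_mean(x),
    nrow(x$nonwear_intervals)))
  invisible(x)
}

#' True mean daytime intensity of a simulated participant
#'
#' Ground-truth accessor used by recovery tests: the mean of the true
#' minute-of-day intensity over the daytime window 06:00-24:00.
#'
#' @param truth a `participant_truth`.
#' @return Intensity in mg.
#' @export
true_daytime_mean <- function(truth) {
  mean(truth$lambda_min[361:1440])
}

# Synthesise the measured signal for the full recording span: gravity +
# isotropic dynamics + arm swing + sensor noise through the per-device
# affine sensor model. Sensor noise is folded into the per-axis Gaussian
# before the gain (the gain perturbs the 2 mg noise by at most ~1%, far
# below any threshold in the pipeline). The orientation random walk is
# simulated on a 1 s grid and interpolated per sample (its 0.5 deg/s
# steps carry essentially no power near the sampling rate); the
# per-sample work (3 Gaussian draws, table lookups, one sine, the
# sensor model) runs in one fused C++ pass.
#
# `split_t`: seconds-from-start instant at which the second device takes
# over (Inf for a single-device recording). `devices`: which device row
# of truth$device_gain/offset to use before/after the split.
sim_measured <- function(truth, config, seed, devices = c(1L, 1L),
                         split_t = Inf) {
  set.seed(seed)
  rate <- config$native_rate_hz
  lead_s <- config$partial_first_min * 60
  total_s <- lead_s + config$n_days * 86400 + config$partial_last_min * 60
  n <- floor(total_s * rate)
  n_min <- ceiling(total_s / 60)
  n_sec <- ceiling(total_s) + 1L

  dt <- (1 / rate) * (1 + rnorm(n - 1, 0, config$jitter_sd))
  t <- c(0, cumsum(dt))

  # Per-minute truth tables over the recording span (minute 0 = start).
  min_rel <- seq_len(n_min) - 1 - config$partial_first_min  # since midnight 1
  lam_tab <- truth$lambda_min[(min_rel %% 1440L) + 1L]
  worn_tab <- rep(TRUE, n_min)
  ints <- truth$nonwear_intervals
  if (nrow(ints) > 0)
    worn_tab <- findInterval(min_rel + 0.5, as.vector(t(ints))) %% 2L == 0L
  lam_tab <- lam_tab * worn_tab

  # Orientation walk at 1 s resolution: azimuth/elevation steps while
  # worn, frozen during non-wear, sporadic posture jumps at minute marks.
  rot <- config$rotation
  sec_min <- pmin(floor(seq_len(n_sec) - 1) %/% 60 + 1L, n_min)
  worn_sec <- worn_tab[sec_min]
  step_sd <- rot$step_deg_per_s * pi / 180
  s_th <- rnorm(n_sec, 0, step_sd) * worn_sec
  s_ph <- rnorm(n_sec, 0, step_sd) * worn_sec
  min_start <- which((seq_len(n_sec) - 1) %% 60 == 0 & worn_sec)
  jump <- min_start[runif(length(min_start)) < rot$jump_prob_per_min]
  if (length(jump)) {
    jsd <- rot$jump_sd_deg * pi / 180
    s_th[jump] <- s_th[jump] + rnorm(length(jump), 0, jsd)
    s_ph[jump] <- s_ph[jump] + rnorm(length(jump), 0, jsd)
  }
  theta <- runif(1, 0, 2 * pi) + cumsum(s_th)
  phi <- runif(1, 0, pi) + cumsum(s_ph)
  sph <- sin(phi)
  G <- cbind(sph * cos(theta), sph * sin(theta), cos(phi))

  # Dynamic component: isotropic Gaussian with per-axis SD lambda (mg)
  # so the magnitude signal |g + d| ~ 1 + d.ghat has SD lambda, plus a
  # 2 Hz arm-swing sinusoid during movement bouts carrying a `weight`
  # share of the variance in expectation over orientations
  # (amplitude lambda * sqrt(6 w), E[(u.ghat)^2] = 1/3).
  sw <- config$swing
  active_tab <- lam_tab > sw$threshold_mg
  sd_tab <- sqrt(lam_tab^2 * (1 - sw$weight * active_tab) +
                   config$sensor_noise_sd_mg^2) / 1000
  amp_tab <- (lam_tab * sqrt(6 * sw$weight) / 1000) * active_tab
  phase0 <- runif(1, 0, 2 * pi)

  split_row <- if (is.finite(split_t)) findInterval(split_t, t) + 1 else n + 1
  xyz <- cpp_assemble_measure(
    t, G, sd_tab, amp_tab, truth$swing_axis,
    2 * pi * sw$freq_hz, phase0,
    truth$device_gain[devices, , drop = FALSE],
    truth$device_offset_mg[devices, , drop = FALSE] / 1000,
    split_row)

  list(t = t, xyz = xyz, start_time = truth$midnight1 - lead_s)
}

#' Simulate one raw recording from participant ground truth
#'
#' Synthesises the measured signal over the full recording span (partial
#' first day, `n_days` full days, partial last day): a slowly
#' re-orienting unit gravity vector, isotropic dynamic acceleration with
#' per-minute SD equal to the true intensity profile (zero and frozen
#' orientation during non-wear), sensor noise, then the device's
#' gain/offset model `measured = gain * a + offset`.
#'
#' @param truth a `participant_truth` from [simulate_truths()].
#' @param config the [sim_config()] used to create `truth`.
#' @param seed integer seed (defaults to the truth's own recording seed).
#' @param device which device's calibration error to apply (1 or 2).
#' @return A [raw_recording()].
#' @export
simulate_recording <- function(truth, config, seed = truth$rec_seed,
                               device = 1L) {
  stopifnot(inherits(truth, "participant_truth"))
  sig <- sim_measured(truth, config, seed, devices = c(device, device))
  raw_recording(truth$participant_id, sprintf("D%s", device),
                sig$start_time, sig$t, sig$xyz)
}

#' Simulate a full cohort of recordings with ground truth
#'
#' Generates participant truths via [simulate_truths()], then one
#' recording per participant. With `config$split_devices` the recording
#' is split at a mid-week noon changeover into two device files with
#' independent calibration errors and a short gap of missing samples.
#'
#' @param config a [sim_config()].
#' @return A `cohort_bundle`: list with `recordings` (per participant, a
#'   list of one or two [raw_recording()]s), `truths`, and `covariates`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tb <- simulate_truths(config)
  recs <- lapply(tb$truths, simulate_participant_recordings, config = config)
  names(recs) <- vapply(tb$truths, `[[`, "", "participant_id")
  structure(list(recordings = recs, truths = tb$truths,
                 covariates = tb$covariates, config = config),
            class = "cohort_bundle")
}

#' Simulate the device file(s) of one participant
#'
#' One recording, or a changeover pair (two devices with independent
#' calibration errors, split at noon of the middle recording day with a
#' short gap of missing samples). A changeover only happens on
#' recordings too long for one battery (`n_days >= 4` and
#' `config$split_devices`); short recordings stay on a single device.
#'
#' @param truth a `participant_truth`.
#' @param config the matching [sim_config()].
#' @return List of one or two [raw_recording()]s.
#' @export
simulate_participant_recordings <- function(truth, config) {
  split <- config$split_devices && config$n_days >= 4
  if (!split) return(list(simulate_recording(truth, config)))
  co_t <- config$partial_first_min * 60 +
    ((ceiling(config$n_days / 2) - 1) * 1440 + 720) * 60
  sig <- sim_measured(truth, config, truth$rec_seed, devices = c(1L, 2L),
                      split_t = co_t)
  ia <- which(sig$t < co_t)
  ib <- which(sig$t >= co_t + config$changeover_gap_s)
  rec_a <- raw_recording(truth$participant_id, "D1", sig$start_time,
                         sig$t[ia], sig$xyz[ia, , drop = FALSE])
  tb0 <- sig$t[ib[1]]
  rec_b <- raw_recording(truth$participant_id, "D2",
                         sig$start_time + tb0, sig$t[ib] - tb0,
                         sig$xyz[ib, , drop = FALSE])
  list(rec_a, rec_b)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d participants (%d case / %d control)\n",
              length(x$truths),
              sum(x$covariates$group == "case"),
              sum(x$covariates$group == "control")))
  cat(sprintf("  %d device file(s) per participant, %d full days\n",
              length(x$recordings[[1]]), x$config$n_days))
  invisible(x)
}
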