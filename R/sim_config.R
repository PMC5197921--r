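#' Configuration for the synthetic cohort simulator
#'
#' Bundles every knob of the generative model: cohort size and recording
#' length, the circadian intensity profile (baseline day/night levels,
#' three Gaussian intensity bumps, night movement bursts), the case-group
#' morning attenuation, non-wear scheduling, per-device miscalibration,
#' sensor noise, wrist-orientation dynamics, covariate distributions and
#' the outcome model that plants target partial correlations between
#' true daytime intensity and clinical scores.
#'
#' All intensities are milli-g (mg) of per-minute dynamic acceleration
#' standard deviation; times of day are minutes since local midnight.
#'
#' @param n_per_group participants per arm (cases and controls).
#' @param n_days full recording days per participant; the recording also
#'   spans a partial first and last day (`partial_first_min`,
#'   `partial_last_min` minutes) that the half-day rule later excludes.
#' @param native_rate_hz device sampling rate before 50 Hz resampling.
#' @param jitter_sd multiplicative timestamp jitter standard deviation.
#' @param morning_attenuation fractional reduction (\eqn{\delta \in
#'   [0,1]}) of the case group's morning intensity bump.
#' @param bump_params data frame with `center_min`, `sd_min`, `height_mg`
#'   for the morning, afternoon and evening intensity bumps.
#' @param base_day_mg,base_night_mg circadian baseline intensity levels.
#' @param envelope_min four minute-of-day breakpoints (rise start/end,
#'   fall start/end) of the raised-cosine day envelope.
#' @param night_burst_prob,night_burst_mg per-minute probability and size
#'   of sporadic movement bursts (sleep movements, evening/morning
#'   fidgeting); bursts are planted where the day envelope is below 0.6.
#' @param subject_scale_sd log-normal sigma of the per-subject activity
#'   scale multiplying the whole intensity profile.
#' @param nonwear list: `prob_per_day`, `dur_mean_min`, `dur_sd_min`,
#'   `dur_range_min` (length 2), `start_range_min` (length 2).
#' @param calib_offset_sd_mg,calib_gain_sd per-axis device offset (mg)
#'   and gain miscalibration standard deviations.
#' @param sensor_noise_sd_mg white sensor noise per axis, mg.
#' @param swing list: `weight` (fraction of active-minute variance given
#'   to the arm-swing sinusoid), `freq_hz`, `threshold_mg` (minutes with
#'   intensity above this count as movement bouts).
#' @param rotation list: `step_deg_per_s` (orientation random-walk step
#'   SD while worn), `jump_prob_per_min`, `jump_sd_deg` (sporadic
#'   posture changes).
#' @param covariate_dists list of `age` (mean, sd), `bmi`, `iq`,
#'   `sex_p`, plus case-group shifts `bmi_case_shift`, `iq_case_shift`.
#' @param outcome_model named list (iadl, sf36, pal, madrs); each entry
#'   has `rho` (target within-group partial correlation with true
#'   daytime intensity), `noise_sd`, `mean_control`, `mean_case`, and
#'   `conf` (named coefficients on age, sex, bmi, iq).
#' @param split_devices split each recording into two device files at a
#'   mid-week changeover instant (battery swap), with
#'   `changeover_gap_s` seconds of missing data.
#' @param partial_first_min,partial_last_min minutes recorded on the
#'   partial day before day 1 and after the last full day.
#' @param start_date calendar date of the first full recording day.
#' @param seed integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 29,
                       n_days = 7,
                       native_rate_hz = 30,
                       jitter_sd = 1e-4,
                       morning_attenuation = 0.3,
                       bump_params = data.frame(
                         center_min = c(540, 900, 1200),
                         sd_min     = c(80, 75, 60),
                         height_mg  = c(80, 50, 30)),
                       base_day_mg = 15,
                       base_night_mg = 3,
                       envelope_min = c(360, 450, 1290, 1380),
                       night_burst_prob = 0.25,
                       night_burst_mg = 60,
                       subject_scale_sd = 0.06,
                       nonwear = list(prob_per_day = 0.9,
                                      dur_mean_min = 150,
                                      dur_sd_min = 25,
                                      dur_range_min = c(30, 300),
                                      start_range_min = c(480, 1140)),
                       calib_offset_sd_mg = 20,
                       calib_gain_sd = 0.01,
                       sensor_noise_sd_mg = 2,
                       swing = list(weight = 0.15, freq_hz = 2,
                                    threshold_mg = 50),
                       rotation = list(step_deg_per_s = 0.5,
                                       jump_prob_per_min = 0.03,
                                       jump_sd_deg = 45),
                       covariate_dists = list(age = c(74, 6),
                                              bmi = c(26, 4),
                                              iq = c(112, 8),
                                              sex_p = 0.5,
                                              bmi_case_shift = 0,
                                              iq_case_shift = 0),
                       outcome_model = default_outcome_model(),
                       split_devices = TRUE,
                       changeover_gap_s = 30,
                       partial_first_min = 180,
                       partial_last_min = 360,
                       start_date = "2024-01-08",
                       seed = 1L) {
  cfg <- as.list(environment())
  check_number(n_per_group, "n_per_group", min = 1)
  check_number(n_days, "n_days", min = 1)
  check_number(native_rate_hz, "native_rate_hz", min = 1)
  check_number(jitter_sd, "jitter_sd", min = 0)
  check_number(morning_attenuation, "morning_attenuation", min = 0, max = 1)
  check_number(sensor_noise_sd_mg, "sensor_noise_sd_mg", min = 0)
  check_number(subject_scale_sd, "subject_scale_sd", min = 0)
  check_number(night_burst_prob, "night_burst_prob", min = 0, max = 1)
  if (!is.data.frame(bump_params) ||
      !all(c("center_min", "sd_min", "height_mg") %in% names(bump_params)))
    stopf("'bump_params' needs columns center_min, sd_min, height_mg")
  if (any(bump_params$sd_min <= 0) || any(bump_params$height_mg < 0))
    stopf("bump widths must be positive and heights non-negative")
  check_number(nonwear$prob_per_day, "nonwear$prob_per_day", min = 0, max = 1)
  check_number(nonwear$dur_mean_min, "nonwear$dur_mean_min", min = 0)
  check_number(swing$weight, "swing$weight", min = 0, max = 0.5)
  cfg$n_per_group <- as.integer(n_per_group)
  cfg$n_days <- as.integer(n_days)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Default outcome model of the simulator
#'
#' Four clinical-score generators (IADL-, SF-36-, PAL- and MADRS-like)
#' linear in true daytime intensity and the confounds, with target
#' within-group partial correlations of +0.60, +0.65, +0.40 and -0.37.
#'
#' @return Named list of outcome specifications (see [sim_config()]).
#' @export
default_outcome_model <- function() {
  list(
    iadl  = list(rho = 0.60, noise_sd = 1.5, mean_control = 8,
                 mean_case = 6.5,
                 conf = c(age = -0.02, sex = 0.1, bmi = -0.02, iq = 0.01)),
    sf36  = list(rho = 0.65, noise_sd = 8, mean_control = 85,
                 mean_case = 62,
                 conf = c(age = -0.15, sex = 1, bmi = -0.1, iq = 0.05)),
    pal   = list(rho = 0.40, noise_sd = 5, mean_control = 25,
                 mean_case = 18,
                 conf = c(age = -0.1, sex = 0, bmi = 0, iq = 0.08)),
    madrs = list(rho = -0.37, noise_sd = 4, mean_control = 1.5,
                 mean_case = 22,
                 conf = c(age = 0.02, sex = 0, bmi = 0, iq = -0.02)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d/group, %d full days (+%d/+%d min partial), %g Hz\n",
    "  morning attenuation delta = %.2f, subject scale sd = %.2f\n",
    "  devices: %s, seed = %d\n"),
    x$n_per_group, x$n_days, x$partial_first_min, x$partial_last_min,
    x$native_rate_hz, x$morning_attenuation, x$subject_scale_sd,
    if (x$split_devices) "two per participant (mid-week changeover)"
    else "one per participant", x$seed))
  invisible(x)
}
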