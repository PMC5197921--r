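# Recovery and calibration studies: seed-controlled experiments that
# quantify how well the pipeline recovers the simulator's planted truth.
# These power the package's validation suite and can be re-run by users
# to characterise operating behaviour at other settings.

#' Morning-effect detection and localization study
#'
#' For each seed, simulates a small two-arm cohort with an attenuated
#' case-group morning intensity bump, runs the full raw-signal pipeline
#' (autocalibration, 50 Hz resampling, band-passed magnitude, wear
#' classification, day qualification, minute activity, average day),
#' then tests the confound-residualized daytime mean activity between
#' groups (pooled t) and locates the minute of day with the largest
#' group difference in mean activity.
#'
#' @param seeds integer vector: one cohort per seed.
#' @param n_per_group,n_days,delta cohort size, recording length, and
#'   morning attenuation passed to [sim_config()].
#' @param quiet suppress progress output.
#' @return Data frame per seed: `t`, `p`, `mean_diff` (case - control,
#'   mg), `peak_minute` (0-1439, argmax of the control - case activity
#'   difference), `peak_in_morning` (06:00-12:00), `n_ok` processed
#'   participants.
#' @export
morning_effect_study <- function(seeds, n_per_group = 10, n_days = 2,
                                 delta = 0.5, quiet = TRUE) {
  out <- lapply(seeds, function(sd) {
    cfg <- sim_config(n_per_group = n_per_group, n_days = n_days,
                      morning_attenuation = delta, seed = as.integer(sd))
    tb <- simulate_truths(cfg)
    res <- lapply(tb$truths, function(tr) {
      process_participant(simulate_participant_recordings(tr, cfg),
                          params = list(features = "activity"))
    })
    ok <- vapply(res, function(r) r$status == "ok", TRUE)
    grp <- tb$covariates$group[ok]
    day_mean <- vapply(res[ok], function(r)
      r$window_means["activity_mg", "daytime"], 0)
    adj <- residualize_confounds(day_mean,
                                 tb$covariates[ok, c("age", "bmi", "iq")])
    tt <- independent_ttest(adj[grp == "case"], adj[grp == "control"])
    profs <- vapply(res[ok], function(r) r$profile$activity_mg,
                    numeric(1440))
    dmin <- rowMeans(profs[, grp == "control", drop = FALSE], na.rm = TRUE) -
      rowMeans(profs[, grp == "case", drop = FALSE], na.rm = TRUE)
    peak <- which.max(dmin) - 1L
    if (!quiet)
      message(sprintf("seed %d: t = %.2f, p = %.3g, peak %02d:%02d",
                      sd, tt$t, tt$p, peak %/% 60, peak %% 60))
    data.frame(seed = sd, t = tt$t, p = tt$p, mean_diff = tt$mean_diff,
               peak_minute = peak,
               peak_in_morning = peak >= 360 && peak < 720,
               n_ok = sum(ok))
  })
  do.call(rbind, out)
}

#' Wear-time detection validation study
#'
#' Simulates a cohort with known (scripted) non-wear bouts, runs the
#' pipeline's wear classification, and scores it at the segment level
#' against the scripted truth. A segment counts as truly non-worn when
#' it lies entirely inside a scripted bout; segments containing any
#' worn time count as worn (the classifier's decision unit is the
#' 30-minute segment, so partially covered segments are not unambiguous
#' targets).
#'
#' @param config a [sim_config()] for the validation cohort.
#' @return List: `sensitivity` (non-wear detected as non-wear),
#'   `specificity` (worn detected as worn), segment counts, and the mean
#'   included-day `compliance` across participants.
#' @export
wear_validation_study <- function(config) {
  tb <- simulate_truths(config)
  tp <- fn <- tn <- fp <- 0L
  compl <- c()
  for (tr in tb$truths) {
    res <- process_participant(simulate_participant_recordings(tr, config),
                               params = list(features = "activity"))
    if (is.null(res$wear_mask)) next
    w <- res$wear_mask
    day0 <- as.Date(format(tr$midnight1, "%Y-%m-%d"))
    seg_start <- (as.numeric(w$date - day0)) * 1440 + w$seg_of_day * 30
    truly_off <- rep(FALSE, nrow(w))
    ints <- tr$nonwear_intervals
    for (k in seq_len(nrow(ints))) {
      truly_off <- truly_off | (seg_start >= ints[k, 1] &
                                  seg_start + 30 <= ints[k, 2])
    }
    use <- !w$flagged
    tp <- tp + sum(use & truly_off & !w$worn)
    fn <- fn + sum(use & truly_off & w$worn)
    tn <- tn + sum(use & !truly_off & w$worn)
    fp <- fp + sum(use & !truly_off & !w$worn)
    compl <- c(compl, res$compliance)
  }
  list(sensitivity = tp / max(tp + fn, 1),
       specificity = tn / max(tn + fp, 1),
       n_nonwear_segments = tp + fn, n_wear_segments = tn + fp,
       compliance = mean(compl, na.rm = TRUE))
}

#' Calibration recovery study
#'
#' Plants known per-axis gain and offset errors on one simulated
#' multi-day recording and measures how closely sphere-fit
#' autocalibration recovers them.
#'
#' @param offset_mg,gain planted per-axis values.
#' @param n_days recording length (days).
#' @param seed integer seed.
#' @return List: recovered model, `offset_err_mg` and `gain_err`
#'   (max absolute recovery errors), `n_still`.
#' @export
calibration_recovery_study <- function(offset_mg = c(30, -45, 15),
                                       gain = c(1.015, 0.985, 1.02),
                                       n_days = 2, seed = 1) {
  cfg <- sim_config(n_per_group = 1, n_days = n_days, seed = seed,
                    split_devices = FALSE)
  tr <- simulate_truths(cfg)$truths[[1]]
  tr$device_offset_mg[1, ] <- offset_mg
  tr$device_gain[1, ] <- gain
  rec <- simulate_recording(tr, cfg)
  cal <- autocalibrate(rec)
  list(model = cal,
       offset_err_mg = max(abs(cal$offset_mg - offset_mg)),
       gain_err = max(abs(cal$gain - gain)),
       n_still = cal$n_still, success = cal$success)
}

#' Partial-correlation recovery study (truth level)
#'
#' Repeatedly simulates participant-level ground truth (no raw signal)
#' and estimates the within-group partial correlation between true
#' daytime intensity and the IADL-like outcome, controlling for age,
#' BMI, IQ and sex, against the planted target.
#'
#' @param n_rep replicates.
#' @param n_per_group participants per arm.
#' @param seed base seed (replicate r uses `seed + r`).
#' @return List: `r` (matrix n_rep x 2, case and control estimates),
#'   `mean_r`, `target`.
#' @export
rho_recovery_study <- function(n_rep = 200, n_per_group = 29, seed = 1000) {
  target <- default_outcome_model()$iadl$rho
  r <- matrix(NA_real_, n_rep, 2,
              dimnames = list(NULL, c("case", "control")))
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_per_group = n_per_group, seed = seed + i)
    tb <- simulate_truths(cfg)
    d <- vapply(tb$truths, true_daytime_mean, 0)
    for (g in c("case", "control")) {
      sel <- tb$covariates$group == g
      r[i, g] <- partial_correlation(
        d[sel], tb$covariates$iadl[sel],
        tb$covariates[sel, c("age", "bmi", "iq", "sex")])$r
    }
  }
  list(r = r, mean_r = mean(r), target = target)
}

#' Null calibration of the group test (truth level)
#'
#' With zero morning attenuation the two arms share one intensity
#' distribution; the pipeline's residualized pooled t test on true
#' daytime means should then reject at its nominal rate.
#'
#' @param n_rep replicates.
#' @param n_per_group participants per arm.
#' @param alpha nominal level.
#' @param seed base seed.
#' @return List: `rejection_rate`, `alpha`, `n_rep`.
#' @export
null_calibration_study <- function(n_rep = 200, n_per_group = 29,
                                   alpha = 0.05, seed = 2000) {
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_per_group = n_per_group, morning_attenuation = 0,
                      seed = seed + i)
    tb <- simulate_truths(cfg)
    d <- vapply(tb$truths, true_daytime_mean, 0)
    adj <- residualize_confounds(d, tb$covariates[c("age", "bmi", "iq")])
    grp <- tb$covariates$group
    tt <- independent_ttest(adj[grp == "case"], adj[grp == "control"])
    rej[i] <- tt$p < alpha
  }
  list(rejection_rate = mean(rej), alpha = alpha, n_rep = n_rep)
}
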