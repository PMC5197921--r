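# Orchestration: per-participant processing chain, cohort assembly,
# configured runs with a manifest.

#' Process one participant's device recordings end to end
#'
#' Runs the per-participant chain: per-device autocalibration and
#' correction, changeover merging, 50 Hz resampling, band-passed
#' magnitude, wear classification, day qualification, minute features,
#' average-day profile and window means. A calibration failure or lack
#' of included days marks the participant excluded instead of aborting.
#'
#' @param recs list of one or two [raw_recording()]s (two = changeover
#'   pair, in chronological order).
#' @param malfunction logical malfunction flag for [qualify_days()].
#' @param params list of pipeline constants (see [pipeline_config()]);
#'   defaults used when omitted.
#' @return A `participant_result` list: `participant_id`, `status`
#'   ("ok" or an exclusion reason), `calibrations`, `days`, `minutes`,
#'   `profile`, `window_means`, `compliance`.
#' @export
process_participant <- function(recs, malfunction = FALSE, params = list()) {
  if (inherits(recs, "raw_recording")) recs <- list(recs)
  p <- modifyList(pipeline_defaults(), params)
  id <- recs[[1]]$participant_id
  res <- list(participant_id = id, status = "ok")

  calibs <- lapply(recs, function(r)
    autocalibrate(r, sd_threshold_mg = p$still_sd_mg,
                  window_s = p$still_window_s))
  res$calibrations <- calibs
  if (!all(vapply(calibs, function(m) isTRUE(m$success), TRUE))) {
    res$status <- "calibration_failure"
    return(structure(res, class = "participant_result"))
  }
  recs <- Map(apply_calibration, recs, calibs)
  rec <- if (length(recs) == 2)
    merge_changeover(recs[[1]], recs[[2]]) else recs[[1]]
  um <- uniform_magnitude(rec, rate_hz = p$rate_hz)
  rm(rec, recs)
  coefs <- bandpass_coefs(p$band_hz[1], p$band_hz[2], p$filter_order,
                          p$rate_hz)
  mag <- filter_magnitude(um$mag_mg, um$participant_id, um$t0,
                          um$rate_hz, coefs, p$edge_trim_s)
  rm(um)
  mask <- classify_wear(mag, sd_threshold_mg = p$wear_sd_mg,
                        segment_min = p$segment_min)
  days <- qualify_days(mask, calibs, malfunction = malfunction,
                       min_worn_min = p$min_worn_min)
  res$wear_mask <- mask
  res$days <- days
  res$compliance <- compliance(days)
  if (!any(days$included)) {
    res$status <- "no_included_days"
    return(structure(res, class = "participant_result"))
  }
  res$minutes <- minute_features(mag, mask, min_samples = p$min_minute_samples,
                                 features = p$features,
                                 entropy_bins = p$entropy_bins,
                                 entropy_range_mg = p$entropy_range_mg)
  res$profile <- average_day(res$minutes, days)
  res$window_means <- sapply(c("night", "daytime", "morning", "day24"),
                             function(w) segment_mean(res$profile, w))
  structure(res, class = "participant_result")
}

#' @export
print.participant_result <- function(x, ...) {
  cat(sprintf("<participant_result> %s: %s", x$participant_id, x$status))
  if (!is.null(x$days))
    cat(sprintf(" (%d/%d days included, compliance %.1f%%)",
                sum(x$days$included), nrow(x$days), 100 * x$compliance))
  cat("\n")
  invisible(x)
}

#' Assemble per-participant window means into a cohort table
#'
#' @param results list of `participant_result`s.
#' @param covariates cohort covariate table (for the group column).
#' @return Data frame: participant_id, group, then
#'   `<feature>.<window>` columns; excluded participants are omitted.
#' @export
cohort_window_means <- function(results, covariates) {
  rows <- lapply(results, function(r) {
    if (r$status != "ok") return(NULL)
    wm <- r$window_means
    vals <- as.list(as.vector(wm))
    names(vals) <- as.vector(outer(
      sub("_mg.*$|_bits$", "", rownames(wm)), colnames(wm), paste, sep = "."))
    cbind(data.frame(participant_id = r$participant_id,
                     stringsAsFactors = FALSE),
          as.data.frame(vals))
  })
  out <- do.call(rbind, rows)
  merge(covariates[c("participant_id", "group")], out,
        by = "participant_id", sort = TRUE)
}

pipeline_defaults <- function() {
  list(rate_hz = 50, band_hz = c(0.2, 15), filter_order = 4,
       edge_trim_s = 5, wear_sd_mg = 13, still_sd_mg = 13,
       still_window_s = 10, segment_min = 30, min_worn_min = 720,
       min_minute_samples = 1500, entropy_bins = 64,
       entropy_range_mg = c(-500, 500),
       features = c("activity", "jerk", "entropy"))
}

#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Every numeric constant
#' of the pipeline is surfaced with the standard value as default
#' (13 mg wear/still thresholds, 30 min segments, 50 Hz, 0.2-15 Hz
#' band, order 4, 64 entropy bins, 720 min half-day rule). Unknown
#' fields are rejected by name.
#'
#' @param simulation a [sim_config()] to generate the cohort, or NULL.
#' @param input_dir directory of raw recording files (used when
#'   `simulation` is NULL): one or two `<participant>_<device>.txt`
#'   files per participant plus `covariates.tsv`.
#' @param out_dir output directory for stage results and the manifest.
#' @param seed integer seed for the run (overrides the simulation
#'   config's seed so one flag controls reproducibility).
#' @param stages subset of `c("simulate", "preprocess", "wear",
#'   "features", "stats")`: outputs to produce (prerequisites always
#'   run in memory).
#' @param write_raw also write simulated raw recordings as text (large).
#' @param ... pipeline constants overriding `pipeline_defaults()`:
#'   `rate_hz`, `band_hz`, `filter_order`, `edge_trim_s`, `wear_sd_mg`,
#'   `still_sd_mg`, `still_window_s`, `segment_min`, `min_worn_min`,
#'   `min_minute_samples`, `entropy_bins`, `entropy_range_mg`,
#'   `features`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL,
                            out_dir = tempfile("wristpa_run_"),
                            seed = 1L,
                            stages = c("simulate", "preprocess", "wear",
                                       "features", "stats"),
                            write_raw = FALSE, ...) {
  dots <- list(...)
  unknown <- setdiff(names(dots), names(pipeline_defaults()))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(simulation) && is.null(input_dir))
    stopf("either a simulation block or an input directory is required")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    stopf("'simulation' must be a sim_config object")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stopf("input directory does not exist: %s", input_dir)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(simulation = simulation, input_dir = input_dir,
                 out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, write_raw = isTRUE(write_raw),
                 params = modifyList(pipeline_defaults(), dots)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain a nested `simulation:` block (passed to
#' [sim_config()]) plus any [pipeline_config()] field.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    sim <- y$simulation
    if (!is.null(sim$bump_params)) sim$bump_params <-
        as.data.frame(sim$bump_params)
    y$simulation <- do.call(sim_config, sim)
  }
  do.call(pipeline_config, y)
}

# Deterministic TSV writer: fixed C-locale scientific formatting so that
# identical runs are byte-identical across platforms.
write_tsv <- function(df, path, digits = 8) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) {
    v <- sprintf(paste0("%.", digits, "g"), df[[j]])
    v[is.na(df[[j]])] <- "NA"
    df[[j]] <- v
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  invisible(path)
}

#' Run the full pipeline as a configured, logged, reproducible job
#'
#' Simulates (or reads) the cohort, processes every participant,
#' assembles the cohort statistics and writes all stage outputs plus a
#' run manifest with md5 checksums. Identical configuration and seed
#' yield byte-identical outputs. Per-participant failures (e.g. a
#' calibration failure) are recorded and the participant excluded
#' without aborting the run.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings <- character()
  files <- character()

  truths <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    say("simulating cohort of %d participants", 2 * sim$n_per_group)
    tb <- simulate_truths(sim)
    covars <- tb$covariates
    truths <- tb$truths
    # recordings are generated one participant at a time inside the
    # processing loop so the whole cohort's raw signal never coexists
    ids <- vapply(truths, `[[`, "", "participant_id")
    recs_by_p <- NULL
  } else {
    say("reading raw recordings from %s", config$input_dir)
    cov_path <- file.path(config$input_dir, "covariates.tsv")
    if (!file.exists(cov_path)) stopf("missing input file: %s", cov_path)
    covars <- utils::read.table(cov_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    raw_files <- sort(list.files(config$input_dir, "^raw_.*\\.txt$",
                                 full.names = TRUE))
    if (!length(raw_files)) stopf("no raw_*.txt files in %s",
                                  config$input_dir)
    recs <- lapply(raw_files, read_raw_recording)
    ids <- vapply(recs, `[[`, "", "participant_id")
    recs_by_p <- split(recs, ids)
    recs_by_p <- lapply(recs_by_p, function(lst)
      lst[order(vapply(lst, function(r) as.numeric(r$start_time), 0))])
  }

  f <- file.path(config$out_dir, "covariates.tsv")
  write_tsv(covars, f); files <- c(files, f)

  if (is.null(truths)) ids <- names(recs_by_p)
  results <- vector("list", length(ids))
  names(results) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    results[[i]] <- tryCatch({
      recs <- if (is.null(truths)) recs_by_p[[i]] else
        simulate_participant_recordings(truths[[i]], sim)
      if (!is.null(truths) && config$write_raw &&
          "simulate" %in% config$stages) {
        for (r in recs) {
          f <- file.path(config$out_dir,
                         sprintf("raw_%s_%s.txt", r$participant_id,
                                 r$device_id))
          write_raw_recording(r, f); files <- c(files, f)
        }
      }
      out <- process_participant(recs, params = config$params)
      rm(recs)
      out
    }, error = function(e) {
      structure(list(participant_id = id,
                     status = paste0("error: ", conditionMessage(e))),
                class = "participant_result")
    })
    if (results[[i]]$status != "ok") {
      warnings <- c(warnings, sprintf("participant %s excluded: %s", id,
                                      results[[i]]$status))
      say("participant %s excluded (%s)", id, results[[i]]$status)
    }
  }

  if ("preprocess" %in% config$stages) {
    calrep <- do.call(rbind, lapply(results, function(r) {
      if (is.null(r$calibrations)) return(NULL)
      do.call(rbind, lapply(seq_along(r$calibrations), function(j) {
        m <- r$calibrations[[j]]
        data.frame(participant_id = r$participant_id, device = j,
                   gain_x = m$gain[1], gain_y = m$gain[2],
                   gain_z = m$gain[3],
                   offset_x_mg = m$offset_mg[1],
                   offset_y_mg = m$offset_mg[2],
                   offset_z_mg = m$offset_mg[3],
                   pre_error_mg = m$pre_error_mg,
                   post_error_mg = m$post_error_mg,
                   n_still = m$n_still, success = m$success,
                   stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(calrep)) {
      f <- file.path(config$out_dir, "calibration_report.tsv")
      write_tsv(calrep, f); files <- c(files, f)
    }
  }

  ledger <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$days)) return(NULL)
    cbind(participant_id = r$participant_id,
          r$days[c("date", "minutes_worn", "included", "exclusion_reason")])
  }))
  if (!is.null(ledger) && "wear" %in% config$stages) {
    ledger$date <- as.character(ledger$date)
    f <- file.path(config$out_dir, "day_ledger.tsv")
    write_tsv(ledger, f); files <- c(files, f)
    mask <- do.call(rbind, lapply(results, function(r) {
      if (is.null(r$wear_mask)) return(NULL)
      cbind(participant_id = r$participant_id,
            as.data.frame(r$wear_mask))
    }))
    if (!is.null(mask)) {
      mask$date <- as.character(mask$date)
      f <- file.path(config$out_dir, "wear_mask.tsv")
      write_tsv(mask, f); files <- c(files, f)
    }
  }

  if ("features" %in% config$stages) {
    prof <- do.call(rbind, lapply(results, function(r) {
      if (r$status != "ok") return(NULL)
      cbind(participant_id = r$participant_id, as.data.frame(r$profile))
    }))
    if (!is.null(prof)) {
      f <- file.path(config$out_dir, "average_day_profiles.tsv")
      write_tsv(prof, f); files <- c(files, f)
    }
  }

  wm <- cohort_window_means(results, covars)
  stats_out <- NULL
  if ("stats" %in% config$stages && !is.null(wm) && nrow(wm) >= 4 &&
      length(unique(wm$group)) == 2) {
    f <- file.path(config$out_dir, "window_means.tsv")
    write_tsv(wm, f); files <- c(files, f)
    stats_out <- tryCatch(cohort_stats(wm, covars), error = function(e) {
      warnings <<- c(warnings, paste0("statistics stage skipped: ",
                                      conditionMessage(e)))
      NULL
    })
    if (!is.null(stats_out)) {
      f <- file.path(config$out_dir, "group_tests.tsv")
      write_tsv(stats_out$group_tests, f); files <- c(files, f)
      f <- file.path(config$out_dir, "correlations.tsv")
      write_tsv(stats_out$correlations, f); files <- c(files, f)
    }
  }

  manifest <- list(
    package = "wristpa",
    version = as.character(utils::packageVersion("wristpa")),
    schema_version = 1L,
    seed = config$seed,
    stages = config$stages,
    params = config$params,
    n_participants = length(results),
    n_ok = sum(vapply(results, function(r) r$status == "ok", TRUE)),
    statuses = vapply(results, `[[`, "", "status"),
    compliance = vapply(results, function(r) r$compliance %||% NA_real_, 0),
    warnings = warnings,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("run complete: %d/%d participants processed", manifest$n_ok,
      manifest$n_participants)
  invisible(c(manifest, list(results = results, window_means = wm,
                             stats = stats_out)))
}
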