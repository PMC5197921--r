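# Statistical layer: confound residualization, pooled two-sample t
# tests, partial correlations with clinical variables, and
# control-referenced neuropsychological Z composites.

#' Remove linear confound effects from participant-level measures
#'
#' Ordinary least squares of each measure on an intercept plus the
#' confounds, pooled across groups; the residuals plus the grand mean of
#' the measure are returned, so confound slopes are removed while group
#' contrasts are preserved.
#'
#' @param values numeric vector (or matrix, column-wise) of
#'   participant-level measures.
#' @param confounds data frame of numeric confounds (e.g. age, BMI,
#'   pre-morbid IQ), no missing values.
#' @return Adjusted values, same shape as `values`.
#' @export
residualize_confounds <- function(values, confounds) {
  confounds <- as.data.frame(confounds)
  if (anyNA(confounds)) stopf("confounds contain missing values")
  X <- cbind(`(Intercept)` = 1, as.matrix(confounds))
  if (!is.numeric(X)) stopf("confounds must be numeric")
  v <- as.matrix(values)
  if (nrow(v) != nrow(X)) stopf("values and confounds have different lengths")
  if (nrow(X) < ncol(X) + 1)
    stopf("need at least %d participants for %d confounds",
          ncol(X) + 1, ncol(X) - 1)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop_cols <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("confound matrix is rank deficient; collinear column(s): %s",
          paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm.fit(X, v)
  out <- fit$residuals + matrix(colMeans(v), nrow(v), ncol(v), byrow = TRUE)
  if (is.matrix(values)) out else drop(out)
}

#' Pooled-variance two-sample t test
#'
#' Classical two-tailed independent t test with pooled variance and
#' `n1 + n2 - 2` degrees of freedom (the convention implied by the
#' study-style df reporting; not the Welch test).
#'
#' @param x,y numeric vectors, the two groups' values.
#' @return A `wpa_ttest`: `t`, `df`, `p`, `mean_diff` (mean(x) -
#'   mean(y)), `n1`, `n2`.
#' @export
independent_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stopf("both groups need at least 2 observations")
  if (stats::var(x) + stats::var(y) == 0)
    stopf("zero pooled variance: t statistic undefined")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(x) - mean(y),
                 n1 = length(x), n2 = length(y)),
            class = "wpa_ttest")
}

#' @export
print.wpa_ttest <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (mean diff %.3f; n = %d/%d)\n",
              x$df, x$t, x$p, x$mean_diff, x$n1, x$n2))
  invisible(x)
}

#' Partial correlation controlling for confounds
#'
#' Pearson correlation of the residuals of `x` and of `y` after
#' ordinary least squares on an intercept plus the confounds. With an
#' empty confound set this reduces to the plain Pearson correlation.
#' Incomplete observations are dropped listwise and the effective n is
#' reported. The p value is two-tailed from
#' `t = r * sqrt((n - k - 2) / (1 - r^2))` on `n - k - 2` df with k
#' confounds.
#'
#' @param x,y numeric vectors.
#' @param confounds optional data frame of numeric confounds.
#' @return A `wpa_pcor`: `r`, `p`, `n`, `df`, `controlled` (confound
#'   names), `degenerate` (TRUE when a residual variance vanished).
#' @export
partial_correlation <- function(x, y, confounds = NULL) {
  if (is.null(confounds) || !length(confounds))
    confounds <- data.frame(row.names = seq_along(x))
  confounds <- as.data.frame(confounds)
  k <- ncol(confounds)
  keep <- if (k > 0) stats::complete.cases(x, y, confounds) else
    stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  confounds <- confounds[keep, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2)
    stopf("need more than %d complete observations for %d confounds",
          k + 2, k)
  if (k > 0) {
    X <- cbind(1, as.matrix(confounds))
    rx <- stats::lm.fit(X, x)$residuals
    ry <- stats::lm.fit(X, y)$residuals
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  # zero residual variance up to numerical noise from the OLS projection
  degenerate <- stats::sd(rx) <= 1e-10 * max(1, stats::sd(x)) ||
    stats::sd(ry) <= 1e-10 * max(1, stats::sd(y))
  if (degenerate) {
    r <- NA_real_; p <- NA_real_
  } else {
    r <- stats::cor(rx, ry)
    tstat <- r * sqrt((n - k - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - k - 2)
  }
  structure(list(r = r, p = p, n = n, df = n - k - 2,
                 controlled = names(confounds), degenerate = degenerate),
            class = "wpa_pcor")
}

#' @export
print.wpa_pcor <- function(x, ...) {
  ctrl <- if (length(x$controlled))
    paste(x$controlled, collapse = ", ") else "none"
  cat(sprintf("partial r = %.3f, p = %.4g, n = %d (controlling: %s)%s\n",
              x$r, x$p, x$n, ctrl,
              if (x$degenerate) " [degenerate: zero residual variance]"
              else ""))
  invisible(x)
}

#' Control-referenced neuropsychological Z composites
#'
#' Standardizes each patient's raw test score against the control
#' group: `z = direction * (x - mean_ctrl) / sd_ctrl`, where
#' `direction = -1` for lower-is-better scores (times, error counts)
#' aligns every test to "higher = better". Missing raw scores are
#' imputed with the respective group's mean before standardization.
#' Domain scores are the mean of their tests' z; the grand mean z
#' averages over all tests.
#'
#' @param patient_scores,control_scores data frames of raw test scores
#'   (columns = tests, rows = participants).
#' @param domain_map named list mapping domain name to the character
#'   vector of its test columns; defaults to [default_domain_map()].
#' @param direction_map named numeric vector of +1/-1 per test;
#'   defaults to the directions in [default_domain_map()].
#' @return A `domain_zscores` list: `z` (per-test patient z matrix),
#'   `domains` (patients x domains), `grand_mean` (per patient),
#'   `control_reference` (per-test mean/sd used).
#' @export
z_composites <- function(patient_scores, control_scores,
                         domain_map = default_domain_map()$domains,
                         direction_map = default_domain_map()$directions) {
  tests <- unique(unlist(domain_map))
  missing_cols <- setdiff(tests, intersect(colnames(patient_scores),
                                           colnames(control_scores)))
  if (length(missing_cols))
    stopf("test column(s) absent from scores: %s",
          paste(missing_cols, collapse = ", "))
  impute <- function(df) {
    for (tn in tests) {
      v <- df[[tn]]
      if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
      df[[tn]] <- v
    }
    df
  }
  pat <- impute(as.data.frame(patient_scores))
  ctl <- impute(as.data.frame(control_scores))
  mu <- vapply(tests, function(tn) mean(ctl[[tn]]), 0)
  sigma <- vapply(tests, function(tn) stats::sd(ctl[[tn]]), 0)
  if (any(sigma == 0))
    stopf("zero control-group SD for test(s): %s",
          paste(tests[sigma == 0], collapse = ", "))
  dirs <- direction_map[tests]
  if (anyNA(dirs)) stopf("direction missing for test(s): %s",
                         paste(tests[is.na(dirs)], collapse = ", "))
  z <- sapply(tests, function(tn)
    dirs[[tn]] * (pat[[tn]] - mu[[tn]]) / sigma[[tn]])
  z <- matrix(z, nrow = nrow(pat),
              dimnames = list(rownames(pat), tests))
  domains <- sapply(names(domain_map), function(dn)
    rowMeans(z[, domain_map[[dn]], drop = FALSE]))
  domains <- matrix(domains, nrow = nrow(pat),
                    dimnames = list(rownames(pat), names(domain_map)))
  structure(list(z = z, domains = domains, grand_mean = rowMeans(z),
                 control_reference = data.frame(test = tests, mean = mu,
                                                sd = sigma,
                                                direction = unname(dirs))),
            class = "domain_zscores")
}

#' Default neuropsychological domain map
#'
#' The five conceptual domains and score orientations used for the Z
#' composites: executive/working memory, attention & psychomotor speed,
#' short-term memory, general memory, and emotional processing. Tests
#' recorded as times, latencies or error counts carry direction -1
#' (lower raw score = better performance).
#'
#' @return List with `domains` (named list of test vectors) and
#'   `directions` (named +1/-1 vector).
#' @export
default_domain_map <- function() {
  domains <- list(
    executive_working_memory = c("fas_total", "ds_backward",
                                 "swm_between_errors"),
    attention_psychomotor = c("trails_a_time", "dsst_time"),
    short_term_memory = c("ds_forward", "ssp_span"),
    general_memory = c("ravl_total", "ravl_delayed", "pal_errors",
                       "rmbt_profile"),
    emotional_processing = c("agn_latency", "fert_correct_ratio"))
  directions <- c(fas_total = 1, ds_backward = 1, swm_between_errors = -1,
                  trails_a_time = -1, dsst_time = -1, ds_forward = 1,
                  ssp_span = 1, ravl_total = 1, ravl_delayed = 1,
                  pal_errors = -1, rmbt_profile = 1, agn_latency = -1,
                  fert_correct_ratio = 1)
  list(domains = domains, directions = directions)
}

#' Group tests and partial correlations over a cohort's window means
#'
#' Convenience layer over the per-participant profiles: residualizes
#' each feature/window mean on the confounds (pooled across groups) and
#' runs the pooled t test case vs control; separately computes
#' within-group partial correlations between window means and clinical
#' outcome columns, controlling for age, BMI, IQ and sex.
#'
#' @param window_means data frame with one row per participant:
#'   `participant_id`, `group` plus `<feature>.<window>` columns (as
#'   produced by [run_pipeline()] / [cohort_window_means()]).
#' @param covariates cohort covariate table (participant_id, group,
#'   age, sex, bmi, iq, outcome columns).
#' @param confounds confound columns for the t tests.
#' @param cor_confounds confound columns for the partial correlations.
#' @param outcomes outcome columns to correlate.
#' @return List with `group_tests` and `correlations` data frames.
#' @export
cohort_stats <- function(window_means, covariates,
                         confounds = c("age", "bmi", "iq"),
                         cor_confounds = c("age", "bmi", "iq", "sex"),
                         outcomes = c("iadl", "sf36", "pal", "madrs")) {
  stopifnot(all(c("participant_id", "group") %in% names(window_means)))
  dat <- merge(window_means, covariates, by = c("participant_id", "group"),
               sort = FALSE)
  value_cols <- setdiff(names(window_means), c("participant_id", "group"))
  grp <- dat$group
  gt <- do.call(rbind, lapply(value_cols, function(cl) {
    adj <- residualize_confounds(dat[[cl]], dat[confounds])
    tt <- independent_ttest(adj[grp == "case"], adj[grp == "control"])
    data.frame(measure = cl, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = tt$mean_diff, n_case = tt$n1,
               n_control = tt$n2, stringsAsFactors = FALSE)
  }))
  outcomes <- intersect(outcomes, names(dat))
  cors <- do.call(rbind, lapply(value_cols, function(cl) {
    do.call(rbind, lapply(outcomes, function(oc) {
      do.call(rbind, lapply(c("case", "control"), function(g) {
        sel <- grp == g
        pc <- tryCatch(
          partial_correlation(dat[[cl]][sel], dat[[oc]][sel],
                              dat[sel, cor_confounds]),
          error = function(e) list(r = NA_real_, p = NA_real_,
                                   n = sum(sel)))
        data.frame(measure = cl, outcome = oc, group = g, r = pc$r,
                   p = pc$p, n = pc$n, stringsAsFactors = FALSE)
      }))
    }))
  }))
  list(group_tests = gt, correlations = cors)
}
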