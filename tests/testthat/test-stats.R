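# Residualization, pooled t tests, partial correlations, Z composites.

test_that("residualization removes confound slopes and nothing else", {
  set.seed(40)
  n <- 60
  conf <- data.frame(age = rnorm(n, 74, 6), bmi = rnorm(n, 26, 4),
                     iq = rnorm(n, 112, 8))
  # a measure orthogonal to the confounds passes through unchanged
  y <- rnorm(n)
  X <- cbind(1, as.matrix(conf))
  y_orth <- stats::lm.fit(X, y)$residuals + 5
  expect_equal(residualize_confounds(y_orth, conf), y_orth,
               tolerance = 1e-10)
  # residual orthogonality for any measure
  adj <- residualize_confounds(rnorm(n, 0, 2) + 2 * conf$age, conf)
  slopes <- stats::coef(stats::lm(adj ~ age + bmi + iq, data = conf))[-1]
  expect_lt(max(abs(slopes)), 1e-10)
  # grand mean is preserved
  y2 <- rnorm(n, 10)
  expect_equal(mean(residualize_confounds(y2, conf)), mean(y2))
  # rank deficiency is reported with the offending column
  conf$age2 <- conf$age * 2
  expect_error(residualize_confounds(y, conf), "age2")
})

test_that("planted linear confounding is removed, leaving the planted
           group effect", {
  set.seed(41)
  n <- 200
  grp <- rep(c("case", "control"), each = n / 2)
  age <- rnorm(n, 74, 6) + (grp == "case") * 3
  measure <- 2 * age + (grp == "control") * 5 + rnorm(n, 0, 1)
  adj <- residualize_confounds(measure, data.frame(age = age))
  diff_adj <- mean(adj[grp == "control"]) - mean(adj[grp == "case"])
  # raw difference is distorted by ~2*3 = 6 units of confounding
  expect_lt(abs(diff_adj - 5), 1)
})

test_that("group t test on residualized measures ignores any linear
           function of the confounds added to the measure", {
  set.seed(42)
  n <- 80
  grp <- rep(c("case", "control"), each = n / 2)
  conf <- data.frame(age = rnorm(n, 74, 6), bmi = rnorm(n, 26, 4))
  y <- rnorm(n) + (grp == "case") * 1.2
  t1 <- independent_ttest(
    residualize_confounds(y, conf)[grp == "case"],
    residualize_confounds(y, conf)[grp == "control"])
  y2 <- y + 0.7 * conf$age - 2 * conf$bmi
  t2 <- independent_ttest(
    residualize_confounds(y2, conf)[grp == "case"],
    residualize_confounds(y2, conf)[grp == "control"])
  expect_equal(t1$t, t2$t, tolerance = 1e-10)
})

test_that("the pooled t test matches its closed form", {
  r <- independent_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / (1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$mean_diff, -3)

  same <- independent_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(independent_ttest(c(1, 1, 1), c(1, 1, 1)), "variance")
  expect_error(independent_ttest(1, c(1, 2)), "at least 2")
})

test_that("partial correlation equals brute-force double residualization
           and an independent precision-matrix route", {
  set.seed(43)
  n <- 120
  conf <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  x <- rnorm(n) + conf$a - 0.5 * conf$c
  y <- 0.4 * x + rnorm(n) + 0.8 * conf$b
  pc <- partial_correlation(x, y, conf)

  X <- cbind(1, as.matrix(conf))
  r_ref <- stats::cor(stats::lm.fit(X, x)$residuals,
                      stats::lm.fit(X, y)$residuals)
  expect_equal(pc$r, r_ref, tolerance = 1e-10)

  # independent route: inverse of the joint correlation matrix
  P <- solve(stats::cor(cbind(x, y, conf)))
  r_prec <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(pc$r, r_prec, tolerance = 1e-10)

  # p value from the t transform
  tstat <- pc$r * sqrt((n - 4 - 2) / (1 - pc$r^2))
  expect_equal(pc$p, 2 * stats::pt(-abs(tstat), n - 6), tolerance = 1e-12)

  # no confounds reduces to plain Pearson
  pc0 <- partial_correlation(x, y)
  expect_equal(pc0$r, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p, stats::cor.test(x, y)$p.value, tolerance = 1e-9)

  # degenerate: y an exact linear function of the confounds
  y_lin <- 2 + conf$a - 3 * conf$d
  pcd <- partial_correlation(x, y_lin, conf)
  expect_true(pcd$degenerate)
  expect_true(is.na(pcd$r))

  # listwise deletion reports the effective n
  x2 <- x; x2[1:5] <- NA
  expect_equal(partial_correlation(x2, y, conf)$n, n - 5)

  expect_error(partial_correlation(x[1:5], y[1:5], conf[1:5, ]), "complete")
})

test_that("Z composites standardize against controls with direction
           alignment, imputation and domain averaging", {
  set.seed(44)
  dm <- list(speed = c("trails_a_time", "dsst_time"),
             memory = c("ravl_total"))
  dirs <- c(trails_a_time = -1, dsst_time = -1, ravl_total = 1)
  ctl <- data.frame(trails_a_time = rnorm(30, 40, 8),
                    dsst_time = rnorm(30, 120, 20),
                    ravl_total = rnorm(30, 45, 6))
  pat <- data.frame(trails_a_time = c(mean(ctl$trails_a_time), 50),
                    dsst_time = c(mean(ctl$dsst_time), 150),
                    ravl_total = c(mean(ctl$ravl_total), NA))
  z <- z_composites(pat, ctl, dm, dirs)
  # patient at the control mean scores 0 everywhere
  expect_equal(unname(z$z[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(z$grand_mean[1]), 0, tolerance = 1e-12)
  # slower times produce negative z (direction -1)
  expect_lt(z$z[2, "trails_a_time"], 0)
  # missing patient value imputed with the patient-group mean
  expect_equal(z$z[2, "ravl_total"],
               unname((mean(pat$ravl_total, na.rm = TRUE) -
                         mean(ctl$ravl_total)) / stats::sd(ctl$ravl_total)))
  # domain = mean of its tests
  expect_equal(unname(z$domains[2, "speed"]),
               mean(z$z[2, c("trails_a_time", "dsst_time")]))

  # controls standardized against themselves: mean 0, sd 1 per test
  zc <- z_composites(ctl, ctl, dm, dirs)
  expect_equal(unname(colMeans(zc$z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zc$z, 2, stats::sd)), c(1, 1, 1),
               tolerance = 1e-12)

  # arithmetic: two-test domain with z = 1 and -0.5 averages to 0.25
  dm1 <- list(dom = c("t1", "t2"))
  d1 <- c(t1 = 1, t2 = 1)
  ctl2 <- data.frame(t1 = c(-1, 1, 0, 0), t2 = c(0, 0, -2, 2))
  sd1 <- stats::sd(ctl2$t1); sd2 <- stats::sd(ctl2$t2)
  p2 <- data.frame(t1 = 1 * sd1, t2 = -0.5 * sd2)
  z2 <- z_composites(p2, ctl2, dm1, d1)
  expect_equal(unname(z2$domains[1, "dom"]), 0.25, tolerance = 1e-12)

  # zero control SD is an error naming the test
  ctl3 <- ctl; ctl3$dsst_time <- 100
  expect_error(z_composites(pat, ctl3, dm, dirs), "dsst_time")

  # default domain map covers all its directions
  dmap <- default_domain_map()
  expect_setequal(unlist(dmap$domains), names(dmap$directions))
})

test_that("cohort_stats produces the group-test and correlation tables", {
  set.seed(45)
  cfg <- sim_config(n_per_group = 20, seed = 9)
  tb <- simulate_truths(cfg)
  d <- vapply(tb$truths, true_daytime_mean, 0)
  wm <- data.frame(participant_id = tb$covariates$participant_id,
                   group = tb$covariates$group,
                   activity.daytime = d * sqrt(2 / pi))
  out <- cohort_stats(wm, tb$covariates)
  expect_equal(nrow(out$group_tests), 1)
  expect_equal(out$group_tests$df, 38)
  expect_lt(out$group_tests$t, 0)     # cases move less
  expect_equal(nrow(out$correlations), 1 * 4 * 2)
  r_iadl <- out$correlations$r[out$correlations$outcome == "iadl"]
  expect_true(all(r_iadl > 0))
})
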