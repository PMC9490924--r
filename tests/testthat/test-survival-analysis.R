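test_that("kaplan-meier reproduces hand-computed product limits", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2 removes a subject from later risk sets
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # no events: flat survival
  km3 <- kaplan_meier(c(5, 6), c(0, 0))
  expect_true(all(km3$surv == 1))
  # no censoring: matches the empirical survival function
  set.seed(8)
  tt <- rexp(30)
  km4 <- kaplan_meier(tt, rep(1, 30))
  expect_equal(km4$surv, 1 - seq_len(30) / 30)
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test is symmetric, null on duplicated groups and
           matches the hypergeometric oracle", {
  d <- toy_survival(2, n = 20)
  g <- rep(c("a", "b"), 10)
  # duplicated data in both groups: statistic 0
  same <- logrank_test(rep(c("a", "b"), each = 20),
                       rep(d$time, 2), rep(d$event, 2))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  lr1 <- logrank_test(g, d$time, d$event)
  expect_equal(logrank_test(ifelse(g == "a", "b", "a"), d$time,
                            d$event)$statistic,
               lr1$statistic, tolerance = 1e-12)

  # 6-subject toy set against the oracle z^2
  x <- c(0, 0, 0, 1, 1, 1)
  tt <- c(2, 4, 6, 1, 3, 5); ev <- c(1, 1, 0, 1, 0, 1)
  z <- oracle_logrank_z(x, tt, ev, 0.5)
  expect_equal(logrank_test(x, tt, ev)$statistic, z^2, tolerance = 1e-9)

  expect_error(logrank_test(rep("a", 5), 1:5, rep(1, 5)), "two")
  expect_error(logrank_test(g, d$time, rep(0, 20)), "events")
})

test_that("maxstat cutpoint equals the exhaustive scan oracle", {
  # perfect separation trend: feature equals the survival-time rank
  tt <- 1:20 + 0.5; ev <- rep(1, 20)
  x <- rank(tt)
  cp <- maxstat_cutpoint(x, tt, ev, p_method = "none")
  ora <- oracle_maxstat(x, tt, ev)
  expect_equal(cp$cutoff, ora$cutoff)
  expect_equal(cp$statistic, ora$statistic, tolerance = 1e-9)

  for (seed in 1:10) {
    d <- toy_survival(seed, n = 35)
    set.seed(seed + 100)
    x <- round(rnorm(35), 2)
    cp <- maxstat_cutpoint(x, d$time, d$event, p_method = "none")
    ora <- oracle_maxstat(x, d$time, d$event)
    expect_equal(cp$cutoff, ora$cutoff)
    expect_equal(cp$statistic, ora$statistic, tolerance = 1e-9)
    expect_gte(cp$n_low, 0.1 * 35 - 1)
    expect_gte(cp$n_high, 0.1 * 35 - 1)
  }
  expect_error(maxstat_cutpoint(rep(1, 10), 1:10, rep(1, 10)), "constant")
  expect_error(maxstat_cutpoint(c(rep(0, 19), 1), 1:20, rep(1, 20),
                                minprop = 0.1),
               "minprop")
})

test_that("maxstat permutation p is deterministic under seed and detects
           strong separation", {
  d <- toy_survival(5, n = 40)
  x <- rank(d$time) + rnorm(40, sd = 1e-3)
  p1 <- maxstat_cutpoint(x, d$time, d$event, n_perm = 99, seed = 11)$p_value
  p2 <- maxstat_cutpoint(x, d$time, d$event, n_perm = 99, seed = 11)$p_value
  expect_identical(p1, p2)
  expect_lte(p1, 0.05)
})

test_that("benjamini-hochberg step-up matches the direct formula and the
           brute-force oracle", {
  res <- benjamini_hochberg(c(0.005, 0.012, 0.9), q = 0.1, m = 3)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE))
  expect_equal(res$table$critical, c(1, 2, 3) * 0.1 / 3)

  expect_false(any(benjamini_hochberg(rep(1, 5), q = 0.1)$reject))

  # the step-up property: a large p can drag smaller ones into rejection
  res2 <- benjamini_hochberg(c(0.01, 0.02, 0.03), q = 0.1, m = 3)
  expect_true(all(res2$reject))

  set.seed(9)
  for (i in 1:20) {
    p <- runif(15)^2
    m <- sample(15:20, 1)
    expect_equal(benjamini_hochberg(p, q = 0.1, m = m)$reject,
                 oracle_bh(p, 0.1, m))
  }
  # m = 15 family at q = 0.1: critical values r/150
  res15 <- benjamini_hochberg(runif(15), q = 0.1, m = 15)
  expect_equal(res15$table$critical, (1:15) / 150)
  expect_error(benjamini_hochberg(c(0.5), q = 1.5), "q")
  expect_error(benjamini_hochberg(c(2)), "\\[0, 1\\]")
})

test_that("binarization is strict and consistent with cutpoint group sizes", {
  f <- data.frame(a = c(1, 2, 3, 4), b = c(0.5, 0.5, 0.7, NA))
  out <- binarize_features(f, c(a = 2, b = 0.6))
  expect_equal(out$a_high, c(0L, 0L, 1L, 1L))  # value == cutoff -> low
  expect_equal(out$b_high, c(0L, 0L, 1L, NA))
  expect_error(binarize_features(f, c(zz = 1)), "lack")

  d <- toy_survival(3, n = 30)
  set.seed(33); x <- rnorm(30)
  cp <- maxstat_cutpoint(x, d$time, d$event, p_method = "none")
  ind <- binarize_features(data.frame(x = x), c(x = cp$cutoff))$x_high
  expect_equal(sum(ind == 1), cp$n_high)
  expect_equal(sum(ind == 0), cp$n_low)
})

test_that("cox fit maximizes the efron partial likelihood and reports
           hazard ratios with basal levels", {
  # 8-subject toy data vs a 1-D grid search of the oracle likelihood
  x <- c(0, 1, 0, 1, 1, 0, 0, 1)
  tt <- c(5, 1, 6, 2, 2, 8, 3, 9)   # includes a tied event time
  ev <- c(1, 1, 0, 1, 1, 1, 1, 0)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  expect_false(fit$separation)
  grid <- seq(-3, 5, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, times = tt,
               events = ev)
  expect_equal(fit$coefficients$coef, grid[which.max(ll)], tolerance = 2e-4)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))

  # a perfectly ordering covariate is flagged as (near-)separation
  sep <- cox_fit(data.frame(x = -(1:30)), 1:30 + 0.5, rep(1, 30))
  expect_true(sep$separation)

  # score identity: the fit's score at beta = 0 equals the analytic
  # (numeric) gradient of the oracle partial likelihood there
  eps <- 1e-6
  score0 <- (oracle_cox_loglik(eps, x, tt, ev) -
             oracle_cox_loglik(-eps, x, tt, ev)) / (2 * eps)
  fit0 <- survival::coxph(survival::Surv(tt, ev) ~ x, init = 0,
                          control = survival::coxph.control(iter.max = 0))
  expect_equal(sum(stats::residuals(fit0, type = "score")), score0,
               tolerance = 1e-6)

  # categorical covariates expose basal levels with HR exactly 1
  d <- gen_cohort(sim_config(seed = 21, n_patients = 150))
  fit2 <- cox_fit(d[c("smoking", "stage", "age_group")], d$time, d$event)
  expect_setequal(fit2$basal$variable, c("smoking", "stage"))
  expect_true(all(fit2$basal$hr == 1))
  expect_setequal(fit2$basal$level, c("non_smoker", "early"))

  # zero-variance covariate dropped with warning
  expect_warning(
    cox_fit(data.frame(x = x, const = 1), tt, ev), "zero-variance")
  expect_error(cox_fit(data.frame(x = x), tt, rep(0, 8)), "event")
})

test_that("concordance index matches pair enumeration and its invariances", {
  tt <- c(2, 4, 6, 8, 10); ev <- c(1, 1, 0, 1, 1)
  risk <- c(0.9, 0.1, 0.5, 0.5, 0.2)
  expect_equal(concordance_index(risk, tt, ev),
               oracle_cindex(risk, tt, ev))
  # perfect ordering and pure ties
  expect_equal(concordance_index(-tt, tt, rep(1, 5)), 1)
  expect_equal(concordance_index(rep(1, 5), tt, rep(1, 5)), 0.5)
  # invariant under strictly monotone transforms
  expect_equal(concordance_index(exp(3 * risk), tt, ev),
               concordance_index(risk, tt, ev))
  set.seed(12)
  for (i in 1:10) {
    d <- toy_survival(i + 40, n = 25)
    r <- rnorm(25)
    expect_equal(concordance_index(r, d$time, d$event),
                 oracle_cindex(r, d$time, d$event))
  }
})

test_that("cross-validated c-index is perfect for a perfectly predictive
           feature and near 0.5 for noise", {
  # deterministic hazard ordering, no censoring
  n <- 120
  set.seed(51)
  d0 <- gen_cohort(sim_config(seed = 51, n_patients = n, censor_frac = 0))
  d0$time <- rank(-d0$t_necrosis) + runif(n, 0, 0.1)  # risk = -time exactly
  d0$event <- 1L
  # expose the perfectly ranking feature through the ITLR slot
  d0$itlr <- d0$t_necrosis
  cv1 <- cv_cindex(d0, "clinical+ITLR", k = 5, seed = 1)
  expect_gte(cv1$median_cindex, 0.99)

  # pure noise features: c-index near 1/2
  d1 <- gen_cohort(sim_config(seed = 52, n_patients = 500))
  cvn <- cv_cindex(d1, "clinical+TIP", k = 10, seed = 2)
  expect_gte(cvn$median_cindex, 0.4)
  expect_lte(cvn$median_cindex, 0.6)
  expect_length(cvn$fold_cindex, 10L)
  # reproducible fold assignment
  expect_equal(cv_cindex(d1, "clinical+TIP", k = 10, seed = 2), cvn)
})

test_that("the survival screen returns one calibrated row per feature", {
  cfg <- sim_config(seed = 61, n_patients = 120, prevalence_dispersion = 0.5,
                    cox_betas = c(t_necrosis = 2))
  d <- gen_cohort(cfg)
  scr <- survival_feature_screen(d, features = c("t_necrosis", "t_immune"),
                                 n_perm = 99, seed = 5)
  expect_equal(scr$feature, c("t_necrosis", "t_immune"))
  expect_true(all(scr$perm_p >= 0 & scr$perm_p <= 1))
  expect_true(all(scr$cutoff > min(d$t_necrosis)))
  # the driven feature is the more significant one
  expect_lte(scr$logrank_p[1], scr$logrank_p[2])
})
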