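test_that("curve cleanup is idempotent, isotonic, and anchors s(0) = 1", {
  clean <- data.frame(t = c(0, 1, 2), s = c(1, 0.8, 0.6))
  expect_equal(as.data.frame(clean_curve(clean)), clean)

  jitter <- clean_curve(data.frame(t = c(0, 1, 2, 3), s = c(1, 0.81, 0.82, 0.6)))
  expect_true(all(diff(jitter$s) <= 0))

  no_zero <- clean_curve(data.frame(t = c(1, 2), s = c(0.9, 0.7)))
  expect_equal(no_zero$t[1], 0)
  expect_equal(no_zero$s[1], 1)

  dup <- clean_curve(data.frame(t = c(0, 1, 1, 2), s = c(1, 0.9, 0.85, 0.7)))
  expect_equal(nrow(dup), 3)
  expect_equal(dup$s[dup$t == 1], 0.85)

  expect_error(clean_curve(data.frame(t = 0, s = 1)),
               class = "alk_validation_error")
  expect_error(clean_curve(data.frame(t = c(-1, 2), s = c(1, 0.5))),
               class = "alk_validation_error")
})

test_that("interval reconstruction applies the survival-ratio event formula", {
  # 10 at risk, survival 1.0 -> 0.8, 8 left at risk: 2 events, 0 censored
  iv <- reconstruct_intervals(
    data.frame(t = c(0, 1), s = c(1, 0.8)),
    at_risk = data.frame(t = c(0, 1), n_risk = c(10, 8))
  )
  expect_equal(iv$d[1], 2L)
  expect_equal(iv$c[1], 0L)

  # flat curve with attrition 10 -> 6: all censoring
  flat <- reconstruct_intervals(
    data.frame(t = c(0, 3), s = c(1, 1)),
    at_risk = data.frame(t = c(0, 3), n_risk = c(10, 6))
  )
  expect_equal(flat$d[1], 0L)
  expect_equal(flat$c[1], 4L)

  # count conservation holds on every interval
  sim <- simulate_survival_trial(c(a = 0.08), sim_config(seed = 2, n_per_arm = 150))
  ivs <- reconstruct_intervals(sim$curves[, c("t", "s")],
                               at_risk = sim$at_risk[, c("t", "n_risk")])
  expect_equal(ivs$n_end, ivs$n_start - ivs$d - ivs$c)

  expect_error(
    reconstruct_intervals(data.frame(t = c(0, 1, 2), s = c(1, 0, 0)),
                          at_risk = data.frame(t = c(0, 1, 2),
                                               n_risk = c(10, 5, 5))),
    class = "alk_validation_error"
  )
})

test_that("reconstruction recovers simulated event counts", {
  # sparse published-style at-risk tables: small error
  rel_err <- vapply(1:5, function(s) {
    sim <- simulate_survival_trial(c(a = log(2) / 9),
                                   cfg = sim_config(seed = s, n_per_arm = 200,
                                                    censoring_rate = 0.1,
                                                    follow_up = 30))
    iv <- reconstruct_intervals(sim$curves[, c("t", "s")],
                                at_risk = sim$at_risk[, c("t", "n_risk")])
    (sum(iv$d) - sum(sim$ipd$event)) / sum(sim$ipd$event)
  }, numeric(1))
  expect_lt(max(abs(rel_err)), 0.05)

  # without at-risk tables the error grows to roughly the hidden dropout
  # fraction (the documented bias of the zero-censoring assumption)
  rel_err0 <- vapply(1:5, function(s) {
    sim <- simulate_survival_trial(c(a = log(2) / 9),
                                   cfg = sim_config(seed = s, n_per_arm = 200,
                                                    censoring_rate = 0.1,
                                                    follow_up = 30))
    iv <- reconstruct_intervals(sim$curves[, c("t", "s")], total_n = 200)
    (sum(iv$d) - sum(sim$ipd$event)) / sum(sim$ipd$event)
  }, numeric(1))
  expect_true(all(rel_err0 >= 0))       # always an overcount
  expect_lt(max(rel_err0), 0.2)
})

test_that("IPD expansion conserves counts and round-trips the curve", {
  iv <- reconstruct_intervals(
    data.frame(t = c(0, 1), s = c(1, 0.8)),
    at_risk = data.frame(t = c(0, 1), n_risk = c(10, 8))
  )
  ipd <- expand_ipd(iv, "trt", "tr1")
  expect_equal(sum(ipd$event), 2)
  expect_equal(nrow(ipd), 2)

  empty <- reconstruct_intervals(data.frame(t = c(0, 1), s = c(1, 1)),
                                 total_n = 5)
  expect_equal(nrow(expand_ipd(empty)), 0)

  # with exact curve and per-event at-risk counts the round trip is exact
  sim <- simulate_survival_trial(c(a = log(2) / 10),
                                 cfg = sim_config(seed = 14, n_per_arm = 120,
                                                  censoring_rate = 0.1,
                                                  follow_up = 24))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sim$ipd)
  exact_curve <- data.frame(t = c(0, fit$time), s = c(1, fit$surv))
  dense_ar <- data.frame(t = c(0, fit$time),
                         n_risk = c(fit$n, fit$n.risk - fit$n.event - fit$n.censor))
  iv2 <- reconstruct_intervals(exact_curve, at_risk = dense_ar)
  expect_equal(sum(iv2$d), sum(fit$n.event))
  km2 <- km_estimator(expand_ipd(iv2, "a", "t"))
  s_rt <- approx(c(0, km2$steps$time), c(1, km2$steps$surv), xout = fit$time,
                 method = "constant", rule = 2)$y
  expect_equal(s_rt, fit$surv, tolerance = 1e-12)
})

test_that("the product-limit estimator matches hand computation", {
  ipd <- tibble::tibble(time = 1:4, event = 1L, treatment_id = "a",
                        trial_id = "t")
  km <- km_estimator(ipd)
  expect_equal(km$steps$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(glance(km)$median, 2)

  one <- km_estimator(tibble::tibble(time = 5, event = 1L))
  expect_equal(one$steps$surv, 0)
  expect_equal(glance(one)$median, 5)

  censored <- km_estimator(tibble::tibble(time = c(3, 4), event = 0L))
  expect_true(is.na(glance(censored)$median))

  big <- simulate_survival_trial(c(a = log(2) / 9),
                                 cfg = sim_config(seed = 1, n_per_arm = 5000,
                                                  censoring_rate = 0,
                                                  follow_up = 80))
  expect_equal(glance(km_estimator(big$ipd))$median, 9, tolerance = 0.02)

  # the two median-CI variants differ but both bracket the median
  g1 <- glance(km_estimator(big$ipd, conf_type = "log-log"))
  g2 <- glance(km_estimator(big$ipd, conf_type = "plain"))
  expect_true(g1$ci_low <= g1$median && g1$median <= g1$ci_high)
  expect_true(g2$ci_low <= g2$median && g2$median <= g2$ci_high)
})

test_that("IPD pooling concatenates trials and extends follow-up", {
  a <- tibble::tibble(time = c(1, 2), event = 1L, treatment_id = "x",
                      trial_id = "t1")
  b <- tibble::tibble(time = c(3, 8), event = 1L, treatment_id = "x",
                      trial_id = "t2")
  pooled <- pool_ipd(a, b)
  expect_equal(nrow(pooled), 4)
  expect_equal(max(pooled$time), 8)
  # duplication invariance of the KM curve
  km1 <- km_estimator(a)
  km2 <- km_estimator(pool_ipd(a, dplyr::mutate(a, trial_id = "t9")))
  expect_equal(km2$steps$surv[km2$steps$time %in% km1$steps$time],
               km1$steps$surv)
  expect_error(
    pool_ipd(dplyr::mutate(a, time_unit = "months"),
             dplyr::mutate(b, time_unit = "weeks")),
    class = "alk_validation_error"
  )
})

test_that("log-rank matches a brute-force risk-table computation", {
  ipd <- tibble::tibble(time = c(1, 3, 2, 4),
                        event = 1L,
                        treatment_id = c("A", "A", "B", "B"),
                        trial_id = "t")
  res <- logrank_test(ipd)
  expect_equal(res$chi2,
               oracle_logrank_2g(ipd$time, ipd$event, ipd$treatment_id),
               tolerance = 1e-10)

  same <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = 1L,
                         treatment_id = rep(c("A", "B"), each = 3),
                         trial_id = "t")
  res0 <- logrank_test(same)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)

  # invariance to group relabeling
  relab <- dplyr::mutate(ipd, treatment_id = ifelse(treatment_id == "A", "Z", "Y"))
  expect_equal(logrank_test(relab)$chi2, res$chi2)

  expect_error(logrank_test(dplyr::mutate(ipd, treatment_id = "A")),
               class = "alk_validation_error")
})

test_that("log-rank has power against a halved hazard at trial scale", {
  hits <- vapply(1:30, function(s) {
    sim <- simulate_survival_trial(c(ctrl = log(2) / 6, trt = log(2) / 12),
                                   cfg = sim_config(seed = 100 + s,
                                                    n_per_arm = 500,
                                                    censoring_rate = 0.1,
                                                    follow_up = 30))
    logrank_test(sim$ipd)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
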