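fast_settings <- function(seed = 1, chains = 2) {
  mcmc_settings(chains = chains, iterations = 6000, burnin = 3000, thin = 3,
                seed = seed)
}

test_that("model construction counts basic parameters correctly", {
  # minimal two-treatment, one-trial graph: one basic parameter
  tiny <- build_network(
    tibble::tibble(trial_id = "t1", design = "RCT",
                   treatment = c("A", "B"), n = 100L, pretreatment = "MIXED"),
    arm_data = tibble::tibble(trial_id = "t1", treatment = c("A", "B"),
                              outcome = "SIM", events = c(30L, 20L),
                              total = 100L)
  )
  m <- build_nma_model(tiny, nma_model_spec("BINARY_ARM", reference = "B"))
  expect_equal(ncol(m$A), 1)

  # four-node contrast network: three basic parameters vs chemotherapy
  hr <- dplyr::mutate(pfs_vs_chemo(),
                      trial_id = paste0("t", dplyr::row_number()),
                      comparator = "chemotherapy")
  net <- build_network(fixture_trials(), contrast_data = hr, outcome = "PFS")
  m4 <- build_nma_model(net, nma_model_spec("CONTRAST_NORMAL"))
  expect_equal(sort(colnames(m4$A)),
               c("d_alectinib", "d_ceritinib", "d_crizotinib"))

  # unrelated-mean-effects variant on a triangle: three free edge parameters
  tri <- build_network(
    tibble::tibble(trial_id = rep(c("t1", "t2", "t3"), each = 2),
                   design = "RCT",
                   treatment = c("A", "B", "B", "C", "A", "C"),
                   n = 100L, pretreatment = "MIXED"),
    arm_data = tibble::tibble(trial_id = rep(c("t1", "t2", "t3"), each = 2),
                              treatment = c("A", "B", "B", "C", "A", "C"),
                              outcome = "SIM", events = 30L, total = 100L)
  )
  mi <- build_nma_model(tri, nma_model_spec("BINARY_ARM", reference = "C",
                                            consistency = FALSE))
  expect_equal(ncol(mi$A), 3)

  # >2-arm trials are rejected, incomplete trials dropped with a warning
  bad <- tiny
  bad$arm_data <- dplyr::bind_rows(
    bad$arm_data,
    tibble::tibble(trial_id = "t1", treatment = "C", outcome = "SIM",
                   events = 10L, total = 100L)
  )
  expect_error(build_nma_model(bad, nma_model_spec("BINARY_ARM", reference = "B")),
               class = "alk_validation_error")
  lop <- tiny
  lop$arm_data <- dplyr::bind_rows(
    lop$arm_data,
    tibble::tibble(trial_id = "t2", treatment = "A", outcome = "SIM",
                   events = 10L, total = 100L)
  )
  expect_warning(build_nma_model(lop, nma_model_spec("BINARY_ARM", reference = "B")),
                 "excluding")
})

test_that("the sampler is deterministic given a seed", {
  net <- simulate_binary_network(cfg = sim_config(seed = 2))
  m <- build_nma_model(net, nma_model_spec("BINARY_ARM"))
  f1 <- run_mcmc(m, fast_settings(seed = 7))
  f2 <- run_mcmc(m, fast_settings(seed = 7))
  expect_identical(f1$chains, f2$chains)
  f3 <- run_mcmc(m, fast_settings(seed = 8))
  expect_false(identical(f1$chains, f3$chains))
  expect_equal(nrow(f1$chains[[1]]), 1000)  # (6000 - 3000) / 3
})

test_that("the sampler matches the conjugate closed form on a toy problem", {
  # one contrast, tau pinned near zero: d | y ~ Normal with precision
  # 1/se^2 + 1/prior_sd^2 (precision-weighted shrinkage of y toward 0)
  y <- 0.8; se <- 0.15; prior_sd <- 2
  net <- list(contrast_data = tibble::tibble(
    trial_id = "t1", treatment = "A", comparator = "B",
    log_hr = y, se_log_hr = se
  ))
  class(net) <- "evidence_network"
  spec <- nma_model_spec("CONTRAST_NORMAL", reference = "B",
                         priors = list(d_sd = prior_sd, tau_upper = 1e-4))
  fit <- run_mcmc(build_nma_model(net, spec),
                  mcmc_settings(chains = 4, iterations = 20000, burnin = 5000,
                                thin = 5, seed = 3))
  draws <- do.call(rbind, fit$chains)[, "d_A"]
  post_prec <- 1 / se^2 + 1 / prior_sd^2
  post_mean <- (y / se^2) / post_prec
  mcse <- sd(draws) / sqrt(400)   # conservative ESS for a correlated chain
  expect_lt(abs(mean(draws) - post_mean), 3 * max(mcse, 0.005))
  expect_equal(sd(draws), sqrt(1 / post_prec), tolerance = 0.1)
})

test_that("posterior concentrates on the observed effect as n grows", {
  truth <- network_truth(treatments = c("A", "B"), d = c(A = log(2)),
                         tau = 0, baseline_p = 0.3, baseline_sd = 0)
  net <- simulate_binary_network(truth, sim_config(trials_per_edge = c("A|B" = 1L),
                                                   n_per_arm = 1e4, seed = 17))
  w <- net$arm_data
  obs_lor <- log(w$events[1] / (w$total[1] - w$events[1])) -
    log(w$events[2] / (w$total[2] - w$events[2]))
  spec <- nma_model_spec("BINARY_ARM", reference = "B",
                         priors = list(tau_upper = 0.01))
  fit <- run_mcmc(build_nma_model(net, spec), fast_settings(seed = 2))
  expect_equal(median(do.call(rbind, fit$chains)[, "d_A"]), obs_lor,
               tolerance = 0.05 / abs(obs_lor))
})

test_that("PSRF follows the Brooks-Gelman-Rubin formula and flags divergence", {
  set.seed(42)
  n <- 2000
  same <- list(cbind(x = rnorm(n)), cbind(x = rnorm(n)))
  expect_equal(psrf(same, "x")$psrf, 1, tolerance = 0.01)

  apart <- list(cbind(x = rnorm(200, 0, 1)), cbind(x = rnorm(200, 100, 1)))
  expect_gt(psrf(apart, "x")$psrf, 10)

  # hand evaluation of the formula on small fixed chains
  c1 <- cbind(x = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  c2 <- cbind(x = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 12))
  W <- mean(c(var(c1[, 1]), var(c2[, 1])))
  B_n <- var(c(mean(c1[, 1]), mean(c2[, 1])))
  expect_equal(psrf(list(c1, c2), "x")$psrf,
               sqrt((9 / 10 * W + B_n) / W), tolerance = 1e-12)

  expect_warning(out <- psrf(list(cbind(x = rep(1, 20)), cbind(x = rep(1, 20))),
                             "x"), "constant")
  expect_equal(out$psrf, 1)
  expect_error(psrf(list(cbind(x = rnorm(20))), "x"),
               class = "alk_diagnostic_error")
})

test_that("league tables are transitive at the draw level and reciprocal", {
  net <- simulate_binary_network(cfg = sim_config(seed = 6))
  fit <- run_mcmc(build_nma_model(net, nma_model_spec("BINARY_ARM")),
                  fast_settings(seed = 1))
  lt <- league_table(fit, "OR")
  trts <- lt$treatments
  # reciprocal symmetry of the draw-wise quantiles
  for (x in trts) for (y in trts) {
    expect_equal(lt$point[y, x] * lt$point[x, y], 1, tolerance = 1e-10)
    expect_equal(lt$ci_low[y, x] * lt$ci_high[x, y], 1, tolerance = 1e-10)
  }
  # draw-level transitivity is exact
  D <- do.call(rbind, fit$chains)
  ab <- D[, "d_alectinib"] - D[, "d_ceritinib"]
  indirect <- (D[, "d_alectinib"] - D[, "d_crizotinib"]) +
    (D[, "d_crizotinib"] - D[, "d_ceritinib"])
  expect_equal(ab, indirect, tolerance = 1e-12)

  # null effects give an all-ones table
  null_draws <- matrix(0, 100, 2, dimnames = list(NULL, c("A", "B")))
  lt0 <- league_table(null_draws, "OR")
  expect_true(all(lt0$point == 1))
})

test_that("rank probabilities are doubly stochastic and direction-aware", {
  single <- matrix(0, 50, 1, dimnames = list(NULL, "A"))
  expect_equal(unname(rank_probabilities(single)$prob[1, 1]), 1)

  set.seed(9)
  twins <- cbind(A = rnorm(4000), B = rnorm(4000))
  rk <- rank_probabilities(twins)
  expect_equal(unname(rk$prob["A", 1]), 0.5, tolerance = 0.05)

  net <- simulate_binary_network(cfg = sim_config(seed = 3))
  fit <- run_mcmc(build_nma_model(net, nma_model_spec("BINARY_ARM")),
                  fast_settings(seed = 4))
  tab <- rank_probabilities(fit, lower_is_better = FALSE)$prob
  expect_equal(unname(rowSums(tab)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(colSums(tab)), rep(1, 4), tolerance = 1e-9)
  # flipping the direction reverses the rank order
  flipped <- rank_probabilities(fit, lower_is_better = TRUE)$prob
  expect_equal(unname(tab[, 1]), unname(flipped[, 4]), tolerance = 1e-12)
})

test_that("consistency and inconsistency models agree on loop-free networks", {
  net <- simulate_binary_network(cfg = sim_config(seed = 12))
  rep_ok <- compare_consistency(net, nma_model_spec("BINARY_ARM"),
                                fast_settings(seed = 5))
  expect_false(rep_ok$has_loop)
  expect_true(all(rep_ok$edges$intervals_overlap))
  expect_lt(max(abs(rep_ok$edges$consistency_median -
                      rep_ok$edges$inconsistency_median)), 0.35)
})

test_that("injected inconsistency on a triangle is detected, null is not", {
  tri_truth <- function(om) {
    network_truth(treatments = c("A", "B", "C"),
                  d = c(A = 1, B = 0.5), tau = 0.02, baseline_p = 0.35,
                  baseline_sd = 0.1,
                  omega = c("A|B" = om))
  }
  tri_cfg <- sim_config(trials_per_edge = c("A|B" = 6L, "B|C" = 6L, "A|C" = 6L),
                        n_per_arm = 2000, seed = 23)
  spec <- nma_model_spec("BINARY_ARM", reference = "C")

  hot <- compare_consistency(simulate_binary_network(tri_truth(1), tri_cfg),
                             spec, fast_settings(seed = 6))
  expect_true(hot$has_loop)
  bad_edge <- hot$edges[paste(hot$edges$treatment, hot$edges$comparator) %in%
                          c("A B", "B A"), ]
  expect_false(bad_edge$intervals_overlap)

  cold <- compare_consistency(simulate_binary_network(tri_truth(0), tri_cfg),
                              spec, fast_settings(seed = 6))
  expect_true(all(cold$edges$intervals_overlap))

  # imposing transitivity on conflicting evidence masquerades as
  # between-trial heterogeneity: tau inflates relative to the null triangle
  tau_hot <- median(do.call(rbind, hot$fits$consistency$chains)[, "tau"])
  tau_cold <- median(do.call(rbind, cold$fits$consistency$chains)[, "tau"])
  expect_gt(tau_hot, 3 * tau_cold)
})

test_that("direct pairwise pooling coheres with the network posterior", {
  truth <- network_truth(treatments = c("A", "B"), d = c(A = 0.7), tau = 0.1,
                         baseline_p = 0.3, baseline_sd = 0.2)
  net <- simulate_binary_network(
    truth, sim_config(trials_per_edge = c("A|B" = 6L), n_per_arm = 300,
                      seed = 19))
  chk <- pairwise_vs_nma_check(net, nma_model_spec("BINARY_ARM", reference = "B"),
                               fast_settings(seed = 11, chains = 2))
  expect_false(any(chk$flagged))
  expect_lt(abs(chk$nma_median - chk$dl_estimate), 0.05)

  # a single-trial pair: the credible interval is not materially narrower
  net1 <- simulate_binary_network(
    truth, sim_config(trials_per_edge = c("A|B" = 1L), n_per_arm = 300,
                      seed = 20))
  chk1 <- pairwise_vs_nma_check(net1, nma_model_spec("BINARY_ARM", reference = "B"),
                                fast_settings(seed = 12))
  expect_gte(chk1$nma_high - chk1$nma_low,
             0.8 * (chk1$dl_high - chk1$dl_low))
})
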