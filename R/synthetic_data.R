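# run expr under a fixed seed, restoring the caller's RNG state afterward
local_seed <- function(seed, expr) {
  if (is.null(seed)) abort("a seed is required", class = "alk_validation_error")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Ground truth for a simulated evidence network
#'
#' Defines the treatments, true basic parameters (log odds or hazard ratios
#' relative to the reference, the last treatment), between-trial standard
#' deviation, baseline event probability and optional per-edge inconsistency
#' offsets for the synthetic generators.
#'
#' The defaults emulate the four-treatment ALK-inhibitor evidence base:
#' alectinib, ceritinib and crizotinib versus a pooled chemotherapy node,
#' with true response-odds ratios near the magnitudes seen in that setting
#' (about 12, 8 and 6 versus chemotherapy), a 30% chemotherapy response
#' rate, and moderate between-trial heterogeneity (tau = 0.2 on the log-odds
#' scale).
#'
#' @param treatments Character vector; the last element is the reference.
#' @param d Named numeric of true log effects versus the reference for every
#'   non-reference treatment.
#' @param tau Between-trial SD of the trial-specific log effects.
#' @param baseline_p Reference-arm event probability.
#' @param baseline_sd SD of trial baseline logits around
#'   `qlogis(baseline_p)`.
#' @param omega Named per-edge inconsistency offsets (`"a|b"` with `a < b`
#'   alphabetically); missing edges get 0.
#' @return A `network_truth` list.
#' @export
network_truth <- function(treatments = c("alectinib", "ceritinib", "crizotinib",
                                         "chemotherapy"),
                          d = c(alectinib = log(12), ceritinib = log(8),
                                crizotinib = log(6)),
                          tau = 0.2,
                          baseline_p = 0.30,
                          baseline_sd = 0.3,
                          omega = NULL) {
  stopifnot(tau >= 0, baseline_p > 0, baseline_p < 1,
            setequal(names(d), utils::head(treatments, -1)))
  structure(list(treatments = treatments, d = d, tau = tau,
                 baseline_p = baseline_p, baseline_sd = baseline_sd,
                 omega = omega %||% numeric(0)),
            class = "network_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' @param trials_per_edge Named integer vector of trials per edge
#'   (`"a|b"`), or `NULL` to use the default layout mirroring the real
#'   evidence base (2 alectinib-crizotinib, 2 ceritinib-chemotherapy and 4
#'   crizotinib-chemotherapy trials with the published arm sizes).
#' @param n_per_arm Patients per arm for edges created via
#'   `trials_per_edge`.
#' @param censoring_rate Target probability that a survival time is censored
#'   before follow-up ends.
#' @param follow_up Administrative follow-up horizon, months.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(trials_per_edge = NULL, n_per_arm = 150,
                       censoring_rate = 0.1, follow_up = 24, seed = 1) {
  stopifnot(n_per_arm >= 1, censoring_rate >= 0, censoring_rate < 1,
            follow_up > 0)
  structure(list(trials_per_edge = trials_per_edge, n_per_arm = n_per_arm,
                 censoring_rate = censoring_rate, follow_up = follow_up,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# default two-arm trial layout: edges and arm sizes as in the published
# four-node network (8 randomized trials)
default_trial_layout <- function() {
  tibble::tribble(
    ~trial_id, ~treatment_a, ~treatment_b, ~n_a, ~n_b,
    "sim_alc_crz_1", "alectinib", "crizotinib", 103L, 104L,
    "sim_alc_crz_2", "alectinib", "crizotinib", 152L, 151L,
    "sim_cer_chm_1", "ceritinib", "chemotherapy", 189L, 187L,
    "sim_cer_chm_2", "ceritinib", "chemotherapy", 115L, 116L,
    "sim_crz_chm_1", "crizotinib", "chemotherapy", 173L, 174L,
    "sim_crz_chm_2", "crizotinib", "chemotherapy", 172L, 171L,
    "sim_crz_chm_3", "crizotinib", "chemotherapy", 104L, 103L,
    "sim_crz_chm_4", "crizotinib", "chemotherapy", 14L, 14L
  )
}

layout_from_config <- function(cfg) {
  if (is.null(cfg$trials_per_edge)) return(default_trial_layout())
  edges <- names(cfg$trials_per_edge)
  purrr::map_dfr(edges, function(e) {
    ab <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(ab) != 2) {
      abort("edge names must look like 'treatmentA|treatmentB'",
            class = "alk_validation_error")
    }
    k <- cfg$trials_per_edge[[e]]
    if (k < 1) abort("trials per edge must be >= 1", class = "alk_validation_error")
    tibble::tibble(
      trial_id = sprintf("sim_%s_%s_%d", substr(ab[1], 1, 3),
                         substr(ab[2], 1, 3), seq_len(k)),
      treatment_a = ab[1], treatment_b = ab[2],
      n_a = as.integer(cfg$n_per_arm), n_b = as.integer(cfg$n_per_arm)
    )
  })
}

#' Simulate arm-level binary data on an evidence network
#'
#' For each two-arm trial on edge (x, y), draws a trial-specific log odds
#' ratio `delta ~ Normal(d_x - d_y + omega_xy, tau^2)` around the true
#' contrast, a trial baseline logit, and binomial event counts in both arms.
#' Deterministic given the seed in `cfg`.
#'
#' @param truth A [network_truth()].
#' @param cfg A [sim_config()]; `cfg$seed` drives all randomness.
#' @return An `evidence_network` with `arm_data` attached (columns
#'   `trial_id`, `treatment`, `outcome = "SIM"`, `events`, `total`) and the
#'   generating `truth` stored as attribute `"truth"`.
#' @export
#' @examples
#' net <- simulate_binary_network(cfg = sim_config(seed = 7))
#' net$arm_data
simulate_binary_network <- function(truth = network_truth(), cfg = sim_config()) {
  layout <- layout_from_config(cfg)
  ref <- utils::tail(truth$treatments, 1)
  d_full <- c(truth$d, stats::setNames(0, ref))
  unknown <- setdiff(unique(c(layout$treatment_a, layout$treatment_b)),
                     names(d_full))
  if (length(unknown) > 0) {
    abort(paste0("layout uses treatments absent from truth: ",
                 paste(unknown, collapse = ", ")),
          class = "alk_validation_error")
  }
  local_seed(cfg$seed, {
    rows <- purrr::pmap_dfr(layout, function(trial_id, treatment_a, treatment_b,
                                             n_a, n_b) {
      edge_key <- paste(sort(c(treatment_a, treatment_b)), collapse = "|")
      om <- if (edge_key %in% names(truth$omega)) truth$omega[[edge_key]] else 0
      mu <- stats::rnorm(1, stats::qlogis(truth$baseline_p), truth$baseline_sd)
      delta <- stats::rnorm(1, d_full[[treatment_a]] - d_full[[treatment_b]] + om,
                            truth$tau)
      p_b <- stats::plogis(mu)
      p_a <- stats::plogis(mu + delta)
      tibble::tibble(
        trial_id = trial_id,
        treatment = c(treatment_a, treatment_b),
        outcome = "SIM",
        events = c(stats::rbinom(1, n_a, p_a), stats::rbinom(1, n_b, p_b)),
        total = c(n_a, n_b)
      )
    })
    trials <- tibble::tibble(
      trial_id = rep(layout$trial_id, each = 2),
      design = "RCT",
      treatment = rows$treatment,
      n = rows$total,
      pretreatment = "MIXED"
    )
    net <- build_network(trials, arm_data = rows, outcome = "SIM")
    attr(net, "truth") <- truth
    net
  })
}

#' Simulate a survival trial and its digitized curve
#'
#' Draws exponential event times per arm, applies independent uniform
#' censoring calibrated to the requested censoring probability plus
#' administrative censoring at follow-up, and emits (a) the true
#' individual-patient data, (b) the Kaplan-Meier curve sampled on a fixed
#' time grid with optional digitizer jitter, and (c) numbers at risk at
#' regular intervals — the artifacts a curve digitization workflow produces.
#'
#' @param rates Named vector of exponential hazard rates per treatment
#'   (per month); the first element is the comparator for the reported true
#'   hazard ratios.
#' @param cfg A [sim_config()].
#' @param n Patients per arm (defaults to `cfg$n_per_arm`).
#' @param grid_step Spacing of the digitized time grid in months
#'   (default 0.5).
#' @param jitter_sd SD of digitizer noise added to survival probabilities
#'   (default 0, i.e. exact coordinates).
#' @param at_risk_every Spacing of the at-risk table in months (default 3).
#' @param trial_id Identifier stamped on all output rows.
#' @return A list with tibbles `ipd` (`time`, `event`, `treatment_id`,
#'   `trial_id`), `curves` (`trial_id`, `treatment`, `t`, `s`), `at_risk`
#'   (`trial_id`, `treatment`, `t`, `n_risk`), and `true_hr` (rates relative
#'   to the first treatment).
#' @export
simulate_survival_trial <- function(rates, cfg = sim_config(),
                                    n = cfg$n_per_arm, grid_step = 0.5,
                                    jitter_sd = 0, at_risk_every = 3,
                                    trial_id = "sim_surv") {
  stopifnot(all(rates > 0), length(names(rates)) == length(rates))
  if (cfg$censoring_rate >= 1) {
    abort("censoring rate must be < 1", class = "alk_validation_error")
  }
  local_seed(cfg$seed, {
    ipd <- purrr::imap_dfr(rates, function(lam, trt) {
      tt <- stats::rexp(n, lam)
      cens <- censoring_times(n, lam, cfg$censoring_rate, cfg$follow_up)
      tibble::tibble(
        time = pmin(tt, cens),
        event = as.integer(tt <= cens),
        treatment_id = trt,
        trial_id = trial_id
      )
    })
    grid <- seq(0, cfg$follow_up, by = grid_step)
    curves <- purrr::imap_dfr(rates, function(lam, trt) {
      sub <- ipd[ipd$treatment_id == trt, ]
      fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
      s <- km_step_at(fit, grid)
      if (jitter_sd > 0) {
        s <- pmin(1, pmax(0, s + stats::rnorm(length(s), 0, jitter_sd)))
        s[1] <- 1
      }
      tibble::tibble(trial_id = trial_id, treatment = trt, t = grid, s = s)
    })
    risk_times <- seq(0, cfg$follow_up, by = at_risk_every)
    at_risk <- purrr::imap_dfr(rates, function(lam, trt) {
      sub <- ipd[ipd$treatment_id == trt, ]
      tibble::tibble(
        trial_id = trial_id, treatment = trt, t = risk_times,
        n_risk = vapply(risk_times, function(tt) sum(sub$time >= tt), 0L)
      )
    })
    list(ipd = ipd, curves = curves, at_risk = at_risk,
         true_hr = rates / rates[[1]])
  })
}

# uniform censoring scale b solving P(C < T) = rate for C ~ U(0, b),
# T ~ Exp(lam); administrative censoring at follow_up applied on top
censoring_times <- function(n, lam, rate, follow_up) {
  if (rate <= 0) return(rep(follow_up, n))
  f <- function(b) (1 - exp(-lam * b)) / (lam * b) - rate
  b <- tryCatch(stats::uniroot(f, c(1e-6, 1e6))$root, error = function(e) follow_up)
  pmin(stats::runif(n, 0, b), follow_up)
}

# step-function evaluation of a survfit curve at arbitrary times
km_step_at <- function(fit, times) {
  st <- c(0, fit$time)
  sv <- c(1, fit$surv)
  idx <- findInterval(times, st)
  sv[pmax(idx, 1)]
}

#' Simulate single-arm proportion studies
#'
#' Study-level true logits are `qlogis(true_p)` plus Normal(0, `tau_logit`^2)
#' offsets; event counts are binomial.
#'
#' @param true_p True underlying proportion.
#' @param k Number of studies.
#' @param n_range Integer range of study sizes (uniformly drawn).
#' @param tau_logit Between-study SD on the logit scale.
#' @param seed Integer seed.
#' @return A tibble (`study_id`, `events`, `n`).
#' @export
simulate_proportion_studies <- function(true_p, k, n_range = c(50, 250),
                                        tau_logit = 0, seed = 1) {
  stopifnot(true_p > 0, true_p < 1, k >= 1)
  local_seed(seed, {
    n <- sample(seq(n_range[1], n_range[2]), k, replace = TRUE)
    logits <- stats::qlogis(true_p) + stats::rnorm(k, 0, tau_logit)
    tibble::tibble(
      study_id = sprintf("sim_prop_%d", seq_len(k)),
      events = stats::rbinom(k, n, stats::plogis(logits)),
      n = n
    )
  })
}
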