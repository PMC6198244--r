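#' Specification of a Bayesian network-meta-analysis model
#'
#' @param outcome_kind `"BINARY_ARM"` (arm-level binomial-logit likelihood)
#'   or `"CONTRAST_NORMAL"` (normal likelihood on reported log hazard
#'   ratios).
#' @param reference Reference treatment; all basic parameters are log
#'   effects versus it.
#' @param priors List with `mu_sd` and `d_sd` (SDs of the vague normal
#'   priors on trial baselines and basic parameters, default 100) and
#'   `tau_upper` (upper bound of the uniform prior on the between-trial SD,
#'   default 5).
#' @param consistency If `TRUE` (default) contrasts obey transitivity
#'   (`d_xy = d_y - d_x`); if `FALSE` every observed edge gets its own
#'   unrelated mean effect (the inconsistency model).
#' @return An `nma_model_spec` list.
#' @export
nma_model_spec <- function(outcome_kind = c("BINARY_ARM", "CONTRAST_NORMAL"),
                           reference = "chemotherapy",
                           priors = list(mu_sd = 100, d_sd = 100, tau_upper = 5),
                           consistency = TRUE) {
  outcome_kind <- match.arg(outcome_kind)
  priors <- utils::modifyList(list(mu_sd = 100, d_sd = 100, tau_upper = 5),
                              priors)
  stopifnot(priors$tau_upper > 0, priors$mu_sd > 0, priors$d_sd > 0)
  structure(list(outcome_kind = outcome_kind, reference = reference,
                 priors = priors, consistency = isTRUE(consistency)),
            class = "nma_model_spec")
}

#' MCMC settings
#'
#' Defaults follow the headline analysis configuration: four chains of
#' 50,000 iterations with a 20,000-iteration burn-in and a thinning interval
#' of 10, retaining 3000 draws per chain.
#'
#' @param chains Number of chains (>= 1; >= 2 needed for [psrf()]).
#' @param iterations Total iterations per chain.
#' @param burnin Burn-in iterations (discarded; proposal adaptation happens
#'   only here).
#' @param thin Thinning interval.
#' @param seed Master seed; chain `c` runs under `seed + c - 1`.
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(chains = 4, iterations = 50000, burnin = 20000,
                          thin = 10, seed = 1) {
  stopifnot(chains >= 1, burnin >= 0, burnin < iterations, thin >= 1)
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Build a network-meta-analysis model from an evidence network
#'
#' Translates a connected two-arm evidence network into the internal model
#' graph sampled by [run_mcmc()]. For arm-level binary data the likelihood
#' is `r ~ Binomial(n, plogis(mu_trial + delta_trial * [non-baseline]))`;
#' for contrast data it is `y ~ Normal(delta_trial, se^2)`. Trial effects
#' `delta` are exchangeable around the edge contrast with between-trial SD
#' `tau`. The baseline arm of each trial is the treatment nearer the
#' reference in the ordering (reference first, others alphabetical).
#'
#' Trials with the outcome missing in one arm are excluded with a warning;
#' trials with more than two arms are rejected (the multi-arm covariance
#' correction is not implemented).
#'
#' @param network An `evidence_network` carrying `arm_data` (binary) or
#'   `contrast_data` (log hazard ratios); see [build_network()].
#' @param spec An [nma_model_spec()].
#' @return An `nma_model` list (treatments in model order, per-trial data
#'   arrays, the design matrix mapping basic parameters to trial contrasts,
#'   and parameter names).
#' @export
build_nma_model <- function(network, spec = nma_model_spec()) {
  stopifnot(inherits(network, "evidence_network"))
  if (!inherits(spec, "nma_model_spec")) {
    abort("spec must be an nma_model_spec()", class = "alk_validation_error")
  }
  binary <- spec$outcome_kind == "BINARY_ARM"
  if (binary) {
    dat <- network$arm_data
    if (is.null(dat)) {
      abort("network has no arm-level binary data attached",
            class = "alk_validation_error")
    }
    dat <- tibble::as_tibble(dat)
    counts <- table(dat$trial_id)
    if (any(counts > 2)) {
      abort(paste0("trials with more than two arms are not supported: ",
                   paste(names(counts)[counts > 2], collapse = ", ")),
            class = "alk_validation_error")
    }
    incomplete <- names(counts)[counts < 2]
    if (length(incomplete) > 0) {
      warn(paste0("excluding trial(s) with outcome missing in one arm: ",
                  paste(incomplete, collapse = ", ")))
      dat <- dat[!(dat$trial_id %in% incomplete), ]
    }
    if (nrow(dat) == 0) {
      abort("no two-arm trials with complete outcome data",
            class = "alk_validation_error")
    }
    trts <- sort(unique(dat$treatment))
  } else {
    dat <- network$contrast_data
    if (is.null(dat)) {
      abort("network has no contrast-level data attached",
            class = "alk_validation_error")
    }
    dat <- as_contrast_data(dat)
    trts <- sort(unique(c(dat$treatment, dat$comparator)))
  }
  if (!(spec$reference %in% trts)) {
    abort(paste0("reference treatment '", spec$reference,
                 "' absent from the outcome data"),
          class = "alk_validation_error")
  }
  treatments <- c(spec$reference, setdiff(trts, spec$reference))

  if (binary) {
    wide <- dat |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::arrange(match(.data$treatment, treatments), .by_group = TRUE) |>
      dplyr::summarise(
        b_trt = .data$treatment[1], t_trt = .data$treatment[2],
        r_b = .data$events[1], n_b = .data$total[1],
        r_t = .data$events[2], n_t = .data$total[2],
        .groups = "drop"
      )
  } else {
    wide <- tibble::tibble(
      trial_id = dat$trial_id,
      # contrast rows report treatment vs comparator; orient each trial so
      # delta is the effect of the treatment further from the reference
      b_trt = ifelse(match(dat$comparator, treatments) <
                       match(dat$treatment, treatments),
                     dat$comparator, dat$treatment),
      t_trt = ifelse(match(dat$comparator, treatments) <
                       match(dat$treatment, treatments),
                     dat$treatment, dat$comparator),
      y = ifelse(match(dat$comparator, treatments) <
                   match(dat$treatment, treatments),
                 dat$log_hr, -dat$log_hr),
      se = dat$se_log_hr
    )
  }

  # connectivity of the trial graph actually entering the likelihood
  comp <- network_components(
    treatments,
    tibble::tibble(treatment_a = wide$b_trt, treatment_b = wide$t_trt)
  )
  if (length(comp) > 1) {
    abort(paste0("outcome data do not form a connected network; components: ",
                 paste(vapply(comp, paste, "", collapse = "+"), collapse = " | ")),
          class = "alk_connectivity_error")
  }

  n_tr <- nrow(wide)
  if (spec$consistency) {
    basic <- treatments[-1]
    A <- matrix(0, n_tr, length(basic),
                dimnames = list(wide$trial_id, paste0("d_", basic)))
    for (i in seq_len(n_tr)) {
      if (wide$t_trt[i] != treatments[1]) A[i, paste0("d_", wide$t_trt[i])] <- 1
      if (wide$b_trt[i] != treatments[1]) A[i, paste0("d_", wide$b_trt[i])] <- -1
    }
  } else {
    edge <- paste0("d_", wide$t_trt, "_vs_", wide$b_trt)
    edges <- unique(edge)
    A <- matrix(0, n_tr, length(edges), dimnames = list(wide$trial_id, edges))
    A[cbind(seq_len(n_tr), match(edge, edges))] <- 1
  }

  structure(
    list(kind = spec$outcome_kind, treatments = treatments, trials = wide,
         A = A, spec = spec,
         param_names = c(colnames(A), "tau",
                         if (binary) paste0("mu_", wide$trial_id),
                         paste0("delta_", wide$trial_id))),
    class = "nma_model"
  )
}

#' @export
print.nma_model <- function(x, ...) {
  cat("NMA model (", x$kind, ", ",
      if (x$spec$consistency) "consistency" else "inconsistency", "): ",
      length(x$treatments), " treatments, ", nrow(x$trials), " trials, ",
      ncol(x$A), " basic parameter(s)\n", sep = "")
  invisible(x)
}

# crude data-driven initial values; chain-specific jitter added in run_mcmc
nma_inits <- function(model) {
  w <- model$trials
  if (model$kind == "BINARY_ARM") {
    mu0 <- stats::qlogis((w$r_b + 0.5) / (w$n_b + 1))
    delta0 <- stats::qlogis((w$r_t + 0.5) / (w$n_t + 1)) - mu0
  } else {
    mu0 <- numeric(0)
    delta0 <- w$y
  }
  d0 <- tryCatch(
    as.numeric(stats::coef(stats::lm.fit(model$A, delta0))),
    error = function(e) rep(0, ncol(model$A))
  )
  d0[!is.finite(d0)] <- 0
  list(mu0 = mu0, delta0 = delta0, d0 = d0, tau0 = 0.2)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Draws from the posterior of an [build_nma_model()] model with
#' random-walk Metropolis updates for every scalar parameter. Proposal
#' scales adapt toward 44% acceptance during burn-in only and are frozen
#' afterward, preserving detailed balance for the retained draws. Chain
#' `c` is seeded with `settings$seed + c - 1`, so results are fully
#' deterministic given the settings.
#'
#' @param model An `nma_model`.
#' @param settings An [mcmc_settings()].
#' @return An `nma_fit`: per-chain matrices of retained draws (columns are
#'   basic parameters `d_*`, the between-trial SD `tau`, trial baselines
#'   `mu_*` for binary models, and trial effects `delta_*`), plus the model
#'   and settings.
#' @export
#' @examples
#' net <- simulate_binary_network(cfg = sim_config(seed = 3))
#' model <- build_nma_model(net, nma_model_spec("BINARY_ARM"))
#' fit <- run_mcmc(model, mcmc_settings(chains = 2, iterations = 2000,
#'                                      burnin = 1000, thin = 1, seed = 1))
#' fit
run_mcmc <- function(model, settings = mcmc_settings()) {
  stopifnot(inherits(model, "nma_model"))
  if (!inherits(settings, "mcmc_settings")) {
    abort("settings must be an mcmc_settings()", class = "alk_validation_error")
  }
  binary <- model$kind == "BINARY_ARM"
  w <- model$trials
  inits <- nma_inits(model)
  if (any(!is.finite(c(inits$mu0, inits$delta0, inits$d0)))) {
    abort(paste0("non-finite initial values; parameter dump: ",
                 paste(utils::capture.output(utils::str(inits)), collapse = " ")),
          class = "alk_initialization_error")
  }
  pri <- model$spec$priors
  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    chains[[ch]] <- local_seed(settings$seed + ch - 1L, {
      # overdisperse starting points across chains
      jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
      draws <- nma_chain_cpp(
        likelihood = if (binary) 0L else 1L,
        r_b = if (binary) as.integer(w$r_b) else integer(0),
        n_b = if (binary) as.integer(w$n_b) else integer(0),
        r_t = if (binary) as.integer(w$r_t) else integer(0),
        n_t = if (binary) as.integer(w$n_t) else integer(0),
        y = if (binary) numeric(0) else w$y,
        se = if (binary) numeric(0) else w$se,
        A = model$A,
        mu_sd = pri$mu_sd, d_sd = pri$d_sd, tau_upper = pri$tau_upper,
        iterations = settings$iterations, burnin = settings$burnin,
        thin = settings$thin,
        mu0 = jit(inits$mu0, 0.2), delta0 = jit(inits$delta0, 0.2),
        d0 = jit(inits$d0, 0.2),
        tau0 = min(max(inits$tau0 * exp(stats::rnorm(1, 0, 0.5)), 0.01),
                   0.9 * pri$tau_upper)
      )
      colnames(draws) <- model$param_names
      draws
    })
  }
  structure(list(chains = chains, model = model, settings = settings),
            class = "nma_fit")
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("NMA posterior: ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " retained draws, ",
      ncol(x$model$A), " basic parameter(s)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

# draws of a named parameter pooled across chains
pooled_draws <- function(fit, params = NULL) {
  m <- do.call(rbind, fit$chains)
  if (is.null(params)) m else m[, params, drop = FALSE]
}

# draws (all chains) of the contrast t vs b on the log scale (consistency)
contrast_draws <- function(fit, treatment, comparator) {
  ref <- fit$model$treatments[1]
  m <- pooled_draws(fit)
  get_d <- function(trt) {
    if (trt == ref) rep(0, nrow(m)) else m[, paste0("d_", trt)]
  }
  get_d(treatment) - get_d(comparator)
}

#' @export
tidy.nma_fit <- function(x, ...) {
  m <- pooled_draws(x)
  keep <- c(colnames(x$model$A), "tau")
  purrr::map_dfr(keep, function(p) {
    v <- m[, p]
    tibble::tibble(parameter = p, median = stats::median(v),
                   mean = mean(v), sd = stats::sd(v),
                   ci_low = unname(stats::quantile(v, 0.025)),
                   ci_high = unname(stats::quantile(v, 0.975)))
  })
}

#' @export
glance.nma_fit <- function(x, ...) {
  ps <- tryCatch(psrf(x), error = function(e) NULL)
  tibble::tibble(
    chains = length(x$chains),
    draws_per_chain = nrow(x$chains[[1]]),
    n_trials = nrow(x$model$trials),
    n_basic = ncol(x$model$A),
    max_psrf = if (is.null(ps)) NA_real_ else max(ps$psrf)
  )
}
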