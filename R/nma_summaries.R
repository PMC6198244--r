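#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' For each scalar parameter, computes
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B/n` the between-chain variance of the chain
#' means. Values near 1 indicate convergence of the chains to a common
#' distribution.
#'
#' @param fit An `nma_fit` (or a list of draw matrices with identical
#'   column names).
#' @param params Parameters to diagnose; defaults to the basic parameters
#'   and `tau`.
#' @return A tibble (`parameter`, `psrf`). Constant chains (zero within-
#'   and between-chain variance) yield 1 with a warning.
#' @export
psrf <- function(fit, params = NULL) {
  chains <- if (inherits(fit, "nma_fit")) fit$chains else fit
  if (length(chains) < 2) {
    abort("PSRF needs at least 2 chains", class = "alk_diagnostic_error")
  }
  n <- nrow(chains[[1]])
  if (n < 10) {
    abort("PSRF needs at least 10 draws per chain", class = "alk_diagnostic_error")
  }
  if (is.null(params)) {
    params <- if (inherits(fit, "nma_fit")) {
      c(colnames(fit$model$A), "tau")
    } else {
      colnames(chains[[1]])
    }
  }
  vals <- vapply(params, function(p) {
    x <- vapply(chains, function(ch) ch[, p], numeric(n))  # n x m
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) {
      if (B_over_n == 0) {
        warn(paste0("parameter '", p, "' is constant across chains; PSRF set to 1"))
        return(1)
      }
      return(Inf)
    }
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  tibble::tibble(parameter = params, psrf = unname(vals))
}

#' League table of all pairwise comparisons
#'
#' Summarizes every pairwise contrast draw-wise: the cell in column `x`,
#' row `y` holds the posterior median and central 95% interval of
#' `exp(d_x - d_y)` (the ratio for the column treatment versus the row
#' treatment). Because cells are formed at the draw level, transitivity is
#' exact: the draw for x-vs-z is the product of the draws for x-vs-y and
#' y-vs-z.
#'
#' @param fit A consistency-model `nma_fit`, or a numeric matrix of draws
#'   of the log effect of each treatment versus a common reference (one
#'   named column per treatment, the reference itself a column of zeros) —
#'   useful for summarizing externally reconstructed posteriors.
#' @param scale `"OR"` or `"HR"` (label only).
#' @param order Display order of treatments; default: model order with the
#'   reference moved last (matrix input: column order).
#' @return A `league_table`: list of `point`, `ci_low`, `ci_high` matrices
#'   (column vs row), treatment order and scale.
#' @export
league_table <- function(fit, scale = c("OR", "HR"), order = NULL) {
  scale <- match.arg(scale)
  D <- draws_vs_reference(fit)
  if (is.null(order)) {
    order <- if (inherits(fit, "nma_fit")) {
      c(fit$model$treatments[-1], fit$model$treatments[1])
    } else {
      colnames(D)
    }
  }
  stopifnot(setequal(order, colnames(D)))
  k <- length(order)
  point <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(order, order))
  diag(point) <- diag(lo) <- diag(hi) <- 1
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      x <- order[i]; y <- order[j]
      ratio <- exp(D[, x] - D[, y])
      q <- stats::quantile(ratio, c(0.025, 0.5, 0.975), names = FALSE)
      point[y, x] <- q[2]; lo[y, x] <- q[1]; hi[y, x] <- q[3]
      # mirror cell by exact draw-wise reciprocity
      point[x, y] <- 1 / q[2]; lo[x, y] <- 1 / q[3]; hi[x, y] <- 1 / q[1]
    }
  }
  structure(list(point = point, ci_low = lo, ci_high = hi,
                 treatments = order, scale = scale),
            class = "league_table")
}

# draws of every treatment's log effect versus the common reference:
# columns named by treatment, reference column identically zero
draws_vs_reference <- function(fit) {
  if (inherits(fit, "nma_fit")) {
    trts <- fit$model$treatments
    m <- pooled_draws(fit)
    D <- vapply(trts, function(trt) {
      if (trt == trts[1]) rep(0, nrow(m)) else m[, paste0("d_", trt)]
    }, numeric(nrow(m)))
    colnames(D) <- trts
    return(D)
  }
  D <- as.matrix(fit)
  if (is.null(colnames(D))) {
    abort("draw matrices must carry treatment names as column names",
          class = "alk_validation_error")
  }
  D
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  cat(render_league_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' @export
tidy.league_table <- function(x, ...) {
  k <- length(x$treatments)
  idx <- which(upper.tri(matrix(0, k, k)) | lower.tri(matrix(0, k, k)),
               arr.ind = TRUE)
  tibble::tibble(
    treatment = x$treatments[idx[, "col"]],
    comparator = x$treatments[idx[, "row"]],
    scale = x$scale,
    estimate = x$point[idx],
    ci_low = x$ci_low[idx],
    ci_high = x$ci_high[idx]
  )
}

#' Posterior rank probabilities
#'
#' For every retained draw the treatments are ranked by their effect versus
#' the reference; rank 1 is the most favourable position under the chosen
#' direction. Entry (t, j) of the result is the fraction of draws in which
#' treatment t occupies rank j. Ties (measure zero for continuous draws)
#' break by treatment order.
#'
#' @param fit A consistency-model `nma_fit`, or a matrix of log-effect
#'   draws versus a common reference as in [league_table()].
#' @param lower_is_better `TRUE` when smaller effects are preferable (e.g.
#'   hazard ratios for progression); `FALSE` when larger effects are (e.g.
#'   response odds ratios). For the discontinuation endpoint the published
#'   convention ranks the *highest* rate first, i.e. `lower_is_better =
#'   FALSE`, so rank 4 is the safest drug.
#' @return A `rank_table`: probability matrix (treatments x ranks; rows and
#'   columns each sum to 1) plus the direction flag.
#' @export
rank_probabilities <- function(fit, lower_is_better = TRUE) {
  D <- draws_vs_reference(fit)
  D <- D[, sort(colnames(D)), drop = FALSE]   # tie-break: treatment id order
  if (!lower_is_better) D <- -D
  k <- ncol(D)
  counts <- matrix(0L, k, k, dimnames = list(colnames(D), paste0("rank_", 1:k)))
  rk <- t(apply(D, 1, rank, ties.method = "first"))
  if (k == 1) rk <- matrix(1L, nrow(D), 1)
  for (j in seq_len(k)) counts[j, ] <- tabulate(rk[, j], nbins = k)
  structure(list(prob = counts / nrow(D), lower_is_better = lower_is_better,
                 n_draws = nrow(D)),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, digits = 2, ...) {
  cat("Rank probabilities (rank 1 = ",
      if (x$lower_is_better) "lowest" else "highest", " effect; ",
      x$n_draws, " draws)\n", sep = "")
  print(round(x$prob, digits))
  invisible(x)
}

#' @export
tidy.rank_table <- function(x, ...) {
  tibble::as_tibble(x$prob, rownames = "treatment") |>
    tidyr::pivot_longer(-"treatment", names_to = "rank",
                        names_prefix = "rank_", values_to = "probability") |>
    dplyr::mutate(rank = as.integer(.data$rank))
}

#' @export
autoplot.rank_table <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rank, y = .data$probability,
                               fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "rank position", y = "posterior probability") +
    ggplot2::theme_minimal()
}

# posterior mean residual deviance of a fitted model
residual_deviance <- function(fit) {
  m <- pooled_draws(fit)
  w <- fit$model$trials
  n_tr <- nrow(w)
  if (fit$model$kind == "BINARY_ARM") {
    dev_arm <- function(r, n, p) {
      rhat <- n * p
      term1 <- ifelse(r > 0, r * log(r / rhat), 0)
      term2 <- ifelse(r < n, (n - r) * log((n - r) / (n - rhat)), 0)
      2 * (term1 + term2)
    }
    total <- 0
    for (i in seq_len(n_tr)) {
      mu <- m[, paste0("mu_", w$trial_id[i])]
      de <- m[, paste0("delta_", w$trial_id[i])]
      total <- total +
        mean(dev_arm(w$r_b[i], w$n_b[i], stats::plogis(mu))) +
        mean(dev_arm(w$r_t[i], w$n_t[i], stats::plogis(mu + de)))
    }
    total
  } else {
    total <- 0
    for (i in seq_len(n_tr)) {
      de <- m[, paste0("delta_", w$trial_id[i])]
      total <- total + mean(((w$y[i] - de) / w$se[i])^2)
    }
    total
  }
}

#' Compare consistency and inconsistency fits
#'
#' Fits the transitive (consistency) model and the unrelated-mean-effects
#' (inconsistency) model to the same network and reports, for every
#' directly observed edge, the posterior median and 95% interval of the
#' direct contrast under each model, together with the posterior mean
#' residual deviance of each fit. Material disagreement on an edge, or a
#' clearly lower deviance for the inconsistency model, signals conflict
#' between direct and indirect evidence. In a network without closed loops
#' the two models estimate the same quantities and should agree within
#' Monte-Carlo error; the report notes this degenerate case.
#'
#' @param network An `evidence_network` with outcome data attached.
#' @param spec An [nma_model_spec()] (its `consistency` flag is ignored).
#' @param settings An [mcmc_settings()].
#' @return A `consistency_report`: tibble of per-edge summaries plus
#'   deviances and a `has_loop` flag.
#' @export
compare_consistency <- function(network, spec = nma_model_spec(),
                                settings = mcmc_settings()) {
  spec_con <- spec; spec_con$consistency <- TRUE
  spec_inc <- spec; spec_inc$consistency <- FALSE
  fit_con <- run_mcmc(build_nma_model(network, spec_con), settings)
  fit_inc <- run_mcmc(build_nma_model(network, spec_inc), settings)

  w <- fit_con$model$trials
  edges <- unique(w[, c("t_trt", "b_trt")])
  per_edge <- purrr::pmap_dfr(edges, function(t_trt, b_trt) {
    con <- contrast_draws(fit_con, t_trt, b_trt)
    inc <- pooled_draws(fit_inc)[, paste0("d_", t_trt, "_vs_", b_trt)]
    qc <- stats::quantile(con, c(0.025, 0.5, 0.975), names = FALSE)
    qi <- stats::quantile(inc, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(
      treatment = t_trt, comparator = b_trt,
      consistency_median = qc[2], consistency_low = qc[1], consistency_high = qc[3],
      inconsistency_median = qi[2], inconsistency_low = qi[1],
      inconsistency_high = qi[3],
      intervals_overlap = qc[1] <= qi[3] & qi[1] <= qc[3]
    )
  })
  n_nodes <- length(fit_con$model$treatments)
  has_loop <- nrow(edges) >= n_nodes   # connected graph: E >= V implies a cycle
  structure(list(edges = per_edge,
                 deviance_consistency = residual_deviance(fit_con),
                 deviance_inconsistency = residual_deviance(fit_inc),
                 has_loop = has_loop,
                 fits = list(consistency = fit_con, inconsistency = fit_inc)),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  if (!x$has_loop) {
    cat("Network has no closed loop: consistency and inconsistency models",
        "estimate the same contrasts (comparison is degenerate).\n")
  }
  print(x$edges)
  cat(sprintf("Posterior mean residual deviance: consistency %.2f, inconsistency %.2f\n",
              x$deviance_consistency, x$deviance_inconsistency))
  invisible(x)
}

#' Coherence check: direct pairwise pooling versus the network model
#'
#' For every directly compared treatment pair, pools the per-trial contrasts
#' classically (DerSimonian-Laird random effects on the log scale; binary
#' arms get a 0.5 continuity correction when a cell is zero) and sets the
#' result against the posterior median and 95% interval of the same
#' contrast from the Bayesian network fit. Pairs whose intervals fail to
#' overlap are flagged.
#'
#' @param network An `evidence_network` with outcome data.
#' @param spec An [nma_model_spec()].
#' @param settings An [mcmc_settings()].
#' @param fit Optionally, a pre-computed consistency `nma_fit` for this
#'   network (skips resampling).
#' @return A tibble with one row per direct comparison: DL estimate and CI,
#'   NMA posterior median and CrI, and a `flagged` column.
#' @export
pairwise_vs_nma_check <- function(network, spec = nma_model_spec(),
                                  settings = mcmc_settings(), fit = NULL) {
  if (is.null(fit)) {
    spec$consistency <- TRUE
    fit <- run_mcmc(build_nma_model(network, spec), settings)
  }
  w <- fit$model$trials
  binary <- fit$model$kind == "BINARY_ARM"
  edges <- unique(w[, c("t_trt", "b_trt")])
  purrr::pmap_dfr(edges, function(t_trt, b_trt) {
    sub <- w[w$t_trt == t_trt & w$b_trt == b_trt, ]
    if (binary) {
      cc <- with(sub, r_t == 0 | r_t == n_t | r_b == 0 | r_b == n_b) * 0.5
      y <- log((sub$r_t + cc) / (sub$n_t - sub$r_t + cc)) -
        log((sub$r_b + cc) / (sub$n_b - sub$r_b + cc))
      se <- sqrt(1 / (sub$r_t + cc) + 1 / (sub$n_t - sub$r_t + cc) +
                   1 / (sub$r_b + cc) + 1 / (sub$n_b - sub$r_b + cc))
    } else {
      y <- sub$y; se <- sub$se
    }
    dl <- pool_inverse_variance(tibble::tibble(y = y, se = se),
                                model = "RANDOM", scale = "log")
    dr <- contrast_draws(fit, t_trt, b_trt)
    q <- stats::quantile(dr, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(
      treatment = t_trt, comparator = b_trt, k = nrow(sub),
      dl_estimate = dl$estimate, dl_low = dl$ci_low, dl_high = dl$ci_high,
      nma_median = q[2], nma_low = q[1], nma_high = q[3],
      flagged = !(dl$ci_low <= q[3] & q[1] <= dl$ci_high)
    )
  })
}
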