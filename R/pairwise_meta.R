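#' Cochran heterogeneity statistics
#'
#' Computes Cochran's Q against the fixed-effect (inverse-variance) pooled
#' estimate, its chi-square p-value on `k - 1` degrees of freedom, and the
#' I-squared statistic `I2 = max(0, (Q - df) / Q) * 100` (0 when `Q = 0`).
#'
#' @param data A data frame with one row per study.
#' @param y,se Columns holding the effect on the analysis scale and its
#'   standard error (tidy-eval; defaults `y`, `se`).
#' @return A one-row tibble with `Q`, `df`, `p_Q`, `I2`, `k`.
#' @export
#' @examples
#' cochran_heterogeneity(data.frame(y = c(0, 1), se = c(1, 1)))
cochran_heterogeneity <- function(data, y = y, se = se) {
  yv <- dplyr::pull(data, {{ y }})
  sev <- dplyr::pull(data, {{ se }})
  check_effects(yv, sev)
  k <- length(yv)
  w <- 1 / sev^2
  yhat <- sum(w * yv) / sum(w)
  Q <- sum(w * (yv - yhat)^2)
  df <- k - 1L
  p_Q <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tibble::tibble(Q = Q, df = df, p_Q = p_Q, I2 = I2, k = k)
}

check_effects <- function(y, se) {
  if (length(y) == 0) {
    abort("no studies supplied", class = "alk_empty_input_error")
  }
  if (any(!is.finite(y)) || any(!is.finite(se)) || any(se <= 0)) {
    abort("every study needs a finite effect and a positive standard error",
          class = "alk_validation_error")
  }
  invisible(NULL)
}

#' Heterogeneity-driven model choice
#'
#' The model-selection rule applied throughout the pipeline: a fixed-effects
#' model when the heterogeneity test is non-significant (`p_Q > 0.1`) and
#' I-squared is below 50%; otherwise a random-effects model.
#'
#' @param p_Q Cochran test p-value.
#' @param I2 I-squared, on the 0-100 percentage scale.
#' @return `"FIXED"` or `"RANDOM"`.
#' @export
#' @examples
#' select_model(0.5, 10)  # FIXED
#' select_model(0.1, 0)   # RANDOM (boundary p)
select_model <- function(p_Q, I2) {
  stopifnot(p_Q >= 0, p_Q <= 1, I2 >= 0, I2 <= 100)
  if (p_Q > 0.1 && I2 < 50) "FIXED" else "RANDOM"
}

#' Inverse-variance pooling with DerSimonian-Laird random effects
#'
#' Fixed-effects weights are `1/se^2`; the random-effects model uses the
#' DerSimonian-Laird moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` and weights
#' `1/(se^2 + tau2)`. The 95% interval is `estimate +/- 1.959964 *
#' sum(w)^(-1/2)`. With `model = "auto"` the choice follows
#' [select_model()].
#'
#' @inheritParams cochran_heterogeneity
#' @param model `"FIXED"`, `"RANDOM"`, or `"auto"`.
#' @param scale Label for the analysis scale, carried into the result
#'   (e.g. `"log_or"`, `"log_hr"`, `"logit"`, `"months"`).
#' @return A `pooled_result` (one-row tibble with `estimate`, `ci_low`,
#'   `ci_high`, `se`, `Q`, `df`, `p_Q`, `I2`, `tau2`, `model`, `k`,
#'   `scale`).
#' @export
#' @examples
#' d <- data.frame(y = c(0.4, 0.6), se = c(0.1, 0.1))
#' pool_inverse_variance(d, model = "FIXED")
pool_inverse_variance <- function(data, y = y, se = se, model = "auto",
                                  scale = "effect") {
  yv <- dplyr::pull(data, {{ y }})
  sev <- dplyr::pull(data, {{ se }})
  check_effects(yv, sev)
  het <- cochran_heterogeneity(tibble::tibble(y = yv, se = sev))
  model <- match.arg(toupper(model), c("AUTO", "FIXED", "RANDOM"))
  if (model == "AUTO") model <- select_model(het$p_Q, het$I2)
  w_f <- 1 / sev^2
  tau2 <- 0
  if (model == "RANDOM") {
    denom <- sum(w_f) - sum(w_f^2) / sum(w_f)
    tau2 <- if (denom > 0) max(0, (het$Q - het$df) / denom) else 0
  }
  w <- 1 / (sev^2 + tau2)
  est <- sum(w * yv) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  out <- tibble::tibble(
    estimate = est,
    ci_low = est - Z975 * se_pool,
    ci_high = est + Z975 * se_pool,
    se = se_pool,
    Q = het$Q, df = het$df, p_Q = het$p_Q, I2 = het$I2,
    tau2 = tau2, model = model, k = het$k, scale = scale
  )
  structure(out, class = c("pooled_result", class(out)))
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled %s (%s effects, k = %d): %.4f (95%% CI %.4f to %.4f)\n",
              x$scale, tolower(x$model), x$k, x$estimate, x$ci_low, x$ci_high))
  cat(sprintf("Heterogeneity: Q = %.3f (df = %d, p = %.4f), I2 = %.1f%%, tau2 = %.4f\n",
              x$Q, x$df, x$p_Q, x$I2, x$tau2))
  invisible(x)
}

#' @export
tidy.pooled_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("estimate", "ci_low", "ci_high", "se", "model",
                           "k", "scale")]
}

#' @export
glance.pooled_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("Q", "df", "p_Q", "I2", "tau2", "model", "k")]
}

#' Pool event proportions on the logit scale
#'
#' Each study's proportion is mapped to `logit(p)` with standard error
#' `sqrt(1/events + 1/(n - events))`; studies with zero or all events get a
#' 0.5 continuity correction added to both cells. Pooling is by
#' [pool_inverse_variance()] on the logit scale, and the estimate and CI are
#' back-transformed to the probability scale (so the interval always lies in
#' \[0, 1\]).
#'
#' @param data A data frame of single-arm (or arm-level) studies.
#' @param events,n Columns with event count and arm size.
#' @param model Model choice as in [pool_inverse_variance()].
#' @return A `pooled_result` on the proportion scale (the `Q`, `I2`, `tau2`
#'   components refer to the logit scale on which pooling happened).
#' @export
#' @examples
#' pool_proportions(data.frame(events = c(30, 40), n = c(50, 50)))
pool_proportions <- function(data, events = events, n = n, model = "auto") {
  r <- dplyr::pull(data, {{ events }})
  nn <- dplyr::pull(data, {{ n }})
  if (length(r) == 0) abort("no studies supplied", class = "alk_empty_input_error")
  if (any(nn < 1) || any(r < 0) || any(r > nn)) {
    abort("proportion studies require 0 <= events <= n and n >= 1",
          class = "alk_validation_error")
  }
  boundary <- r == 0 | r == nn
  a <- r + 0.5 * boundary
  b <- (nn - r) + 0.5 * boundary
  eff <- tibble::tibble(y = log(a / b), se = sqrt(1 / a + 1 / b))
  pooled <- pool_inverse_variance(eff, model = model, scale = "logit")
  pooled$estimate <- stats::plogis(pooled$estimate)
  pooled$ci_low <- stats::plogis(pooled$ci_low)
  pooled$ci_high <- stats::plogis(pooled$ci_high)
  pooled$scale <- "proportion"
  pooled
}

#' Pool reported medians (e.g. median progression-free survival)
#'
#' The standard error of each median is inferred from its reported 95%
#' interval as `(ci_high - ci_low) / (2 * 1.959964)` and the medians are
#' pooled by inverse variance directly on the months scale. Pooling medians
#' this way assumes approximate normality of the reported medians and is
#' fragile when follow-up differs strongly between studies; prefer
#' reconstructed individual-patient data ([km_estimator()]) when curves are
#' available.
#'
#' @param data A data frame of studies.
#' @param median,ci_low,ci_high Columns with the median and its 95% CI.
#' @param model Model choice as in [pool_inverse_variance()].
#' @return A `pooled_result` in months. Studies missing either CI bound are
#'   dropped with a warning.
#' @export
pool_medians <- function(data, median = median, ci_low = ci_low,
                         ci_high = ci_high, model = "auto") {
  m <- dplyr::pull(data, {{ median }})
  lo <- dplyr::pull(data, {{ ci_low }})
  hi <- dplyr::pull(data, {{ ci_high }})
  keep <- !is.na(lo) & !is.na(hi)
  if (any(!keep)) {
    warn(sprintf("dropping %d study(ies) with missing median CI", sum(!keep)))
    m <- m[keep]; lo <- lo[keep]; hi <- hi[keep]
  }
  if (length(m) == 0) abort("no studies with usable CIs", class = "alk_empty_input_error")
  if (any(lo > m | m > hi)) {
    abort("median CI must bracket the median", class = "alk_validation_error")
  }
  eff <- tibble::tibble(y = m, se = (hi - lo) / (2 * Z975))
  pool_inverse_variance(eff, model = model, scale = "months")
}

#' Pool within subgroups
#'
#' Runs a pooling function independently within each level of one or more
#' grouping labels (typically drug and pretreatment status) and once
#' overall.
#'
#' @param data A data frame of studies carrying the grouping columns.
#' @param ... Grouping columns (tidy-eval), e.g. `drug, pretreatment`.
#' @param .f Pooling function taking the data subset first; defaults to
#'   [pool_proportions()].
#' @param .args Extra arguments passed to `.f`.
#' @return A tibble with one row per subgroup plus an `".overall"` row;
#'   grouping columns are retained, pooled columns follow.
#' @export
#' @examples
#' d <- data.frame(drug = c("a", "a", "b"), events = c(5, 6, 20), n = c(50, 60, 55))
#' subgroup_pool(d, drug)
subgroup_pool <- function(data, ..., .f = pool_proportions, .args = list()) {
  data <- tibble::as_tibble(data)
  groups <- dplyr::group_by(data, ...)
  labels <- dplyr::group_keys(groups)
  if (ncol(labels) == 0) {
    abort("supply at least one grouping column", class = "alk_validation_error")
  }
  parts <- dplyr::group_split(groups)
  per <- purrr::map2_dfr(parts, seq_along(parts), function(d, i) {
    res <- do.call(.f, c(list(d), .args))
    dplyr::bind_cols(labels[i, , drop = FALSE], tibble::as_tibble(res))
  })
  overall <- do.call(.f, c(list(data), .args))
  overall <- dplyr::bind_cols(
    tibble::as_tibble(stats::setNames(as.list(rep(".overall", ncol(labels))),
                                      names(labels))),
    tibble::as_tibble(overall)
  )
  dplyr::bind_rows(per, overall)
}
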