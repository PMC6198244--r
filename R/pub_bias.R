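#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `y/se` on precision
#' `1/se`; the test statistic is the two-sided t test (df `k - 2`) of the
#' intercept. A non-zero intercept indicates small-study asymmetry of the
#' funnel plot.
#'
#' @param data A data frame with one row per study.
#' @param y,se Effect and standard-error columns (tidy-eval).
#' @return A one-row tibble (`method = "EGGER"`) with `intercept`, `slope`,
#'   `statistic` (intercept t), `df`, `p`, `k`.
#' @export
#' @examples
#' d <- data.frame(y = c(-0.2, 0, 0.2, 0.5), se = c(0.1, 0.2, 0.3, 0.4))
#' egger_test(d)
egger_test <- function(data, y = y, se = se) {
  yv <- dplyr::pull(data, {{ y }})
  sev <- dplyr::pull(data, {{ se }})
  check_effects(yv, sev)
  k <- length(yv)
  if (k < 3) {
    abort("Egger's test needs at least 3 studies",
          class = "alk_insufficient_studies_error")
  }
  fit <- stats::lm(I(yv / sev) ~ I(1 / sev))
  sm <- summary(fit)$coefficients
  tibble::tibble(
    method = "EGGER",
    intercept = sm[1, 1],
    slope = sm[2, 1],
    statistic = sm[1, 3],
    df = k - 2L,
    p = sm[1, 4],
    k = k
  )
}

#' Begg-Mazumdar rank-correlation test
#'
#' Kendall's tau between the variance-standardized deviations from the
#' fixed-effect pooled estimate and the study variances, with the
#' tie-corrected normal approximation for the p-value (no continuity
#' correction by default).
#'
#' @inheritParams egger_test
#' @param continuity Apply the 0.5 continuity correction to the normal
#'   approximation (default `FALSE`).
#' @return A one-row tibble (`method = "BEGG"`) with `kendall_tau`,
#'   `statistic` (normalized z), `p`, `k`.
#' @export
begg_test <- function(data, y = y, se = se, continuity = FALSE) {
  yv <- dplyr::pull(data, {{ y }})
  sev <- dplyr::pull(data, {{ se }})
  check_effects(yv, sev)
  k <- length(yv)
  if (k < 3) {
    abort("Begg's test needs at least 3 studies",
          class = "alk_insufficient_studies_error")
  }
  w <- 1 / sev^2
  pooled <- sum(w * yv) / sum(w)
  v_star <- sev^2 - 1 / sum(w)
  v_star[v_star <= 0] <- .Machine$double.eps
  t_i <- (yv - pooled) / sqrt(v_star)
  ct <- suppressWarnings(
    stats::cor.test(t_i, sev^2, method = "kendall", exact = FALSE,
                    continuity = continuity)
  )
  tibble::tibble(
    method = "BEGG",
    kendall_tau = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p = ct$p.value,
    k = k
  )
}

#' Funnel-plot coordinates with pseudo-95% guide lines
#'
#' @inheritParams egger_test
#' @param study_id Optional study-label column.
#' @return A list of tibbles: `points` (`study_id`, `y`, `se`, `precision`,
#'   `snd`) and `guides` (`se`, `lower`, `upper`) tracing
#'   `pooled +/- 1.959964 * se` over the observed standard-error range,
#'   plus the fixed-effect `pooled` value.
#' @export
funnel_coordinates <- function(data, y = y, se = se, study_id = NULL) {
  yv <- dplyr::pull(data, {{ y }})
  sev <- dplyr::pull(data, {{ se }})
  check_effects(yv, sev)
  ids <- if (rlang::quo_is_null(rlang::enquo(study_id))) {
    as.character(seq_along(yv))
  } else {
    as.character(dplyr::pull(data, {{ study_id }}))
  }
  w <- 1 / sev^2
  pooled <- sum(w * yv) / sum(w)
  se_grid <- seq(0, max(sev) * 1.05, length.out = 50)
  list(
    points = tibble::tibble(study_id = ids, y = yv, se = sev,
                            precision = 1 / sev, snd = yv / sev),
    guides = tibble::tibble(se = se_grid,
                            lower = pooled - Z975 * se_grid,
                            upper = pooled + Z975 * se_grid),
    pooled = pooled
  )
}

#' Funnel plot
#'
#' @param data A data frame of studies with effect and standard-error
#'   columns.
#' @inheritParams funnel_coordinates
#' @return A ggplot: effects against standard error (inverted axis) with
#'   pseudo-95% guide lines.
#' @export
plot_funnel <- function(data, y = y, se = se, study_id = NULL) {
  fc <- funnel_coordinates(data, {{ y }}, {{ se }}, {{ study_id }})
  ggplot2::ggplot() +
    ggplot2::geom_line(data = tidyr::pivot_longer(fc$guides, c("lower", "upper")),
                       ggplot2::aes(x = .data$value, y = .data$se, group = .data$name),
                       linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = fc$pooled, colour = "grey40") +
    ggplot2::geom_point(data = fc$points, ggplot2::aes(x = .data$y, y = .data$se)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "effect", y = "standard error") +
    ggplot2::theme_minimal()
}
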