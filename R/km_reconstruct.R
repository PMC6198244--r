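#' Clean digitized survival-curve coordinates
#'
#' Repairs digitizer noise in curve coordinates: clamps survival to
#' \[0, 1\], deduplicates repeated times (keeping the last reading),
#' prepends the point (0, 1) when absent, and projects the probabilities
#' onto the nearest non-increasing sequence (isotonic regression).
#' Idempotent for curves that are already clean.
#'
#' @param points A data frame with columns `t` (months, >= 0) and `s`
#'   (survival probability).
#' @return A tibble (`t`, `s`) sorted by time, `s(0) = 1`, non-increasing.
#' @export
#' @examples
#' clean_curve(data.frame(t = c(1, 2, 3), s = c(0.81, 0.82, 0.60)))
clean_curve <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("t", "s") %in% names(points)))
  if (any(points$t < 0)) {
    abort("curve times must be non-negative", class = "alk_validation_error")
  }
  points <- points[order(points$t), ]
  points <- points[!duplicated(points$t, fromLast = TRUE), ]  # keep last reading
  points$s <- pmin(1, pmax(0, points$s))
  if (points$t[1] != 0) {
    points <- dplyr::bind_rows(tibble::tibble(t = 0, s = 1), points)
  }
  points$s[1] <- 1
  if (nrow(points) < 2) {
    abort("a curve needs at least 2 distinct time points",
          class = "alk_validation_error")
  }
  # isotonic (non-increasing) least-squares projection
  iso <- stats::isoreg(points$t, -points$s)
  points$s <- pmin(1, pmax(0, -iso$yf))
  points$s[1] <- 1
  points
}

# step-function value of a cleaned curve at arbitrary times
curve_step_at <- function(curve, times) {
  idx <- findInterval(times, curve$t)
  curve$s[pmax(idx, 1)]
}

#' Reconstruct interval event and censoring counts from a digitized curve
#'
#' Applies the Tierney-style relation between successive survival
#' probabilities and the number at risk: within the interval from `t_j` to
#' `t_{j+1}` with `n_j` at risk, the event count is
#' `d_j = round(n_j * (S(t_j) - S(t_{j+1})) / S(t_j))` and the censored
#' count is the residual attrition `c_j = n_j - d_j - n_{j+1}` (floored at
#' zero, with any negative remainder re-allocated to the events).
#'
#' With an at-risk table, its times define the interval boundaries and the
#' censored counts are identified from the published numbers at risk. This
#' is the reliable variant. Without one, `total_n` seeds the first interval,
#' each curve step becomes an interval, and zero within-interval censoring
#' is assumed — attrition beyond the curve drops is then invisible, the
#' dominant source of reconstruction error for digitized figures.
#'
#' @param curve A cleaned curve (see [clean_curve()]); cleaning is applied
#'   if needed.
#' @param at_risk Optional data frame (`t`, `n_risk`), non-increasing in
#'   `t`.
#' @param total_n Initial number at risk; required when `at_risk` is
#'   absent.
#' @return A tibble of intervals (`t_start`, `t_end`, `d`, `c`,
#'   `n_start`, `n_end`) satisfying `n_end = n_start - d - c`, with an
#'   `"events"` attribute holding the within-interval event placement times
#'   used by [expand_ipd()].
#' @export
reconstruct_intervals <- function(curve, at_risk = NULL, total_n = NULL) {
  curve <- clean_curve(curve)
  if (is.null(at_risk)) {
    if (is.null(total_n)) {
      abort("supply an at-risk table or total_n", class = "alk_validation_error")
    }
    at_risk <- tibble::tibble(t = curve$t[1], n_risk = as.integer(total_n))
  }
  at_risk <- tibble::as_tibble(at_risk)[order(at_risk$t), ]
  if (any(diff(at_risk$n_risk) > 0)) {
    abort("numbers at risk must be non-increasing in time",
          class = "alk_validation_error")
  }

  # interval boundaries: at-risk times, closed by the end of the curve
  bounds <- unique(c(at_risk$t, max(curve$t, at_risk$t)))
  n_known <- c(at_risk$n_risk, NA_integer_)[seq_along(bounds)]
  out <- vector("list", length(bounds) - 1)
  events <- vector("list", length(bounds) - 1)
  n_cur <- at_risk$n_risk[1]

  for (j in seq_len(length(bounds) - 1)) {
    t0 <- bounds[j]; t1 <- bounds[j + 1]
    s0 <- curve_step_at(curve, t0)
    s1 <- curve_step_at(curve, t1)
    if (s0 == 0 && n_cur > 0) {
      abort(sprintf("degenerate interval at t = %g: S = 0 with %d still at risk",
                    t0, n_cur),
            class = "alk_validation_error")
    }
    d <- if (s0 > 0) round(n_cur * (s0 - s1) / s0) else 0
    d <- min(max(d, 0), n_cur)
    n_next <- n_known[j + 1]
    if (!is.na(n_next)) {
      cc <- n_cur - d - n_next
      if (cc < 0) {            # re-allocate the negative remainder to events
        d <- n_cur - n_next
        cc <- 0
      }
    } else {
      cc <- 0                  # open-ended tail: no censoring assumed
      n_next <- n_cur - d
    }

    # place events at the digitized drop times inside (t0, t1]
    drops <- curve[curve$t > t0 & curve$t <= t1, ]
    prev_s <- c(s0, drops$s)
    rel <- ifelse(utils::head(prev_s, -1) > 0,
                  (utils::head(prev_s, -1) - drops$s) / utils::head(prev_s, -1), 0)
    if (d > 0 && nrow(drops) > 0 && sum(rel) > 0) {
      alloc <- largest_remainder(d * rel / sum(rel), d)
      ev <- drops$t[alloc > 0]
      ev_n <- alloc[alloc > 0]
    } else if (d > 0) {
      ev <- t0 + .Machine$double.eps * max(1, t0)   # no visible drop: interval start
      ev_n <- d
    } else {
      ev <- numeric(0); ev_n <- integer(0)
    }
    events[[j]] <- tibble::tibble(time = ev, count = as.integer(ev_n))
    out[[j]] <- tibble::tibble(t_start = t0, t_end = t1, d = as.integer(d),
                               c = as.integer(cc), n_start = as.integer(n_cur),
                               n_end = as.integer(n_next))
    n_cur <- n_next
  }
  res <- dplyr::bind_rows(out)
  attr(res, "events") <- events
  res
}

# round non-negative reals to integers preserving their sum
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Expand interval counts into pseudo individual-patient data
#'
#' Events are placed at the digitized drop times recorded by
#' [reconstruct_intervals()] (interval start when no drop is visible);
#' censored patients are placed at the interval midpoint. This placement
#' reproduces the input curve at the interval boundaries when the counts
#' are exact.
#'
#' @param intervals Output of [reconstruct_intervals()].
#' @param treatment_id,trial_id Labels stamped on every record.
#' @return A tibble of records (`time`, `event`, `treatment_id`,
#'   `trial_id`), one per patient who left the risk set.
#' @export
expand_ipd <- function(intervals, treatment_id = "treatment",
                       trial_id = "trial") {
  ev_list <- attr(intervals, "events")
  rows <- purrr::map_dfr(seq_len(nrow(intervals)), function(j) {
    iv <- intervals[j, ]
    ev <- if (!is.null(ev_list)) {
      ev_list[[j]]
    } else if (iv$d > 0) {
      tibble::tibble(time = iv$t_start, count = iv$d)
    } else {
      tibble::tibble(time = numeric(0), count = integer(0))
    }
    dplyr::bind_rows(
      if (nrow(ev) > 0) {
        tibble::tibble(time = rep(ev$time, ev$count), event = 1L)
      },
      if (iv$c > 0) {
        tibble::tibble(time = rep((iv$t_start + iv$t_end) / 2, iv$c), event = 0L)
      }
    )
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(time = numeric(0), event = integer(0),
                          treatment_id = character(0), trial_id = character(0)))
  }
  dplyr::mutate(rows, treatment_id = treatment_id, trial_id = trial_id)
}

#' Reconstruct pseudo-IPD straight from a digitized curve
#'
#' Convenience wrapper chaining [clean_curve()], [reconstruct_intervals()]
#' and [expand_ipd()].
#'
#' @inheritParams reconstruct_intervals
#' @inheritParams expand_ipd
#' @return A tibble of pseudo individual-patient records.
#' @export
reconstruct_ipd <- function(curve, at_risk = NULL, total_n = NULL,
                            treatment_id = "treatment", trial_id = "trial") {
  expand_ipd(reconstruct_intervals(curve, at_risk, total_n),
             treatment_id = treatment_id, trial_id = trial_id)
}

#' Product-limit (Kaplan-Meier) estimate
#'
#' Fits the product-limit estimator with Greenwood variance via
#' [survival::survfit()]. The median is the smallest time with survival at
#' or below 0.5; its 95% interval comes from inverting the survival CI
#' (Brookmeyer-Crowley), using the log-log transform by default or the
#' linear (`"plain"`) variant.
#'
#' @param ipd A data frame of records (`time`, `event`).
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return A `km_estimate`: the `survfit` object plus tidy `steps`
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`,
#'   `ci_low`, `ci_high`) and a `median` row (`median`, `ci_low`,
#'   `ci_high`; `NA` when the curve never reaches 0.5, i.e. median not
#'   reached).
#' @export
km_estimator <- function(ipd, conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  ipd <- tibble::as_tibble(ipd)
  if (nrow(ipd) == 0) {
    abort("no records supplied", class = "alk_empty_input_error")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                           conf.type = conf_type)
  # median: smallest time with S(t) <= 0.5; CI by inverting the pointwise
  # survival band at 0.5 (Brookmeyer-Crowley)
  first_at_or_below <- function(v) {
    hit <- which(!is.na(v) & v <= 0.5)
    if (length(hit) == 0) NA_real_ else fit$time[hit[1]]
  }
  med <- tibble::tibble(median = first_at_or_below(fit$surv),
                        ci_low = first_at_or_below(fit$lower),
                        ci_high = first_at_or_below(fit$upper))
  steps <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    std_err = fit$surv * fit$std.err,   # Greenwood SE of S(t)
    ci_low = fit$lower, ci_high = fit$upper
  )
  structure(list(fit = fit, steps = steps, median = med, n = nrow(ipd)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  med <- x$median
  cat(sprintf("Kaplan-Meier estimate on %d records, %d events\n",
              x$n, sum(x$steps$n_event)))
  if (is.na(med$median)) {
    cat("Median: not reached\n")
  } else {
    cat(sprintf("Median: %.3f months (95%% CI %.3f to %.3f)\n",
                med$median, med$ci_low, med$ci_high))
  }
  invisible(x)
}

#' @export
tidy.km_estimate <- function(x, ...) x$steps

#' @export
glance.km_estimate <- function(x, ...) {
  dplyr::mutate(x$median, n = x$n, events = sum(x$steps$n_event))
}

#' @export
autoplot.km_estimate <- function(object, ...) {
  st <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, ci_low = 1, ci_high = 1),
    tidy(object)
  )
  ggplot2::ggplot(st, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_low), linetype = 3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_high), linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Pool reconstructed IPD across trials
#'
#' Naive concatenation of per-trial pseudo-IPD, keeping the trial label for
#' optional stratification. All inputs must use the same time unit; if a
#' `time_unit` column is present its values must agree.
#'
#' @param ... Data frames of IPD records (`time`, `event`,
#'   `treatment_id`, `trial_id`), or a single list of them.
#' @return A single tibble of records across all trials.
#' @export
pool_ipd <- function(...) {
  parts <- rlang::list2(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]])) {
    parts <- parts[[1]]
  }
  out <- dplyr::bind_rows(parts)
  if ("time_unit" %in% names(out) && dplyr::n_distinct(out$time_unit) > 1) {
    abort("IPD inputs use different time units", class = "alk_validation_error")
  }
  out
}

#' Kaplan-Meier estimates per treatment
#'
#' @param ipd Pooled IPD with a `treatment_id` column.
#' @param conf_type Passed to [km_estimator()].
#' @return A named list of `km_estimate` objects, one per treatment.
#' @export
km_by_treatment <- function(ipd, conf_type = "log-log") {
  parts <- split(tibble::as_tibble(ipd), ipd$treatment_id)
  purrr::map(parts, km_estimator, conf_type = conf_type)
}

#' K-sample log-rank test
#'
#' The standard log-rank chi-square statistic with hypergeometric variance
#' across event times, via [survival::survdiff()]; optionally stratified by
#' trial (recommended for IPD pooled across trials, since it compares
#' treatments within trials rather than across them).
#'
#' @param ipd IPD records with a grouping column.
#' @param group Grouping column (tidy-eval; default `treatment_id`).
#' @param stratify_by_trial Stratify on `trial_id` (default `FALSE`,
#'   matching an unstratified pooled analysis).
#' @return A one-row tibble (`chi2`, `df`, `p`, `groups`).
#' @export
logrank_test <- function(ipd, group = treatment_id, stratify_by_trial = FALSE) {
  ipd <- tibble::as_tibble(ipd)
  g <- factor(dplyr::pull(ipd, {{ group }}))
  if (nlevels(g) < 2) {
    abort("log-rank test needs at least 2 groups", class = "alk_validation_error")
  }
  if (any(table(g) == 0)) {
    abort("every group needs at least one record", class = "alk_validation_error")
  }
  df <- data.frame(time = ipd$time, event = ipd$event, g = g)
  if (stratify_by_trial) {
    df$strat <- factor(ipd$trial_id)
    sd <- survival::survdiff(
      survival::Surv(time, event) ~ g + survival::strata(strat), data = df)
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  }
  dof <- nlevels(g) - 1L
  tibble::tibble(chi2 = sd$chisq, df = dof,
                 p = stats::pchisq(sd$chisq, dof, lower.tail = FALSE),
                 groups = nlevels(g))
}

#' Read digitized curve points / at-risk tables
#'
#' @param path CSV with columns `trial_id`, `treatment`, `t`, `s` (curve
#'   points) or `trial_id`, `treatment`, `t`, `n_risk` (at-risk rows).
#' @return A tibble.
#' @export
read_km_points_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(c("trial_id", "treatment", "t", "s"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("KM points CSV missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "alk_format_error")
  }
  x
}

#' @rdname read_km_points_csv
#' @export
read_at_risk_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(c("trial_id", "treatment", "t", "n_risk"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("at-risk CSV missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "alk_format_error")
  }
  x
}
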