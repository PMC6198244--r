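#' Read a trial-characteristics table
#'
#' Reads a comma-separated table with one row per treatment arm and validates
#' it into the arm-level trial representation used throughout the package.
#' The packaged fixture `trials.csv` (see [alk_trials_fixture()]) transcribes
#' the characteristics of 33 ALK-inhibitor trials: 8 randomized controlled
#' trials and 25 single-arm studies, 5507 participants in total.
#'
#' Required columns are `trial_id`, `design` (`RCT` or `SINGLE_ARM`),
#' `treatment`, `n` (arm size) and `pretreatment` (`ALKI_NAIVE`,
#' `PRETREATED` or `MIXED`). Extra columns (trial phase, follow-up,
#' quality labels) are carried through untouched; quality labels are stored
#' verbatim and never interpreted numerically. The literal string `"NA"`
#' parses to missing.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble of arms (class `alk_trials`), one row per arm, arm order
#'   as in the file.
#' @export
#' @examples
#' trials <- read_trials_csv(alk_trials_fixture())
#' dplyr::n_distinct(trials$trial_id)
#' sum(trials$n)
read_trials_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("trial file not found: ", path), class = "alk_validation_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = "character", check.names = TRUE)
  required <- c("trial_id", "design", "treatment", "n", "pretreatment")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("trial CSV is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "alk_format_error")
  }
  raw <- tibble::as_tibble(raw)
  n_num <- suppressWarnings(as.numeric(raw$n))
  bad <- which(!is.na(raw$n) & (is.na(n_num) | n_num != round(n_num) | n_num < 1))
  if (length(bad) > 0) {
    abort(paste0("unparseable arm size 'n' on data row(s): ",
                 paste(bad, collapse = ", ")),
          class = "alk_format_error")
  }
  raw$n <- as.integer(n_num)
  if ("median_followup_months" %in% names(raw)) {
    raw$median_followup_months <- suppressWarnings(as.numeric(raw$median_followup_months))
  }
  validate_trials(raw)
}

#' Validate an arm-level trial table
#'
#' @param arms A data frame with one row per arm.
#' @return The validated tibble with class `alk_trials`.
#' @export
validate_trials <- function(arms) {
  arms <- tibble::as_tibble(arms)
  if (nrow(arms) == 0) {
    return(structure(arms, class = c("alk_trials", class(arms))))
  }
  dup <- duplicated(arms[, c("trial_id", "treatment")])
  if (any(dup)) {
    abort(paste0("duplicate (trial_id, treatment) arm row(s): ",
                 paste(unique(arms$trial_id[dup]), collapse = ", ")),
          class = "alk_validation_error")
  }
  bad_design <- setdiff(unique(arms$design), c("RCT", "SINGLE_ARM"))
  if (length(bad_design) > 0) {
    abort(paste0("unknown design value(s): ", paste(bad_design, collapse = ", ")),
          class = "alk_validation_error")
  }
  per_trial <- dplyr::count(arms, .data$trial_id, .data$design)
  bad_rct <- per_trial$trial_id[per_trial$design == "RCT" & per_trial$n < 2]
  if (length(bad_rct) > 0) {
    abort(paste0("RCT with fewer than 2 arms: ", paste(bad_rct, collapse = ", ")),
          class = "alk_validation_error")
  }
  bad_sa <- per_trial$trial_id[per_trial$design == "SINGLE_ARM" & per_trial$n != 1]
  if (length(bad_sa) > 0) {
    abort(paste0("single-arm trial with more than one arm: ",
                 paste(bad_sa, collapse = ", ")),
          class = "alk_validation_error")
  }
  structure(arms, class = unique(c("alk_trials", class(arms))))
}

#' Write an arm-level trial table to CSV
#'
#' Inverse of [read_trials_csv()]: `read_trials_csv(write_trials_csv(x, f))`
#' reproduces every field value exactly.
#'
#' @param trials An `alk_trials` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

#' Path to the packaged trial-characteristics fixture
#'
#' @return Path to `trials.csv` inside the installed package.
#' @export
alk_trials_fixture <- function() {
  system.file("extdata", "trials.csv", package = "alkmeta", mustWork = TRUE)
}

#' Build the evidence network of multi-arm comparisons
#'
#' Constructs the comparison graph underlying a network meta-analysis: one
#' node per treatment appearing in at least one multi-arm trial, one edge per
#' directly compared treatment pair, with the edge count equal to the number
#' of head-to-head trials of that pair. Node weight is the total sample size
#' of the treatment across the multi-arm trials.
#'
#' @param trials An `alk_trials` tibble (see [read_trials_csv()]).
#' @param arm_data Optional arm-level binary outcome tibble with columns
#'   `trial_id`, `treatment`, `events`, `total` (one outcome).
#' @param contrast_data Optional contrast-level tibble with columns
#'   `trial_id`, `treatment`, `comparator` and either `log_hr`, `se_log_hr`
#'   or `hr`, `ci_low`, `ci_high` (the latter converted via
#'   [as_contrast_data()]).
#' @param outcome Optional outcome label (`"ORR"`, `"DCR"`,
#'   `"DISCONTINUATION"`, `"PFS"`).
#' @param require_connected Error if the multi-arm graph is disconnected
#'   (default `TRUE`).
#' @return An `evidence_network`: list with tibbles `treatments`
#'   (`id`, `n_total`), `edges` (`treatment_a`, `treatment_b`, `n_trials`),
#'   the arm table restricted to multi-arm trials, and any attached outcome
#'   data.
#' @export
#' @examples
#' trials <- read_trials_csv(alk_trials_fixture())
#' net <- build_network(trials)
#' net$edges
build_network <- function(trials, arm_data = NULL, contrast_data = NULL,
                          outcome = NULL, require_connected = TRUE) {
  trials <- validate_trials(trials)
  multi <- dplyr::filter(
    trials,
    .data$trial_id %in% names(which(table(trials$trial_id) >= 2))
  )
  if (nrow(multi) == 0) {
    abort("no multi-arm trials: cannot form a comparison network",
          class = "alk_validation_error")
  }
  nodes <- multi |>
    dplyr::group_by(id = .data$treatment) |>
    dplyr::summarise(n_total = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$id)
  edges <- multi |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::reframe(pair = apply(utils::combn(sort(.data$treatment), 2), 2,
                                paste, collapse = "\r")) |>
    dplyr::count(.data$pair, name = "n_trials") |>
    tidyr::separate_wider_delim("pair", "\r",
                                names = c("treatment_a", "treatment_b"))
  if (require_connected) {
    comp <- network_components(nodes$id, edges)
    if (length(comp) > 1) {
      abort(paste0("evidence network is disconnected; components: ",
                   paste(vapply(comp, paste, "", collapse = "+"),
                         collapse = " | ")),
            class = "alk_connectivity_error")
    }
  }
  if (!is.null(contrast_data)) contrast_data <- as_contrast_data(contrast_data)
  structure(
    list(treatments = nodes, edges = tibble::as_tibble(edges), trials = multi,
         arm_data = arm_data, contrast_data = contrast_data, outcome = outcome),
    class = "evidence_network"
  )
}

# connected components by label propagation over the edge list
network_components <- function(ids, edges) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$treatment_a[i]; b <- edges$treatment_b[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(names(comp), comp))
}

#' @export
print.evidence_network <- function(x, ...) {
  cat("Evidence network:", nrow(x$treatments), "treatments,",
      nrow(x$edges), "direct comparisons,",
      dplyr::n_distinct(x$trials$trial_id), "trials\n")
  if (!is.null(x$outcome)) cat("Outcome:", x$outcome, "\n")
  print(x$edges)
  invisible(x)
}

#' @export
tidy.evidence_network <- function(x, ...) {
  dplyr::mutate(x$edges,
                n_a = x$treatments$n_total[match(.data$treatment_a, x$treatments$id)],
                n_b = x$treatments$n_total[match(.data$treatment_b, x$treatments$id)])
}

#' Plot-ready geometry for a network diagram
#'
#' Lays nodes out on a circle; node diameter is proportional to the total
#' treatment sample size and edge width to the number of head-to-head trials,
#' mirroring the conventional network plot of a multiple-treatment
#' comparison.
#'
#' @param network An `evidence_network`.
#' @param diameter_scale Diameter units per patient (default `1`).
#' @param width_scale Width units per trial (default `1`).
#' @return A list of tibbles `nodes` (`id`, `n_total`, `x`, `y`, `diameter`)
#'   and `edges` (`treatment_a`, `treatment_b`, segment coordinates,
#'   `width`).
#' @export
network_geometry <- function(network, diameter_scale = 1, width_scale = 1) {
  stopifnot(inherits(network, "evidence_network"))
  nodes <- network$treatments
  k <- nrow(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  nodes <- dplyr::mutate(nodes,
                         x = cos(theta), y = sin(theta),
                         diameter = diameter_scale * .data$n_total)
  edges <- network$edges
  if (k < 2 || nrow(edges) == 0) {
    edges <- tibble::tibble(treatment_a = character(), treatment_b = character(),
                            n_trials = integer(), x = numeric(), y = numeric(),
                            xend = numeric(), yend = numeric(), width = numeric())
  } else {
    ia <- match(edges$treatment_a, nodes$id)
    ib <- match(edges$treatment_b, nodes$id)
    edges <- dplyr::mutate(edges,
                           x = nodes$x[ia], y = nodes$y[ia],
                           xend = nodes$x[ib], yend = nodes$y[ib],
                           width = width_scale * .data$n_trials)
  }
  list(nodes = nodes, edges = edges)
}

#' @describeIn network_geometry ggplot of the network diagram.
#' @param object An `evidence_network`.
#' @param ... Passed to `network_geometry()`.
#' @export
autoplot.evidence_network <- function(object, ...) {
  geom <- network_geometry(object, ...)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = geom$edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$n_trials),
      colour = "grey55"
    ) +
    ggplot2::geom_point(
      data = geom$nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_total),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = geom$nodes,
      ggplot2::aes(x = 1.18 * .data$x, y = 1.18 * .data$y, label = .data$id)
    ) +
    ggplot2::scale_size_area(max_size = 18) +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45)) +
    ggplot2::labs(size = "patients", linewidth = "trials") +
    ggplot2::theme_void()
}

#' Read arm-level binary outcomes
#'
#' Expects columns `trial_id`, `treatment`, `outcome`, `events`, `total`;
#' `events <= total` is enforced.
#'
#' @param path CSV path.
#' @return A tibble, one row per arm and outcome.
#' @export
read_binary_outcomes_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                         na.strings = "NA"))
  required <- c("trial_id", "treatment", "outcome", "events", "total")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("binary outcome CSV missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "alk_format_error")
  }
  if (any(x$events < 0 | x$total < 1 | x$events > x$total)) {
    abort("binary outcomes require 0 <= events <= total and total >= 1",
          class = "alk_validation_error")
  }
  x
}

#' Convert hazard-ratio summaries to log scale
#'
#' Given contrast rows with `hr`, `ci_low`, `ci_high`, fills in `log_hr` and
#' `se_log_hr = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`; rows already
#' carrying `log_hr`/`se_log_hr` are kept as supplied.
#'
#' @param x A data frame of contrasts (`trial_id`, `treatment`,
#'   `comparator`, and HR columns).
#' @return A tibble with `log_hr` and `se_log_hr` present.
#' @export
as_contrast_data <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("trial_id", "treatment", "comparator") %in% names(x))) {
    abort("contrast data needs columns trial_id, treatment, comparator",
          class = "alk_format_error")
  }
  if (!("log_hr" %in% names(x))) x$log_hr <- NA_real_
  if (!("se_log_hr" %in% names(x))) x$se_log_hr <- NA_real_
  if (all(c("hr", "ci_low", "ci_high") %in% names(x))) {
    bad <- !is.na(x$hr) & !(x$ci_low <= x$hr & x$hr <= x$ci_high & x$ci_low > 0)
    if (any(bad)) {
      abort("hazard-ratio CI must satisfy 0 < ci_low <= hr <= ci_high",
            class = "alk_validation_error")
    }
    fill <- is.na(x$log_hr) & !is.na(x$hr)
    x$log_hr[fill] <- log(x$hr[fill])
    x$se_log_hr[fill] <- (log(x$ci_high[fill]) - log(x$ci_low[fill])) / (2 * Z975)
  }
  if (any(is.na(x$log_hr) | is.na(x$se_log_hr) | x$se_log_hr <= 0)) {
    abort("every contrast needs a finite log_hr and positive se_log_hr",
          class = "alk_validation_error")
  }
  x
}

#' Read contrast-level hazard-ratio summaries
#'
#' @param path CSV path with columns `trial_id`, `treatment`, `comparator`,
#'   `hr`, `ci_low`, `ci_high` (or `log_hr`, `se_log_hr` directly).
#' @return A tibble with log-scale columns filled in.
#' @export
read_contrasts_csv <- function(path) {
  as_contrast_data(utils::read.csv(path, stringsAsFactors = FALSE,
                                   na.strings = "NA"))
}
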