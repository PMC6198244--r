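#' Render a league table as a lower-triangle text table
#'
#' Diagonal cells carry the treatment names; each off-diagonal cell shows
#' `point (low-high)` for the column treatment versus the row treatment,
#' ratios rounded to 2 decimals as in published multiple-treatment
#' comparison tables.
#'
#' @param table A `league_table`.
#' @param digits Decimals for ratios (default 2).
#' @return A character vector of tab-separated lines.
#' @export
render_league_table <- function(table, digits = 2) {
  stopifnot(inherits(table, "league_table"))
  trts <- table$treatments
  k <- length(trts)
  fmt <- function(p, l, h) {
    sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"), p, l, h)
  }
  lines <- character(k)
  for (i in seq_len(k)) {
    cells <- character(i)
    for (j in seq_len(i)) {
      cells[j] <- if (i == j) {
        trts[i]
      } else {
        fmt(table$point[trts[i], trts[j]],
            table$ci_low[trts[i], trts[j]],
            table$ci_high[trts[i], trts[j]])
      }
    }
    lines[i] <- paste(cells, collapse = "\t")
  }
  lines
}

#' Assemble a pipeline run configuration
#'
#' @param trials Path to the trial-characteristics CSV (required).
#' @param binary_outcomes Optional path to arm-level binary outcomes CSV.
#' @param contrasts Optional path to hazard-ratio contrasts CSV.
#' @param km_points,at_risk Optional paths to digitized curve points and
#'   at-risk tables.
#' @param reference Reference treatment for network models.
#' @param settings An [mcmc_settings()].
#' @param out_dir Output directory (created if missing).
#' @param yaml_file Alternatively, a YAML file holding any of the above
#'   fields; explicit arguments win.
#' @return A `run_config` list.
#' @export
run_config <- function(trials = NULL, binary_outcomes = NULL, contrasts = NULL,
                       km_points = NULL, at_risk = NULL,
                       reference = NULL,
                       settings = NULL, out_dir = NULL,
                       yaml_file = NULL) {
  cfg <- list(trials = trials, binary_outcomes = binary_outcomes,
              contrasts = contrasts, km_points = km_points, at_risk = at_risk,
              reference = reference, settings = settings, out_dir = out_dir)
  if (!is.null(yaml_file)) {
    y <- yaml::read_yaml(yaml_file)
    if (!is.null(y$settings)) y$settings <- do.call(mcmc_settings, y$settings)
    for (nm in names(y)) if (is.null(cfg[[nm]])) cfg[[nm]] <- y[[nm]]
  }
  if (is.null(cfg$reference)) cfg$reference <- "chemotherapy"
  if (is.null(cfg$settings)) cfg$settings <- mcmc_settings()
  if (is.null(cfg$out_dir)) cfg$out_dir <- "alkmeta_results"
  structure(cfg, class = "run_config")
}

#' Run the full evidence-synthesis pipeline
#'
#' Executes load, pairwise pooling, network meta-analysis, ranking,
#' optional survival reconstruction and publication-bias stages, writing
#' every artifact (CSV/JSON) plus a manifest recording the seed, settings
#' and package version into `out_dir`. Deterministic for a fixed seed: two
#' runs with the same configuration produce identical result files.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list of in-memory results (`network`, `nma`,
#'   `league`, `ranks`, `pooled`, `bias`, `km`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  # pre-flight: every referenced input must exist before any computation
  for (nm in c("trials", "binary_outcomes", "contrasts", "km_points", "at_risk")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("pre-flight validation failed: missing input '", nm,
                   "': ", p),
            class = "alk_validation_error")
    }
  }
  if (is.null(config$trials)) {
    abort("pre-flight validation failed: a trials CSV is required",
          class = "alk_validation_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stages_run <- character(0)
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "alk_runtime_error", parent = e)
    })
    log_line(stage, sprintf("done in %.2fs", as.numeric(Sys.time() - t0,
                                                        units = "secs")))
    stages_run <<- c(stages_run, stage)
    out
  }

  trials <- run_stage("load", read_trials_csv(config$trials))
  arm_data <- if (!is.null(config$binary_outcomes)) {
    read_binary_outcomes_csv(config$binary_outcomes)
  }
  contrast_data <- if (!is.null(config$contrasts)) {
    read_contrasts_csv(config$contrasts)
  }
  results$network <- run_stage("network", {
    net <- build_network(trials, arm_data = arm_data,
                         contrast_data = contrast_data)
    geom <- network_geometry(net)
    utils::write.csv(geom$nodes, file.path(config$out_dir, "network_nodes.csv"),
                     row.names = FALSE)
    utils::write.csv(geom$edges, file.path(config$out_dir, "network_edges.csv"),
                     row.names = FALSE)
    net
  })

  if (!is.null(arm_data)) {
    results$pooled <- run_stage("pairwise", {
      pooled <- arm_data |>
        dplyr::group_by(.data$outcome, .data$treatment) |>
        dplyr::group_modify(~ tibble::as_tibble(
          pool_proportions(.x, events = events, n = total))) |>
        dplyr::ungroup()
      utils::write.csv(pooled, file.path(config$out_dir, "pooled_proportions.csv"),
                       row.names = FALSE)
      pooled
    })
    results$bias <- run_stage("bias", {
      per_outcome <- arm_data |>
        dplyr::mutate(cc = 0.5 * (.data$events == 0 | .data$events == .data$total),
                      y = log((.data$events + .data$cc) /
                                (.data$total - .data$events + .data$cc)),
                      se = sqrt(1 / (.data$events + .data$cc) +
                                  1 / (.data$total - .data$events + .data$cc))) |>
        dplyr::group_by(.data$outcome) |>
        dplyr::group_modify(function(d, key) {
          if (nrow(d) < 3) return(tibble::tibble())
          dplyr::bind_rows(egger_test(d), begg_test(d))
        }) |>
        dplyr::ungroup()
      utils::write.csv(per_outcome, file.path(config$out_dir, "bias_tests.csv"),
                       row.names = FALSE)
      per_outcome
    })
  }

  run_nma_for <- function(net, kind, scale, tag) {
    spec <- nma_model_spec(kind, reference = config$reference)
    fit <- run_mcmc(build_nma_model(net, spec), config$settings)
    lt <- league_table(fit, scale = scale)
    rk <- rank_probabilities(fit, lower_is_better = (scale == "HR"))
    utils::write.csv(tidy(lt), file.path(config$out_dir,
                                         paste0("league_", tag, ".csv")),
                     row.names = FALSE)
    writeLines(render_league_table(lt),
               file.path(config$out_dir, paste0("league_", tag, ".txt")))
    utils::write.csv(tidy(rk), file.path(config$out_dir,
                                         paste0("ranks_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(psrf(fit), file.path(config$out_dir,
                                          paste0("psrf_", tag, ".csv")),
                     row.names = FALSE)
    list(fit = fit, league = lt, ranks = rk)
  }

  if (!is.null(arm_data)) {
    results$nma_binary <- run_stage("nma-binary", {
      outcomes <- unique(arm_data$outcome)
      purrr::map(stats::setNames(outcomes, outcomes), function(oc) {
        sub <- arm_data[arm_data$outcome == oc, ]
        net <- build_network(trials, arm_data = sub, outcome = oc)
        run_nma_for(net, "BINARY_ARM", "OR", paste0("or_", tolower(oc)))
      })
    })
  }
  if (!is.null(contrast_data)) {
    results$nma_pfs <- run_stage("nma-pfs", {
      net <- build_network(trials, contrast_data = contrast_data,
                           outcome = "PFS")
      run_nma_for(net, "CONTRAST_NORMAL", "HR", "hr_pfs")
    })
  }

  if (!is.null(config$km_points)) {
    results$km <- run_stage("km", {
      pts <- read_km_points_csv(config$km_points)
      risk <- if (!is.null(config$at_risk)) read_at_risk_csv(config$at_risk)
      ipd <- pts |>
        dplyr::group_by(.data$trial_id, .data$treatment) |>
        dplyr::group_map(function(d, key) {
          ar <- if (!is.null(risk)) {
            r <- risk[risk$trial_id == key$trial_id &
                        risk$treatment == key$treatment, c("t", "n_risk")]
            if (nrow(r) > 0) r else NULL
          }
          tn <- if (is.null(ar)) {
            if (!("total_n" %in% names(d))) {
              abort(paste0("trial ", key$trial_id, "/", key$treatment,
                           " has neither at-risk rows nor a total_n column"),
                    class = "alk_validation_error")
            }
            d$total_n[1]
          }
          reconstruct_ipd(d[, c("t", "s")], at_risk = ar, total_n = tn,
                          treatment_id = key$treatment, trial_id = key$trial_id)
        }) |>
        pool_ipd()
      utils::write.csv(ipd, file.path(config$out_dir, "reconstructed_ipd.csv"),
                       row.names = FALSE)
      kms <- km_by_treatment(ipd)
      medians <- purrr::imap_dfr(kms, ~ dplyr::mutate(glance(.x),
                                                      treatment = .y,
                                                      .before = 1))
      utils::write.csv(medians, file.path(config$out_dir, "km_medians.csv"),
                       row.names = FALSE)
      lr <- logrank_test(ipd)
      utils::write.csv(lr, file.path(config$out_dir, "logrank.csv"),
                       row.names = FALSE)
      list(ipd = ipd, km = kms, medians = medians, logrank = lr)
    })
  } else {
    log_line("km", "skipped (no survival inputs)")
  }

  manifest <- list(
    package = "alkmeta",
    version = as.character(utils::packageVersion("alkmeta")),
    seed = config$settings$seed,
    settings = unclass(config$settings),
    inputs = config[c("trials", "binary_outcomes", "contrasts", "km_points",
                      "at_risk")],
    stages = stages_run,
    km_skipped = is.null(config$km_points),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
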