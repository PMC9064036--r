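#' Analysis configuration
#'
#' Settings for an end-to-end run: the observation window, which kinetic
#' models to fit, whether zero-growth replicates enter the fits as
#' `mu = 0` points, and an optional coarser histogram bin width for the
#' exported generation-time distributions.
#'
#' @param window An [observation_window()].
#' @param models Character subset of `"single"`, `"two"`, `"monod"`,
#'   `"teissier"`.
#' @param include_zero_growth_in_fit Include zero-growth replicates as
#'   `mu = 0` observations in the kinetic fits (default `TRUE`).
#' @param rebin_width Optional distribution bin width, hours (multiple
#'   of `delta_tau`).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(window = observation_window(),
                            models = c("single", "two"),
                            include_zero_growth_in_fit = TRUE,
                            rebin_width = NULL) {
  check_window(window)
  models <- match.arg(models, names(kinetic_models), several.ok = TRUE)
  if (length(models) < 1) stop("Select at least one model.", call. = FALSE)
  structure(
    list(window = window, models = models,
         include_zero_growth_in_fit = include_zero_growth_in_fit,
         rebin_width = rebin_width),
    class = "analysis_config"
  )
}

#' Run the full analysis pipeline
#'
#' From a division-event table to (1) the per-experiment results table
#' (event counts, status, growth rate, heterogeneity statistics),
#' (2) the bias-corrected generation-time distribution of every analyzed
#' experiment, (3) kinetic fits of the selected models on the
#' replicate-level growth rates, and (4) optionally the transport-
#' limitation report. Excluded experiments (5–49 events) appear in the
#' results table but contribute to neither fits nor heterogeneity;
#' zero-growth experiments contribute `mu = 0` points to the fits when
#' configured. A run log records per-stage counts.
#'
#' @param events Division events: a tibble or a path to a TSV readable
#'   by [read_events()].
#' @param config An [analysis_config()].
#' @param experiments Optional roster of all experiments (see
#'   [analyze_experiments()]); use the `truth` manifest of
#'   [simulate_study()] to keep event-less replicates visible.
#' @param transport Optional [transport_params()] for the transport
#'   report.
#' @param out_dir Optional directory: writes `results.tsv`, one
#'   `dist_<experiment>.tsv` per analyzed experiment, one
#'   `fit_<model>.json` per model, and `run_log.txt`.
#' @return A list of class `mm_analysis` with elements `results`,
#'   `distributions` (named list of `gt_dist`), `fits` (named list of
#'   `kinetic_fit` or the error condition where a fit was degenerate),
#'   `heterogeneity`, `transport`, `log`.
#' @export
run_analysis <- function(events, config = analysis_config(),
                         experiments = NULL, transport = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  window <- config$window
  if (is.character(events)) {
    events <- read_events(events, window)
  }
  log <- character(0)
  say <- function(...) sprintf(...)
  log <- c(log, say("events read: %d rows, %d experiment(s)",
                    nrow(events),
                    dplyr::n_distinct(events$experiment_id)))
  n_kept <- nrow(filter_events(events, window))
  log <- c(log, say("events inside [%g, %g] h window: %d",
                    window$t_start, window$t_end, n_kept))
  near_singular <- sum(
    filter_events(events, window)$generation_time_h >
      0.8 * window_length(window)
  )
  if (near_singular > 0) {
    log <- c(log, say(
      "warning: %d event(s) with tau > 0.8 x window length (correction weight large)",
      near_singular))
  }

  results <- analyze_experiments(events, window, experiments)
  log <- c(log, say("experiments: %d analyzed, %d zero_growth, %d excluded",
                    sum(results$status == "analyzed"),
                    sum(results$status == "zero_growth"),
                    sum(results$status == "excluded")))

  analyzed_ids <- results$experiment_id[results$status == "analyzed"]
  kept <- filter_events(events, window)
  distributions <- purrr::map(
    rlang::set_names(analyzed_ids),
    function(id) {
      estimate_distribution(
        kept[kept$experiment_id == id, ], window,
        bin_width = config$rebin_width
      )
    }
  )

  fit_data <- results |>
    dplyr::filter(.data$status %in%
                    if (config$include_zero_growth_in_fit) {
                      c("analyzed", "zero_growth")
                    } else "analyzed") |>
    dplyr::transmute(
      concentration = .data$concentration_mmol_per_L,
      mu = .data$growth_rate_per_h,
      experiment_id = .data$experiment_id
    )
  fits <- purrr::map(rlang::set_names(config$models), function(m) {
    tryCatch(
      fit_kinetics(fit_data, model = m,
                   include_zero_growth = config$include_zero_growth_in_fit),
      error = function(e) e
    )
  })
  for (m in names(fits)) {
    log <- c(log, if (inherits(fits[[m]], "error")) {
      say("fit '%s': DEGENERATE (%s)", m, conditionMessage(fits[[m]]))
    } else {
      say("fit '%s': RSS %.5g on %d observations", m,
          fits[[m]]$rss, fits[[m]]$n_obs)
    })
  }

  heterogeneity <- results |>
    dplyr::filter(.data$status == "analyzed") |>
    dplyr::select("experiment_id", "concentration_mmol_per_L",
                  "mean_tau_h", "var_tau_h2", "cv_tau")

  transport_out <- if (!is.null(transport)) transport_report(transport)

  out <- structure(
    list(results = results, distributions = distributions, fits = fits,
         heterogeneity = heterogeneity, transport = transport_out,
         log = log),
    class = "mm_analysis"
  )
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

write_analysis <- function(x, out_dir) {
  stopifnot(inherits(x, "mm_analysis"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(x$results, file.path(out_dir, "results.tsv"),
                   progress = FALSE)
  for (id in names(x$distributions)) {
    write_distribution(x$distributions[[id]],
                       file.path(out_dir, sprintf("dist_%s.tsv", id)))
  }
  for (m in names(x$fits)) {
    if (!inherits(x$fits[[m]], "error")) {
      write_fit_report(x$fits[[m]],
                       file.path(out_dir, sprintf("fit_%s.json", m)))
    }
  }
  writeLines(x$log, file.path(out_dir, "run_log.txt"))
  invisible(x)
}

#' @export
print.mm_analysis <- function(x, ...) {
  cat("<mm_analysis>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' Per-concentration summary of replicate growth rates
#'
#' Mean and standard deviation of the replicate-level population growth
#' rates at each concentration (the error-bar layer of a kinetic plot).
#' Excluded experiments do not contribute.
#'
#' @param results The `results` tibble of [run_analysis()] /
#'   [analyze_experiments()].
#' @return A tibble: `concentration_mmol_per_L`, `n_replicates`,
#'   `mean_mu_per_h`, `sd_mu_per_h`.
#' @export
summarize_concentrations <- function(results) {
  results |>
    dplyr::filter(.data$status != "excluded") |>
    dplyr::group_by(.data$concentration_mmol_per_L) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_mu_per_h = mean(.data$growth_rate_per_h),
      sd_mu_per_h = stats::sd(.data$growth_rate_per_h),
      .groups = "drop"
    )
}
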