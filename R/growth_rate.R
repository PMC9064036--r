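#' Censoring-bias correction factor
#'
#' In a finite observation window only cells that are born after
#' `t_start` and divide before `t_end` are fully observed, so a cell with
#' generation time `tau` can only start its life within an interval of
#' length `t_end - t_start - tau`. Long generation times are therefore
#' under-represented in the raw event counts. The correction factor
#' rescales each count by the inverse of its observable-window length,
#'
#' \deqn{c_\tau = \frac{t_{end} - t_{start}}{t_{end} - t_{start} - \tau},}
#'
#' so that equally probable long and short generation times contribute
#' equally after weighting. It tends to 1 as `tau` tends to 0 and
#' diverges as `tau` approaches the window length (such events are never
#' fully observable).
#'
#' @param tau Generation time(s) in hours, `0 < tau < window length`.
#' @param window An [observation_window()].
#' @return The dimensionless weight(s) `c_tau >= 1`.
#' @examples
#' correction_factor(5, observation_window(15, 40)) # 25/20 = 1.25
#' @export
correction_factor <- function(tau, window) {
  check_window(window)
  len <- window_length(window)
  if (any(!is.finite(tau) | tau <= 0)) {
    stop("`tau` must be positive and finite.", call. = FALSE)
  }
  if (any(tau >= len - 1e-12)) {
    stop(sprintf(
      "`tau` must be smaller than the window length (%g h): %s",
      len, "events at least as long as the window are never fully observed."
    ), call. = FALSE)
  }
  len / (len - tau)
}

#' Bias-corrected generation-time distribution
#'
#' Bins the observed generation times on the imaging grid and converts
#' counts to a discrete probability distribution, weighting each bin by
#' the censoring correction [correction_factor()] evaluated at the bin
#' centre:
#' \deqn{f(\tau_i) = \frac{n_i\, c_{\tau_i}}{\sum_j n_j\, c_{\tau_j}}.}
#' Any `tau`-independent prefactor of the weight cancels in the
#' normalization.
#'
#' @param events A tibble of division events, already restricted with
#'   [filter_events()]; must contain at least one row, with all
#'   generation times shorter than the window length.
#' @param window An [observation_window()].
#' @param bin_width Optional bin width in hours; must be a multiple of
#'   `window$delta_tau`. Defaults to the raw imaging grid.
#' @param correct If `FALSE`, skip the censoring correction (all weights
#'   1); mainly useful for demonstrating the bias.
#'
#' @return A tibble of class `gt_dist` with columns `tau_h` (bin centre),
#'   `count`, `weight`, `probability`, carrying the window as attribute
#'   `window`. Probabilities sum to 1 to within 1e-12.
#' @export
estimate_distribution <- function(events, window, bin_width = NULL,
                                  correct = TRUE) {
  check_window(window)
  tau <- events$generation_time_h
  if (length(tau) == 0) {
    stop("No events to estimate a distribution from; classify the ",
         "experiment with `classify_experiments()` first (fewer than 5 ",
         "events means growth rate zero).", call. = FALSE)
  }
  len <- window_length(window)
  if (any(tau <= 0) || any(tau >= len - 1e-9)) {
    stop("All generation times must lie in (0, window length).",
         call. = FALSE)
  }
  dt <- window$delta_tau
  if (!is.null(bin_width)) {
    m <- bin_width / dt
    if (!is.finite(m) || abs(m - round(m)) > 1e-8 || m < 1) {
      stop("`bin_width` must be a positive multiple of `delta_tau`.",
           call. = FALSE)
    }
    dt <- bin_width
  }
  # events are grid-snapped at ingest, so binning is exact counting
  k <- as.integer(floor(tau / dt + 0.5 + 1e-9))
  k[k < 1] <- 1L
  counts <- table(k)
  tau_i <- as.integer(names(counts)) * dt
  n_i <- as.numeric(counts)
  w_i <- if (correct) correction_factor(tau_i, window) else rep(1, length(tau_i))
  p <- n_i * w_i
  p <- p / sum(p)
  out <- tibble::tibble(
    tau_h = tau_i, count = n_i, weight = w_i, probability = p
  )
  attr(out, "window") <- window
  class(out) <- c("gt_dist", class(out))
  out
}

check_gt_dist <- function(dist) {
  if (!all(c("tau_h", "probability") %in% names(dist))) {
    stop("`dist` must have columns `tau_h` and `probability` ",
         "(see `estimate_distribution()`).", call. = FALSE)
  }
  if (nrow(dist) == 0) {
    stop("`dist` is empty.", call. = FALSE)
  }
  if (any(dist$tau_h <= 0)) {
    stop("All `tau_h` must be positive.", call. = FALSE)
  }
  if (abs(sum(dist$probability) - 1) > 1e-8 || any(dist$probability < 0)) {
    stop("`probability` must be a normalized distribution.", call. = FALSE)
  }
  invisible(dist)
}

#' Population growth rate from a generation-time distribution
#'
#' Solves the Euler–Lotka relation for binary fission,
#' \deqn{1 = 2 \sum_i f(\tau_i)\, e^{-\mu \tau_i},}
#' for the population (colony) growth rate `mu`. The residual
#' `g(mu) = 2 sum f exp(-mu tau) - 1` is strictly decreasing with
#' `g(0) = 1`, and `g` is negative at `log(2)/min(tau) + 1`, so the root
#' is unique and bracketed; it is found by `stats::uniroot()` to a
#' tolerance of 1e-12.
#'
#' @param dist A `gt_dist` tibble (columns `tau_h`, `probability`).
#' @return The growth rate `mu` in 1/h.
#' @examples
#' d <- tibble::tibble(tau_h = 1, probability = 1)
#' solve_growth_rate(d) # log(2): doubling once per hour
#' @export
solve_growth_rate <- function(dist) {
  check_gt_dist(dist)
  tau <- dist$tau_h
  p <- dist$probability
  g <- function(mu) 2 * sum(p * exp(-mu * tau)) - 1
  upper <- log(2) / min(tau) + 1
  stats::uniroot(g, lower = 0, upper = upper, tol = 1e-12)$root
}

#' Heterogeneity statistics of a generation-time distribution
#'
#' Probability-weighted mean, variance and coefficient of variation of
#' the (bias-corrected) generation-time distribution. These are
#' distribution-level moments: no finite-sample correction is applied.
#'
#' @param dist A `gt_dist` tibble.
#' @return A one-row tibble with `mean_tau_h`, `var_tau_h2`, `cv_tau`.
#' @export
heterogeneity_stats <- function(dist) {
  check_gt_dist(dist)
  m <- sum(dist$probability * dist$tau_h)
  v <- sum(dist$probability * (dist$tau_h - m)^2)
  tibble::tibble(mean_tau_h = m, var_tau_h2 = v, cv_tau = sqrt(v) / m)
}

#' Analyze one experiment
#'
#' Composition of the per-experiment pipeline: window filtering,
#' classification by event count, and — for analyzed experiments —
#' distribution estimation, Euler–Lotka inversion and heterogeneity
#' statistics. Experiments with fewer than 5 events get growth rate
#' exactly 0 (`zero_growth`); experiments with 5–49 events are `excluded`
#' and report no growth rate.
#'
#' @param events Division events of a single experiment (any filtering
#'   state; the window filter is applied here).
#' @param window An [observation_window()].
#' @return A one-row tibble: `n_events`, `status`, `growth_rate_per_h`,
#'   `mean_tau_h`, `var_tau_h2`, `cv_tau`.
#' @export
analyze_experiment <- function(events, window) {
  check_window(window)
  kept <- filter_events(events, window)
  # defensive: a tau == window length can slip in via in-memory tables
  len <- window_length(window)
  too_long <- kept$generation_time_h >= len - 1e-9
  if (any(too_long)) {
    warning(sprintf("Dropped %d event(s) with tau >= window length.",
                    sum(too_long)), call. = FALSE)
    kept <- kept[!too_long, ]
  }
  n <- nrow(kept)
  status <- classify_experiment(n)
  if (status == "analyzed") {
    dist <- estimate_distribution(kept, window)
    mu <- solve_growth_rate(dist)
    stats <- heterogeneity_stats(dist)
    tibble::tibble(
      n_events = n, status = status, growth_rate_per_h = mu,
      mean_tau_h = stats$mean_tau_h, var_tau_h2 = stats$var_tau_h2,
      cv_tau = stats$cv_tau
    )
  } else if (status == "zero_growth") {
    tibble::tibble(
      n_events = n, status = status, growth_rate_per_h = 0,
      mean_tau_h = NA_real_, var_tau_h2 = NA_real_, cv_tau = NA_real_
    )
  } else {
    tibble::tibble(
      n_events = n, status = status, growth_rate_per_h = NA_real_,
      mean_tau_h = NA_real_, var_tau_h2 = NA_real_, cv_tau = NA_real_
    )
  }
}

#' Analyze every experiment in an event table
#'
#' Runs [analyze_experiment()] for each `experiment_id` and assembles the
#' per-experiment results table. Experiments present in the optional
#' roster but without any event rows are reported as `zero_growth` with
#' growth rate 0.
#'
#' @param events A tibble of division events (all experiments pooled).
#' @param window An [observation_window()].
#' @param experiments Optional roster tibble (`experiment_id`,
#'   `concentration_mmol_per_L`) of all experiments, including event-less
#'   ones.
#' @return A tibble with one row per experiment: `experiment_id`,
#'   `concentration_mmol_per_L`, `n_events`, `status`,
#'   `growth_rate_per_h`, `mean_tau_h`, `var_tau_h2`, `cv_tau`.
#' @export
analyze_experiments <- function(events, window, experiments = NULL) {
  check_window(window)
  roster <- classify_experiments(events, window, experiments)
  per_exp <- split(events, events$experiment_id) |>
    purrr::imap(function(ev, id) {
      dplyr::mutate(analyze_experiment(ev, window),
                    experiment_id = id, .before = 1)
    }) |>
    purrr::list_rbind()
  if (nrow(per_exp) == 0) {
    per_exp <- tibble::tibble(
      experiment_id = character(), n_events = integer(),
      status = character(), growth_rate_per_h = double(),
      mean_tau_h = double(), var_tau_h2 = double(), cv_tau = double()
    )
  }
  roster |>
    dplyr::select("experiment_id", "concentration_mmol_per_L") |>
    dplyr::left_join(per_exp, by = "experiment_id") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      status = dplyr::coalesce(.data$status, "zero_growth"),
      growth_rate_per_h = dplyr::if_else(
        .data$status == "zero_growth", 0, .data$growth_rate_per_h
      )
    )
}

#' Export a generation-time distribution
#'
#' Writes the `tau_h`, `count`, `weight`, `probability` table of one
#' analyzed experiment as TSV (the data layer behind a generation-time
#' histogram).
#'
#' @param dist A `gt_dist` tibble.
#' @param path Output file path.
#' @return `dist`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  check_gt_dist(dist)
  readr::write_tsv(
    tibble::as_tibble(dist)[c("tau_h", "count", "weight", "probability")],
    path, progress = FALSE
  )
  invisible(dist)
}
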