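#' @importFrom rlang .data
NULL

# canonical column order of the on-disk event table
event_columns <- c(
  "experiment_id", "concentration_mmol_per_L", "channel_id",
  "cell_id", "birth_time_h", "generation_time_h"
)

#' Read a division-event table
#'
#' Reads a tab-separated table of observed cell lives, one row per cell:
#' the experiment it belongs to, the substrate concentration of that
#' experiment, the growth channel and cell identifiers, the time the cell
#' first appeared (birth) and its generation time (birth to division).
#' Birth and division times are snapped onto the imaging grid `delta_tau`
#' on ingest (nearest multiple, ties rounded up) since the microscope
#' cannot resolve finer. Events whose generation time reaches or exceeds
#' the window length are dropped with a warning: such an event cannot be
#' fully observed and would make the censoring correction undefined.
#'
#' @param path Path to a UTF-8 TSV file with header columns exactly
#'   `experiment_id`, `concentration_mmol_per_L`, `channel_id`, `cell_id`,
#'   `birth_time_h`, `generation_time_h`.
#' @param window An [observation_window()]; supplies the imaging grid used
#'   for snapping and the window length used for the ingest validity check.
#'
#' @return A tibble of division events with the six canonical columns,
#'   row order preserved within each experiment.
#' @seealso [write_events()], [filter_events()], [classify_experiments()]
#' @export
read_events <- function(path, window = observation_window()) {
  check_window(window)
  if (!file.exists(path)) {
    stop("Event table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(event_columns, names(raw))
  if (length(missing) > 0) {
    stop("Event table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[event_columns]
  numeric_cols <- c("concentration_mmol_per_L", "birth_time_h",
                    "generation_time_h")
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("Non-numeric value '%s' in column '%s' at data row %d.",
                   raw[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  validate_events(raw, window)
}

# shared ingest validation + grid snapping; `events` has canonical columns
validate_events <- function(events, window) {
  events <- tibble::as_tibble(events)[event_columns]
  bad_tau <- which(!is.finite(events$generation_time_h) |
                     events$generation_time_h <= 0)
  if (length(bad_tau) > 0) {
    stop(sprintf(
      "Invalid generation_time_h (%s) at data row %d: must be > 0.",
      format(events$generation_time_h[bad_tau[1]]), bad_tau[1]
    ), call. = FALSE)
  }
  bad_birth <- which(!is.finite(events$birth_time_h) |
                       events$birth_time_h < 0)
  if (length(bad_birth) > 0) {
    stop(sprintf(
      "Invalid birth_time_h (%s) at data row %d: must be >= 0.",
      format(events$birth_time_h[bad_birth[1]]), bad_birth[1]
    ), call. = FALSE)
  }
  bad_conc <- which(!is.finite(events$concentration_mmol_per_L) |
                      events$concentration_mmol_per_L < 0)
  if (length(bad_conc) > 0) {
    stop(sprintf("Negative or missing concentration at data row %d.",
                 bad_conc[1]), call. = FALSE)
  }
  dt <- window$delta_tau
  division <- snap_to_grid(events$birth_time_h + events$generation_time_h, dt)
  birth <- snap_to_grid(events$birth_time_h, dt)
  tau <- division - birth
  if (any(tau <= 0)) {
    stop(sprintf(
      "Generation time at data row %d collapses to 0 on the %.3g-min imaging grid.",
      which(tau <= 0)[1], dt * 60
    ), call. = FALSE)
  }
  events$birth_time_h <- birth
  events$generation_time_h <- tau
  too_long <- tau >= window_length(window) - 1e-9
  if (any(too_long)) {
    warning(sprintf(
      "Dropped %d event(s) with generation time >= the %g h window length; %s",
      sum(too_long), window_length(window),
      "they cannot arise from a correctly censored observation."
    ), call. = FALSE)
    events <- events[!too_long, ]
  }
  events
}

#' Write a division-event table
#'
#' Writes events in the same TSV dialect that [read_events()] reads, so
#' that a write/read cycle round-trips to identical records.
#'
#' @param events A tibble of division events (canonical columns).
#' @param path Output file path.
#' @return `events`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(event_columns %in% names(events)))
  readr::write_tsv(events[event_columns], path, progress = FALSE)
  invisible(events)
}

#' Restrict events to the observation window
#'
#' Keeps exactly the events that are fully observable within the analysis
#' window: birth at or after `t_start` (divisions starting earlier are
#' discarded to exclude preculture carry-over) and division at or before
#' `t_end` (later divisions are never seen). Order is preserved and the
#' operation is idempotent.
#'
#' @param events A tibble of division events.
#' @param window An [observation_window()].
#' @return The retained events (possibly zero rows).
#' @export
filter_events <- function(events, window) {
  check_window(window)
  eps <- 1e-9
  dplyr::filter(
    events,
    .data$birth_time_h >= window$t_start - eps,
    .data$birth_time_h + .data$generation_time_h <= window$t_end + eps
  )
}

#' Classify an experiment by its usable event count
#'
#' Experiments with fewer than 5 division events in the analysis window
#' are marked as growth rate zero (`zero_growth`); experiments with at
#' least 5 but fewer than 50 events are too small to represent a
#' population growth rate and are `excluded`; experiments with 50 or more
#' events are `analyzed`.
#'
#' @param n_events Non-negative integer count(s) of events surviving
#'   [filter_events()].
#' @return A character vector of statuses among `"zero_growth"`,
#'   `"excluded"`, `"analyzed"`.
#' @examples
#' classify_experiment(c(4, 5, 30, 50, 120))
#' @export
classify_experiment <- function(n_events) {
  if (any(!is.finite(n_events) | n_events < 0 |
            n_events != floor(n_events))) {
    stop("`n_events` must be non-negative integer count(s).", call. = FALSE)
  }
  dplyr::case_when(
    n_events < 5 ~ "zero_growth",
    n_events < 50 ~ "excluded",
    TRUE ~ "analyzed"
  )
}

#' Per-experiment event counts and status
#'
#' Applies the window filter per experiment and classifies each experiment
#' by its surviving event count. Experiments listed in `experiments` but
#' absent from `events` (for instance replicates that never divided and so
#' produced no event rows) are included with a count of 0 and status
#' `zero_growth`.
#'
#' @param events A tibble of division events.
#' @param window An [observation_window()].
#' @param experiments Optional tibble with columns `experiment_id` and
#'   `concentration_mmol_per_L` giving the full roster of experiments.
#' @return A tibble with one row per experiment: `experiment_id`,
#'   `concentration_mmol_per_L`, `n_events`, `status`.
#' @export
classify_experiments <- function(events, window, experiments = NULL) {
  check_window(window)
  roster <- dplyr::distinct(
    events, .data$experiment_id, .data$concentration_mmol_per_L
  )
  if (!is.null(experiments)) {
    roster <- dplyr::bind_rows(
      roster,
      tibble::as_tibble(experiments)[c("experiment_id",
                                       "concentration_mmol_per_L")]
    )
    roster <- dplyr::distinct(roster, .data$experiment_id, .keep_all = TRUE)
  }
  counts <- filter_events(events, window) |>
    dplyr::count(.data$experiment_id, name = "n_events")
  roster |>
    dplyr::left_join(counts, by = "experiment_id") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      status = classify_experiment(.data$n_events)
    )
}
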