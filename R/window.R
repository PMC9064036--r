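#' Observation window of a mother-machine experiment
#'
#' Describes the interval of a time-lapse experiment that enters the
#' analysis and the imaging interval of the microscope. The analysis
#' discards events starting before `t_start` (to exclude carry-over from
#' the preculture) and events dividing after `t_end` (they are never
#' observed). All times are in hours.
#'
#' @param t_start Start of the analysis window in hours (default 15).
#' @param t_end End of the experiment in hours (default 40).
#' @param delta_tau Imaging interval in hours (default 5 minutes, `5/60`).
#'
#' @return An object of class `observation_window`: a list with elements
#'   `t_start`, `t_end`, `delta_tau`.
#' @examples
#' w <- observation_window()
#' window_length(w) # 25 h
#' @export
observation_window <- function(t_start = 15, t_end = 40, delta_tau = 5 / 60) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(delta_tau),
            length(t_start) == 1, length(t_end) == 1, length(delta_tau) == 1)
  if (!is.finite(delta_tau) || delta_tau <= 0) {
    stop("`delta_tau` must be a positive imaging interval in hours.",
         call. = FALSE)
  }
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start) {
    stop("`t_end` must be greater than `t_start`.", call. = FALSE)
  }
  if (t_end - t_start <= delta_tau) {
    stop("The window length `t_end - t_start` must exceed `delta_tau`.",
         call. = FALSE)
  }
  structure(
    list(t_start = t_start, t_end = t_end, delta_tau = delta_tau),
    class = "observation_window"
  )
}

#' @rdname observation_window
#' @param window An `observation_window`.
#' @export
window_length <- function(window) {
  check_window(window)
  window$t_end - window$t_start
}

check_window <- function(window) {
  if (!inherits(window, "observation_window")) {
    stop("`window` must be created with `observation_window()`.",
         call. = FALSE)
  }
  invisible(window)
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf(
    "<observation_window> [%g, %g] h, imaging every %.4g min\n",
    x$t_start, x$t_end, x$delta_tau * 60
  ))
  invisible(x)
}

# round-half-up snapping of a time (h) onto the imaging grid
snap_to_grid <- function(t, delta_tau) {
  floor(t / delta_tau + 0.5 + 1e-9) * delta_tau
}
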