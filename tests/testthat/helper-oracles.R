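# Independent oracle for the Euler-Lotka inversion: dense grid scan of the
# residual g(mu) = 2 sum f exp(-mu tau) - 1 at step `step` to bracket the
# sign change, then plain bisection inside that bracket. Shares no code
# path with solve_growth_rate() (which uses stats::uniroot on an analytic
# bracket).
oracle_growth_rate <- function(tau, p, step = 1e-6, tol = 1e-12) {
  g <- function(mu) 2 * colSums(p * exp(-outer(tau, mu))) - 1
  lo <- 0
  hi <- NA
  from <- step
  repeat {
    mus <- seq(from, from + 1e5 * step, by = step)
    vals <- g(mus)
    i <- which(vals <= 0)[1]
    if (!is.na(i)) {
      lo <- if (i == 1) from - step else mus[i - 1]
      hi <- mus[i]
      break
    }
    from <- from + 1e5 * step + step
    if (from > 50) stop("oracle: no sign change found below mu = 50")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# quick builder for an event tibble with defaults
make_events <- function(birth, tau, experiment_id = "e1",
                        concentration = 1, channel_id = "ch01") {
  n <- max(length(birth), length(tau))
  tibble::tibble(
    experiment_id = experiment_id,
    concentration_mmol_per_L = concentration,
    channel_id = channel_id,
    cell_id = sprintf("cell%04d", seq_len(n)),
    birth_time_h = rep_len(birth, n),
    generation_time_h = rep_len(tau, n)
  )
}

# pool lineage simulations (already window-filtered) until n events
simulate_event_pool <- function(n, mean_tau, cv, window,
                                family = "gamma") {
  out <- vector("list", 0)
  got <- 0
  while (got < n) {
    batch <- purrr::map(1:200, function(i) {
      lin <- simulate_lineage(mean_tau, family, cv, window)
      dplyr::filter(lin, birth_time_h >= window$t_start,
                    birth_time_h + generation_time_h <= window$t_end,
                    generation_time_h < window_length(window) - 1e-9)
    }) |> purrr::list_rbind()
    out <- c(out, list(batch))
    got <- got + nrow(batch)
  }
  dplyr::slice_head(purrr::list_rbind(out), n = n)
}

# discretized, window-truncated version of a gamma generation-time
# density on the imaging grid (the "truth" a corrected histogram should
# approach)
truncated_gamma_pmf <- function(mean_tau, cv, window) {
  shape <- 1 / cv^2
  rate <- shape / mean_tau
  dt <- window$delta_tau
  len <- window_length(window)
  k <- seq_len(ceiling(len / dt) - 1)
  lo <- (k - 0.5) * dt
  hi <- (k + 0.5) * dt
  p <- stats::pgamma(pmin(hi, len), shape, rate) -
    stats::pgamma(lo, shape, rate)
  tibble::tibble(tau_h = k * dt, probability = p / sum(p))
}

# total-variation distance between two discrete distributions given as
# (tau_h, probability) tibbles
tv_distance <- function(a, b) {
  m <- dplyr::full_join(a, b, by = "tau_h", suffix = c("_a", "_b"))
  pa <- dplyr::coalesce(m$probability_a, 0)
  pb <- dplyr::coalesce(m$probability_b, 0)
  sum(abs(pa - pb)) / 2
}
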