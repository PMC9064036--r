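#' Default probability that a replicate shows no growth at all
#'
#' Mother-machine replicates occasionally fail wholesale: at
#' bacteriostatic concentrations (>= 50 mmol/L) no channel ever divides,
#' near the toxicity threshold (20–50 mmol/L) replicate outcomes are
#' all-or-nothing, and at very low concentrations (< 0.05 mmol/L)
#' transport limitation keeps some replicates from dividing. In the
#' comfortable mid-range every replicate grows.
#'
#' @param c Concentration(s), mmol/L.
#' @return Probability/probabilities in `[0, 1]`.
#' @export
default_p_nongrowth <- function(c) {
  dplyr::case_when(
    c >= 50 ~ 1,
    c > 20 ~ 0.6,
    c >= 0.05 ~ 0,
    TRUE ~ 0.2
  )
}

#' Configuration of a simulated mother-machine study
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the study conditions the pipeline targets: 12 substrate
#' concentrations spanning four orders of magnitude, 5 biological
#' replicates each, 30 parallel growth channels per experiment, a 40 h
#' experiment imaged every 5 min and analyzed from 15 h, gamma-
#' distributed generation times with coefficient of variation 0.2, and
#' single-step Monod-with-inhibition kinetics mapping concentration to
#' the target population growth rate.
#'
#' @param concentrations Concentrations in mmol/L.
#' @param replicates Biological replicates per concentration.
#' @param channels Growth channels (mother lineages) per experiment.
#' @param window An [observation_window()].
#' @param tau_family Generation-time family: `"gamma"`, `"lognormal"` or
#'   `"fixed"`.
#' @param cv_tau Coefficient of variation of the generation times.
#' @param kinetic_model `"single"` or `"two"`.
#' @param kinetic_params Named list of parameters for the kinetic model.
#' @param p_nongrowth Function of concentration returning the
#'   probability that a replicate is entirely non-growing.
#' @param seed Master integer seed; every experiment and channel derives
#'   its own reproducible stream from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    concentrations = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 1, 6, 20, 30, 50, 100),
    replicates = 5,
    channels = 30,
    window = observation_window(),
    tau_family = c("gamma", "lognormal", "fixed"),
    cv_tau = 0.2,
    kinetic_model = c("single", "two"),
    kinetic_params = list(mu_max = 0.37, K = 0.185, K_I = 23.37, n_I = 4.2),
    p_nongrowth = default_p_nongrowth,
    seed = 1L) {
  tau_family <- match.arg(tau_family)
  kinetic_model <- match.arg(kinetic_model)
  check_window(window)
  stopifnot(
    length(concentrations) >= 1, all(concentrations >= 0),
    replicates >= 1, channels >= 1, cv_tau > 0,
    is.function(p_nongrowth),
    is.numeric(seed), length(seed) == 1, seed == floor(seed)
  )
  pr <- p_nongrowth(concentrations)
  if (any(pr < 0 | pr > 1)) {
    stop("`p_nongrowth` must return probabilities in [0, 1].",
         call. = FALSE)
  }
  structure(
    list(
      concentrations = concentrations, replicates = as.integer(replicates),
      channels = as.integer(channels), window = window,
      tau_family = tau_family, cv_tau = cv_tau,
      kinetic_model = kinetic_model, kinetic_params = kinetic_params,
      p_nongrowth = p_nongrowth, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# kinetic curve of a simulation config
config_mu <- function(config, c) {
  p <- config$kinetic_params
  if (config$kinetic_model == "single") {
    mu_single(c, p$mu_max, p$K, p$K_I, p$n_I)
  } else {
    mu_two(c, p$mu1, p$mu2, p$K1, p$K2, p$K_I, p$n_I)
  }
}

#' Mean generation time producing a target population growth rate
#'
#' Inverts the Euler–Lotka relation `1 = 2 E[exp(-mu tau)]` within a
#' parametric generation-time family: returns the family mean such that
#' the population growth rate is exactly `mu_target`. For the gamma
#' family the Laplace transform gives the closed form
#' `shape k = 1/cv^2`, `scale theta = (2^(1/k) - 1)/mu`, mean `k theta`;
#' the lognormal case is solved numerically; the fixed (point-mass)
#' family returns `log(2)/mu`.
#'
#' @param mu_target Target population growth rate, 1/h (> 0).
#' @param family `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param cv Coefficient of variation of the family (ignored for
#'   `"fixed"`).
#' @return Mean generation time, hours.
#' @examples
#' mean_tau_for_target_mu(0.5, "gamma", cv = 1) # 2 h
#' @export
mean_tau_for_target_mu <- function(mu_target,
                                   family = c("gamma", "lognormal", "fixed"),
                                   cv = 0.2) {
  family <- match.arg(family)
  if (!is.finite(mu_target) || mu_target <= 0) {
    stop("`mu_target` must be positive.", call. = FALSE)
  }
  if (family != "fixed" && (!is.finite(cv) || cv <= 0)) {
    stop("`cv` must be positive.", call. = FALSE)
  }
  switch(family,
    fixed = log(2) / mu_target,
    gamma = {
      k <- 1 / cv^2
      theta <- (2^(1 / k) - 1) / mu_target
      k * theta
    },
    lognormal = {
      s2 <- log(1 + cv^2)
      s <- sqrt(s2)
      laplace <- function(m) {
        stats::integrate(
          function(z) exp(-mu_target * exp(m + s * z)) * stats::dnorm(z),
          lower = -8, upper = 8, rel.tol = 1e-10
        )$value
      }
      anchor <- log(log(2) / mu_target)
      root <- stats::uniroot(
        function(m) laplace(m) - 0.5,
        lower = anchor - 10, upper = anchor + 10, tol = 1e-12
      )$root
      exp(root + s2 / 2)
    }
  )
}

# iid draws from a generation-time family with given mean and cv
draw_tau <- function(n, mean_tau, family, cv) {
  switch(family,
    fixed = rep(mean_tau, n),
    gamma = {
      shape <- 1 / cv^2
      stats::rgamma(n, shape = shape, rate = shape / mean_tau)
    },
    lognormal = {
      s2 <- log(1 + cv^2)
      stats::rlnorm(n, meanlog = log(mean_tau) - s2 / 2, sdlog = sqrt(s2))
    }
  )
}

#' Simulate one mother-cell lineage
#'
#' Simulates the division events of the single mother cell held at the
#' end of one growth channel (daughters are washed out immediately).
#' The mother's age at `t = 0` is uniform on `[0, tau_1)` — a
#' steady-state start — and subsequent generation times are drawn iid
#' from the configured family. Births and divisions are snapped onto the
#' imaging grid, and only complete lives are emitted: birth observed at
#' or after time 0 (the initial, partially observed life is never
#' emitted) and division at or before `t_end`. This reproduces the
#' natural censoring of a finite recording that the analysis pipeline
#' must correct.
#'
#' Uses the current RNG state; seed the session (or use
#' [simulate_experiment()], which manages per-channel streams) for
#' reproducibility.
#'
#' @param mean_tau Mean generation time, hours.
#' @param family Generation-time family (see [simulation_config()]).
#' @param cv Coefficient of variation.
#' @param window An [observation_window()]; only `t_end` and `delta_tau`
#'   are used here (the `t_start` cutoff belongs to the analysis).
#' @param initial_age Optional fixed initial age of the mother (hours);
#'   default draws it uniformly on `[0, tau_1)`.
#' @return A tibble with columns `birth_time_h`, `generation_time_h`.
#' @export
simulate_lineage <- function(mean_tau, family = "gamma", cv = 0.2,
                             window = observation_window(),
                             initial_age = NULL) {
  check_window(window)
  stopifnot(mean_tau > 0)
  t_end <- window$t_end
  dt <- window$delta_tau
  tau1 <- draw_tau(1, mean_tau, family, cv)
  age <- if (is.null(initial_age)) stats::runif(1, 0, tau1) else initial_age
  t <- tau1 - age # first division of the (unobserved-birth) initial life
  births <- numeric(0)
  taus <- numeric(0)
  while (t <= t_end) {
    tau <- draw_tau(1, mean_tau, family, cv)
    b <- snap_to_grid(t, dt)
    d <- snap_to_grid(t + tau, dt)
    if (d <= t_end + 1e-9 && d - b > 1e-9 && b >= -1e-9) {
      births <- c(births, b)
      taus <- c(taus, d - b)
    }
    t <- t + tau
  }
  tibble::tibble(birth_time_h = births, generation_time_h = taus)
}

# deterministic 32-bit stream seed per (master seed, experiment, channel);
# multipliers kept small so double arithmetic stays exact
stream_seed <- function(seed, conc_index, rep_index, channel = 0L) {
  base <- (seed %% 2147483629) * 65537 +
    conc_index * 8191 + rep_index * 127
  ((base * 31 + channel) %% 2147483629) + 1
}

#' Simulate one experiment (one chip replicate)
#'
#' Simulates all growth channels of one replicate at one concentration.
#' With probability `p_nongrowth(c)` the replicate is entirely
#' non-growing and emits no events; otherwise the target population
#' growth rate is taken from the configured kinetic model and converted
#' to the family mean generation time through the exact Euler–Lotka
#' inverse, and each channel contributes one independent mother lineage.
#' A concentration with zero model growth rate (e.g. `c = 0`) emits no
#' events. RNG streams are derived per (experiment, channel) from the
#' master seed, so adding replicates never perturbs existing ones.
#'
#' @param concentration Substrate concentration, mmol/L.
#' @param config A [simulation_config()].
#' @param conc_index,rep_index 1-based indices identifying the
#'   experiment within the study design (used for the RNG stream and
#'   the experiment id).
#' @return A list with `events` (tibble in the canonical event-table
#'   columns) and `truth` (one-row tibble: `experiment_id`,
#'   `concentration_mmol_per_L`, `mu_true_per_h`, `mean_tau_h`,
#'   `family`, `cv_tau`, `nongrowth`).
#' @export
simulate_experiment <- function(concentration, config,
                                conc_index = 1L, rep_index = 1L) {
  stopifnot(inherits(config, "simulation_config"), concentration >= 0)
  id <- sprintf("c%g_r%d", concentration, rep_index)
  mu <- config_mu(config, concentration)
  empty <- tibble::tibble(
    experiment_id = character(), concentration_mmol_per_L = double(),
    channel_id = character(), cell_id = character(),
    birth_time_h = double(), generation_time_h = double()
  )
  truth <- tibble::tibble(
    experiment_id = id, concentration_mmol_per_L = concentration,
    mu_true_per_h = mu, mean_tau_h = NA_real_,
    family = config$tau_family, cv_tau = config$cv_tau, nongrowth = FALSE
  )
  withr::local_seed(stream_seed(config$seed, conc_index, rep_index))
  if (stats::runif(1) < config$p_nongrowth(concentration)) {
    truth$nongrowth <- TRUE
    return(list(events = empty, truth = truth))
  }
  if (mu <= 0) {
    return(list(events = empty, truth = truth))
  }
  mean_tau <- mean_tau_for_target_mu(mu, config$tau_family, config$cv_tau)
  truth$mean_tau_h <- mean_tau
  events <- purrr::map(seq_len(config$channels), function(j) {
    withr::local_seed(stream_seed(config$seed, conc_index, rep_index, j))
    lin <- simulate_lineage(mean_tau, config$tau_family, config$cv_tau,
                            config$window)
    if (nrow(lin) == 0) return(NULL)
    tibble::tibble(
      experiment_id = id,
      concentration_mmol_per_L = concentration,
      channel_id = sprintf("ch%02d", j),
      cell_id = sprintf("ch%02d_cell%03d", j, seq_len(nrow(lin))),
      birth_time_h = lin$birth_time_h,
      generation_time_h = lin$generation_time_h
    )
  }) |> purrr::list_rbind()
  if (nrow(events) == 0) events <- empty
  list(events = events, truth = truth)
}

#' Simulate a complete study
#'
#' Runs [simulate_experiment()] over the full concentration-by-replicate
#' design and pools the results. Optionally writes the event table
#' (`events.tsv`, the dialect of [read_events()]) and the ground-truth
#' manifest (`truth.json`) to a directory; reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list with `events` (pooled event tibble) and `truth`
#'   (manifest tibble, one row per experiment — including experiments
#'   that emitted no events).
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  design <- tidyr::expand_grid(
    conc_index = seq_along(config$concentrations),
    rep_index = seq_len(config$replicates)
  )
  sims <- purrr::pmap(design, function(conc_index, rep_index) {
    simulate_experiment(config$concentrations[conc_index], config,
                        conc_index, rep_index)
  })
  events <- purrr::list_rbind(purrr::map(sims, "events"))
  truth <- purrr::list_rbind(purrr::map(sims, "truth"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_events(events, file.path(out_dir, "events.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, na = "null", pretty = TRUE)
  }
  list(events = events, truth = truth)
}

#' Simulate replicate-level growth-rate observations
#'
#' Draws the `(concentration, mu)` replicate pairs that [fit_kinetics()]
#' consumes directly from a kinetic model: the model curve plus iid
#' Gaussian measurement noise, truncated at 0 (growth rates cannot be
#' negative). This bypasses the event-level simulation and is the
#' standard input for parameter-recovery checks of the fitting stage.
#'
#' @param concentrations Concentrations, mmol/L.
#' @param replicates Replicates per concentration.
#' @param sigma Noise standard deviation, 1/h (default 0.03).
#' @param model `"single"` or `"two"`.
#' @param params Named list of kinetic parameters.
#' @param seed Optional integer seed.
#' @return A tibble with columns `concentration`, `mu`, `experiment_id`.
#' @export
simulate_growth_observations <- function(
    concentrations = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 1, 6, 20, 30, 50, 100),
    replicates = 5, sigma = 0.03,
    model = c("single", "two"),
    params = list(mu_max = 0.37, K = 0.185, K_I = 23.37, n_I = 4.2),
    seed = NULL) {
  model <- match.arg(model)
  stopifnot(replicates >= 1, sigma >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  mu_fn <- if (model == "single") {
    function(c) mu_single(c, params$mu_max, params$K, params$K_I, params$n_I)
  } else {
    function(c) mu_two(c, params$mu1, params$mu2, params$K1, params$K2,
                       params$K_I, params$n_I)
  }
  tidyr::expand_grid(
    concentration = concentrations,
    replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(
      mu = pmax(0, mu_fn(.data$concentration) +
                  stats::rnorm(dplyr::n(), 0, sigma)),
      experiment_id = sprintf("c%g_r%d", .data$concentration,
                              .data$replicate)
    ) |>
    dplyr::select("concentration", "mu", "experiment_id")
}
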