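test_that("the Euler-Lotka inverse returns means that hit the target rate", {
  # gamma with cv = 1 is exponential: theta = 1/mu, mean = 2 h at mu = 0.5
  expect_equal(mean_tau_for_target_mu(0.5, "gamma", cv = 1), 2)
  expect_equal(mean_tau_for_target_mu(log(2), "fixed"), 1)
  # vanishing cv approaches the deterministic limit log(2)/mu
  expect_equal(mean_tau_for_target_mu(0.4, "gamma", cv = 0.01),
               log(2) / 0.4, tolerance = 1e-3)
  expect_error(mean_tau_for_target_mu(0, "gamma"), "positive")

  # the generating family really satisfies 2 E[exp(-mu tau)] = 1
  for (family in c("gamma", "lognormal")) {
    for (mu in c(0.1, 0.36, 0.7)) {
      m <- mean_tau_for_target_mu(mu, family, cv = 0.25)
      dens <- if (family == "gamma") {
        shape <- 1 / 0.25^2
        function(x) stats::dgamma(x, shape, rate = shape / m)
      } else {
        s2 <- log(1 + 0.25^2)
        function(x) stats::dlnorm(x, log(m) - s2 / 2, sqrt(s2))
      }
      lap <- stats::integrate(function(x) exp(-mu * x) * dens(x),
                              0, Inf, rel.tol = 1e-10)$value
      expect_equal(2 * lap, 1, tolerance = 1e-6)
    }
  }
})

test_that("a deterministic lineage emits exactly the enumerable events", {
  w0 <- observation_window(0, 40)
  lin <- simulate_lineage(5, "fixed", 0.2, w0, initial_age = 0)
  # initial life [0,5) is partially observed and never emitted; then
  # births 5,10,...,35 each divide within the 40 h recording: 7 events
  expect_equal(lin$birth_time_h, seq(5, 35, by = 5))
  expect_equal(lin$generation_time_h, rep(5, 7))
  # nothing completes when the generation time exceeds the recording
  none <- simulate_lineage(50, "fixed", 0.2, w0)
  expect_equal(nrow(none), 0)
})

test_that("lineage simulation is grid-snapped and seed-deterministic", {
  w <- observation_window()
  set.seed(99)
  a <- simulate_lineage(2, "gamma", 0.3, w)
  set.seed(99)
  b <- simulate_lineage(2, "gamma", 0.3, w)
  expect_identical(a, b)
  dt <- w$delta_tau
  expect_equal(a$birth_time_h / dt, round(a$birth_time_h / dt))
  expect_equal(a$generation_time_h / dt,
               round(a$generation_time_h / dt))
  expect_true(all(a$generation_time_h > 0))
  expect_true(all(a$birth_time_h + a$generation_time_h <= w$t_end + 1e-9))
})

test_that("observed (censored) generation times are biased short", {
  w <- observation_window()
  set.seed(31)
  pool <- simulate_event_pool(2000, mean_tau = 5, cv = 0.35, w)
  expect_lt(mean(pool$generation_time_h), 5)
})

test_that("experiment simulation honours kinetics and non-growth", {
  cfg <- simulation_config()

  none <- simulate_experiment(0, cfg, conc_index = 1, rep_index = 1)
  expect_equal(nrow(none$events), 0) # mu(0) = 0: nothing divides
  expect_equal(none$truth$mu_true_per_h, 0)

  grow <- simulate_experiment(6, cfg, conc_index = 8, rep_index = 1)
  expect_gte(nrow(grow$events), 50)
  expect_equal(grow$truth$mu_true_per_h,
               mu_single(6, 0.37, 0.185, 23.37, 4.2))
  expect_equal(grow$truth$mean_tau_h,
               mean_tau_for_target_mu(grow$truth$mu_true_per_h,
                                      "gamma", 0.2))
  expect_equal(unique(grow$events$experiment_id), "c6_r1")

  cfg_ng <- simulation_config(p_nongrowth = function(c) rep(1, length(c)))
  dead <- simulate_experiment(6, cfg_ng, conc_index = 8, rep_index = 1)
  expect_equal(nrow(dead$events), 0)
  expect_true(dead$truth$nongrowth)
})

test_that("event counts grow linearly with the number of channels", {
  n30 <- nrow(simulate_experiment(
    6, simulation_config(channels = 30), 8, 1)$events)
  n90 <- nrow(simulate_experiment(
    6, simulation_config(channels = 90), 8, 1)$events)
  expect_equal(n90 / n30, 3, tolerance = 0.2)
})

test_that("study simulation is reproducible and self-consistent", {
  cfg <- simulation_config(concentrations = c(0.2, 6, 100),
                           replicates = 2, channels = 10, seed = 4)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  study <- simulate_study(cfg, dir1)
  simulate_study(cfg, dir2)

  expect_equal(nrow(study$truth), 6) # 3 concentrations x 2 replicates
  expect_equal(anyDuplicated(study$truth$experiment_id), 0)
  # manifest growth rates equal the kinetic-model evaluations
  expect_equal(study$truth$mu_true_per_h,
               mu_single(study$truth$concentration_mmol_per_L,
                         0.37, 0.185, 23.37, 4.2))
  # byte-identical rerun
  expect_identical(readLines(file.path(dir1, "events.tsv")),
                   readLines(file.path(dir2, "events.tsv")))
  expect_identical(readLines(file.path(dir1, "truth.json")),
                   readLines(file.path(dir2, "truth.json")))
  # the written table reads back as valid events
  back <- read_events(file.path(dir1, "events.tsv"), cfg$window)
  expect_equal(nrow(back), nrow(study$events))
})

test_that("adding replicates never perturbs existing RNG streams", {
  cfg2 <- simulation_config(concentrations = 6, replicates = 2, seed = 7)
  cfg3 <- simulation_config(concentrations = 6, replicates = 3, seed = 7)
  s2 <- simulate_study(cfg2)
  s3 <- simulate_study(cfg3)
  expect_identical(
    s2$events,
    dplyr::filter(s3$events, !grepl("_r3$", experiment_id))
  )
})
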