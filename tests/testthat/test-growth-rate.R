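w <- observation_window() # length 25 h

test_that("correction factor follows the observable-window geometry", {
  expect_equal(correction_factor(5, w), 25 / 20) # = 1.25
  expect_equal(correction_factor(1e-9, w), 1, tolerance = 1e-9)
  taus <- seq(0.5, 24, by = 0.5)
  expect_true(all(diff(correction_factor(taus, w)) > 0))
  expect_true(all(correction_factor(taus, w) >= 1))
  expect_error(correction_factor(25, w), "window length")
  expect_error(correction_factor(30, w), "window length")
  expect_error(correction_factor(0, w), "positive")
  expect_error(correction_factor(-1, w), "positive")
})

test_that("distribution estimation weights counts by the correction", {
  # point mass
  d <- estimate_distribution(make_events(16, 2), w)
  expect_equal(d$tau_h, 2)
  expect_equal(d$probability, 1)

  # 10 events at 5 h (weight 1.25) and 10 at 15 h (weight 2.5):
  # 12.5 and 25 out of 37.5 -> 1/3 and 2/3
  ev <- make_events(rep(16, 20), c(rep(5, 10), rep(15, 10)))
  d2 <- estimate_distribution(ev, w)
  expect_equal(d2$count, c(10, 10))
  expect_equal(d2$weight, c(1.25, 2.5))
  expect_equal(d2$probability, c(1 / 3, 2 / 3))

  # equal counts at two bins: the longer tau always gets more mass
  ev3 <- make_events(rep(16, 8), c(rep(2, 4), rep(9, 4)))
  d3 <- estimate_distribution(ev3, w)
  expect_gt(d3$probability[2], d3$probability[1])

  expect_error(estimate_distribution(make_events(16, 2)[0, ], w),
               "classify")
})

test_that("estimated distributions are exactly normalized", {
  set.seed(11)
  for (i in 1:10) {
    tau <- sample(seq(1, 20, by = w$delta_tau), 30, replace = TRUE)
    d <- estimate_distribution(make_events(16, tau), w)
    expect_lt(abs(sum(d$probability) - 1), 1e-12)
    expect_true(all(diff(d$tau_h) > 0))
  }
})

test_that("rescaling all correction weights leaves probabilities unchanged", {
  ev <- make_events(rep(16, 30), sample(c(2, 5, 9, 14), 30, replace = TRUE))
  d <- estimate_distribution(ev, w)
  rescaled <- d$count * d$weight * 7.3
  expect_equal(rescaled / sum(rescaled), d$probability)
})

test_that("Euler-Lotka inversion matches closed forms", {
  point <- function(tau) tibble::tibble(tau_h = tau, probability = 1)
  expect_equal(solve_growth_rate(point(1)), log(2), tolerance = 1e-9)
  expect_equal(solve_growth_rate(point(2)), log(2) / 2, tolerance = 1e-9)
  # f(1) = f(2) = 1/2: substituting x = exp(-mu) gives x^2 + x - 1 = 0
  two <- tibble::tibble(tau_h = c(1, 2), probability = c(0.5, 0.5))
  expect_equal(solve_growth_rate(two), -log((sqrt(5) - 1) / 2),
               tolerance = 1e-8)
  # degenerate inputs
  expect_error(solve_growth_rate(two[0, ]), "empty")
  bad <- tibble::tibble(tau_h = c(1, 2), probability = c(0.5, 0.4))
  expect_error(solve_growth_rate(bad), "normalized")
})

test_that("solver agrees with the grid-search oracle on small supports", {
  set.seed(7)
  for (i in 1:8) {
    k <- sample(1:4, 1)
    tau <- sort(sample(seq(0.5, 6, by = 0.25), k))
    p <- stats::runif(k)
    p <- p / sum(p)
    dist <- tibble::tibble(tau_h = tau, probability = p)
    expect_equal(solve_growth_rate(dist), oracle_growth_rate(tau, p),
                 tolerance = 1e-8)
  }
})

test_that("heterogeneity statistics are probability-weighted moments", {
  point <- tibble::tibble(tau_h = 3, probability = 1)
  s <- heterogeneity_stats(point)
  expect_equal(s$var_tau_h2, 0)
  expect_equal(s$cv_tau, 0)

  d <- tibble::tibble(tau_h = c(1, 3), probability = c(0.5, 0.5))
  s2 <- heterogeneity_stats(d)
  expect_equal(s2$mean_tau_h, 2)
  expect_equal(s2$var_tau_h2, 1) # no finite-sample correction
  expect_equal(s2$cv_tau, 0.5)
})

test_that("growth rate and mean generation time satisfy the Jensen bound", {
  set.seed(21)
  for (i in 1:10) {
    tau <- sample(seq(1, 12, by = w$delta_tau), 80, replace = TRUE)
    d <- estimate_distribution(make_events(16, tau), w)
    mu <- solve_growth_rate(d)
    s <- heterogeneity_stats(d)
    expect_gte(mu * s$mean_tau_h, log(2) - 1e-9)
  }
  # equality iff variance is zero
  point <- tibble::tibble(tau_h = 2.5, probability = 1)
  expect_equal(solve_growth_rate(point) * 2.5, log(2), tolerance = 1e-9)
})

test_that("analyze_experiment composes filter, classify and inversion", {
  # 4 post-filter events -> growth rate exactly zero
  few <- analyze_experiment(make_events(rep(16, 4), 2), w)
  expect_equal(few$status, "zero_growth")
  expect_identical(few$growth_rate_per_h, 0)

  # 200 events all at tau = 1 h -> doubling every hour
  many <- analyze_experiment(make_events(rep(16, 200), 1), w)
  expect_equal(many$status, "analyzed")
  expect_equal(many$growth_rate_per_h, log(2), tolerance = 1e-9)
  expect_equal(many$var_tau_h2, 0)

  # 30 post-filter events -> excluded, no growth rate emitted
  mid <- analyze_experiment(make_events(rep(16, 30), 2), w)
  expect_equal(mid$status, "excluded")
  expect_true(is.na(mid$growth_rate_per_h))
})

test_that("the censoring correction removes the short-tau bias", {
  # uncorrected histograms under-weight long generation times, so their
  # mean sits below the corrected mean whenever variance is positive
  win <- observation_window(15, 40)
  set.seed(5)
  pool <- simulate_event_pool(3000, mean_tau = 4, cv = 0.35, win)
  ev <- make_events(pool$birth_time_h, pool$generation_time_h)
  corr <- estimate_distribution(ev, win)
  raw <- estimate_distribution(ev, win, correct = FALSE)
  expect_gt(heterogeneity_stats(corr)$mean_tau_h,
            heterogeneity_stats(raw)$mean_tau_h)
})
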