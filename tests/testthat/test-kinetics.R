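tbl1_single <- list(mu_max = 0.37, K = 0.185, K_I = 23.37, n_I = 4.2)
tbl1_two <- list(mu1 = 0.22, mu2 = 0.2, K1 = 0.061, K2 = 1.71,
                 K_I = 21.66, n_I = 3.5)

test_that("Hill inhibition has the right anchors and limits", {
  expect_equal(inhibition(0, 23.37, 4.2), 1)
  expect_equal(inhibition(23.37, 23.37, 4.2), 0.5)
  expect_equal(inhibition(100, 23.37, 4.2), 0.0022254, tolerance = 1e-4)
  expect_equal(inhibition(1e12, 23.37, 4.2), 0) # overflow-guarded
  taus <- inhibition(c(0.1, 1, 10, 100), 23.37, 4.2)
  expect_true(all(diff(taus) < 0))
})

test_that("model curves evaluate correctly at reference points", {
  expect_identical(mu_single(0, 0.37, 0.185, 23.37, 4.2), 0)
  expect_equal(do.call(mu_single, c(list(c = 6), tbl1_single)),
               0.35775, tolerance = 1e-4)
  expect_lt(do.call(mu_single, c(list(c = 1e6), tbl1_single)), 1e-10)

  expect_identical(do.call(mu_two, c(list(c = 0), tbl1_two)), 0)
  expect_equal(do.call(mu_two, c(list(c = 6), tbl1_two)),
               0.36930, tolerance = 1e-4)
  # K1 = K2, mu1 = mu2 = m reduces to single-step with mu_max = 2m
  cc <- c(0.05, 0.5, 5, 50)
  expect_equal(mu_two(cc, 0.15, 0.15, 0.3, 0.3, 20, 3),
               mu_single(cc, 0.3, 0.3, 20, 3))

  expect_equal(mu_monod(0.02, 0.26, 0.020), 0.13)
  expect_equal(mu_monod(0.020, 0.26, 0.020), 0.26 / 2)
  expect_equal(mu_teissier(0.014, 0.20, 0.014), 0.20 * (1 - exp(-1)))
})

test_that("both reference parameter sets peak between 2 and 8 mmol/L", {
  cc <- exp(seq(log(0.01), log(100), length.out = 4000))
  for (curve in list(
    do.call(mu_single, c(list(c = cc), tbl1_single)),
    do.call(mu_two, c(list(c = cc), tbl1_two))
  )) {
    c_peak <- cc[which.max(curve)]
    expect_gt(c_peak, 2)
    expect_lt(c_peak, 8)
    # unimodal: rises up to the peak, falls after it
    i <- which.max(curve)
    expect_true(all(diff(curve[1:i]) > 0))
    expect_true(all(diff(curve[i:length(curve)]) < 0))
  }
})

test_that("noiseless data are recovered essentially exactly", {
  cc <- exp(seq(log(0.01), log(100), length.out = 12))
  obs <- tibble::tibble(
    concentration = cc,
    mu = do.call(mu_single, c(list(c = cc), tbl1_single)),
    experiment_id = as.character(seq_along(cc))
  )
  fit <- fit_kinetics(obs, "single")
  expect_equal(as.list(fit$coefficients)[names(tbl1_single)],
               tbl1_single, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)

  obs_m <- tibble::tibble(concentration = cc, mu = mu_monod(cc, 0.26, 0.02))
  fit_m <- fit_kinetics(obs_m, "monod")
  expect_equal(unname(fit_m$coefficients), c(0.26, 0.02), tolerance = 1e-6)
})

test_that("fitting uninhibited data with the inhibition model pushes K_I out", {
  # Monod data carry no inhibition signal: the fitted inhibition term
  # stays ~1 over the whole data range (K_I driven towards its bound)
  cc <- exp(seq(log(0.01), log(100), length.out = 12))
  obs <- tibble::tibble(concentration = cc, mu = mu_monod(cc, 0.26, 0.02))
  fit <- suppressWarnings(fit_kinetics(obs, "single"))
  inh_over_range <- inhibition(max(cc), fit$coefficients[["K_I"]],
                               fit$coefficients[["n_I"]])
  expect_gt(inh_over_range, 0.95)
})

test_that("noisy replicate fits recover the generating parameters", {
  obs <- simulate_growth_observations(seed = 123)
  fit <- suppressWarnings(fit_kinetics(obs, "single"))
  expect_equal(fit$coefficients[["mu_max"]], 0.37, tolerance = 0.15)
  expect_equal(fit$coefficients[["K_I"]], 23.37, tolerance = 0.25)
  expect_equal(fit$n_obs, 60)
})

test_that("degenerate fitting inputs are rejected with a named deficit", {
  two_obs <- tibble::tibble(concentration = c(1, 2), mu = c(0.1, 0.2))
  expect_error(fit_kinetics(two_obs, "single"), "Under-determined")
  five_same <- tibble::tibble(concentration = rep(c(1, 2), c(3, 3)),
                              mu = rep(0.1, 6))
  expect_error(fit_kinetics(five_same, "single"), "distinct")
})

test_that("two-step fits respect the K1 <= K2 ordering convention", {
  cc <- exp(seq(log(0.01), log(100), length.out = 14))
  obs <- tibble::tibble(
    concentration = cc,
    mu = do.call(mu_two, c(list(c = cc), tbl1_two))
  )
  fit <- suppressWarnings(fit_kinetics(obs, "two"))
  expect_lte(fit$coefficients[["K1"]], fit$coefficients[["K2"]])
  expect_lt(fit$rss, 1e-6)
})

test_that("tidy, glance and the JSON report expose the fit", {
  obs <- simulate_growth_observations(seed = 9)
  fit <- suppressWarnings(fit_kinetics(obs, "single"))
  td <- tidy(fit)
  expect_equal(td$term, c("mu_max", "K", "K_I", "n_I"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 60)
  expect_equal(gl$n_par, 4)
  expect_gte(gl$rss, 0)

  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$model, "single")
  expect_equal(rep$n_obs, 60)
  expect_equal(length(rep$start_grid), fit$n_starts) # grid is recorded
  expect_named(rep$start_grid[[1]], c("mu_max", "K", "K_I", "n_I"))
})
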