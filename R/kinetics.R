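#' Hill-type substrate inhibition factor
#'
#' Multiplicative inhibition term suppressing growth at high substrate
#' concentration: \deqn{I(c) = \frac{1}{1 + (c/K_I)^{n_I}}.}
#' Equals 1 at `c = 0`, 1/2 at `c = K_I`, and tends to 0 as `c` grows;
#' `n_I` sets the steepness. Evaluation is guarded so that very large
#' `(c/K_I)^{n_I}` returns exactly 0 instead of overflowing.
#'
#' @param c Substrate concentration(s), mmol/L, `>= 0`.
#' @param K_I Inhibition constant, mmol/L.
#' @param n_I Hill exponent (dimensionless).
#' @return Factor(s) in (0, 1].
#' @export
inhibition <- function(c, K_I, n_I) {
  stopifnot(K_I > 0, n_I > 0)
  if (any(c < 0)) stop("`c` must be non-negative.", call. = FALSE)
  x <- (c / K_I)^n_I
  out <- 1 / (1 + x)
  out[!is.finite(x)] <- 0
  out
}

#' Single-step growth kinetic: Monod saturation with Hill inhibition
#'
#' \deqn{\mu(c) = \mu_{max} \frac{c}{K + c} \cdot \frac{1}{1 + (c/K_I)^{n_I}}}
#'
#' One rate-limiting uptake/metabolic step with substrate inhibition at
#' high concentration. `mu(0) = 0` exactly, and for `n_I > 1` the curve
#' is unimodal: it rises Monod-like, peaks, and is driven back to 0 by
#' the inhibition term.
#'
#' @param c Concentration(s), mmol/L.
#' @param mu_max Maximum growth rate, 1/h.
#' @param K Half-velocity constant, mmol/L.
#' @inheritParams inhibition
#' @return Growth rate(s), 1/h.
#' @examples
#' mu_single(6, 0.37, 0.185, 23.37, 4.2) # ~0.358 1/h
#' @export
mu_single <- function(c, mu_max, K, K_I, n_I) {
  stopifnot(mu_max > 0, K > 0)
  if (any(c < 0)) stop("`c` must be non-negative.", call. = FALSE)
  mu_max * c / (K + c) * inhibition(c, K_I, n_I)
}

#' Two-step growth kinetic: parallel Michaelis-Menten terms with Hill inhibition
#'
#' \deqn{\mu(c) = \left(\mu_1 \frac{c}{K_1 + c} + \mu_2 \frac{c}{K_2 + c}\right)
#'   \cdot \frac{1}{1 + (c/K_I)^{n_I}}}
#'
#' Two uptake systems (e.g. passive porin transport and an active
#' transporter) working in parallel, both subject to the same
#' high-concentration inhibition. With `K1 = K2` and `mu1 = mu2 = m` it
#' reduces to the single-step model with `mu_max = 2m`.
#'
#' @param c Concentration(s), mmol/L.
#' @param mu1,mu2 Maximal growth rates of the two kinetics, 1/h.
#' @param K1,K2 Respective half-velocity constants, mmol/L.
#' @inheritParams inhibition
#' @return Growth rate(s), 1/h.
#' @export
mu_two <- function(c, mu1, mu2, K1, K2, K_I, n_I) {
  stopifnot(mu1 > 0, mu2 > 0, K1 > 0, K2 > 0)
  if (any(c < 0)) stop("`c` must be non-negative.", call. = FALSE)
  (mu1 * c / (K1 + c) + mu2 * c / (K2 + c)) * inhibition(c, K_I, n_I)
}

#' Comparator kinetics without inhibition
#'
#' Classic two-parameter saturating kinetics used as comparators:
#' Monod, \eqn{\mu_{max} c / (K + c)}, and Teissier,
#' \eqn{\mu_{max}(1 - e^{-c/K})}.
#'
#' @param c Concentration(s), mmol/L.
#' @param mu_max Maximum growth rate, 1/h.
#' @param K Half-velocity constant, mmol/L.
#' @return Growth rate(s), 1/h.
#' @export
mu_monod <- function(c, mu_max, K) {
  stopifnot(mu_max > 0, K > 0)
  if (any(c < 0)) stop("`c` must be non-negative.", call. = FALSE)
  mu_max * c / (K + c)
}

#' @rdname mu_monod
#' @export
mu_teissier <- function(c, mu_max, K) {
  stopifnot(mu_max > 0, K > 0)
  if (any(c < 0)) stop("`c` must be non-negative.", call. = FALSE)
  mu_max * (1 - exp(-c / K))
}

# model registry: formulas, parameter names, bounds
kinetic_models <- list(
  single = list(
    fn = function(c, p) mu_single(c, p[["mu_max"]], p[["K"]],
                                  p[["K_I"]], p[["n_I"]]),
    pars = c("mu_max", "K", "K_I", "n_I"),
    lower = c(mu_max = 1e-4, K = 1e-4, K_I = 1, n_I = 0.5),
    upper = c(mu_max = 2, K = 10, K_I = 1e3, n_I = 10)
  ),
  two = list(
    fn = function(c, p) mu_two(c, p[["mu1"]], p[["mu2"]], p[["K1"]],
                               p[["K2"]], p[["K_I"]], p[["n_I"]]),
    pars = c("mu1", "mu2", "K1", "K2", "K_I", "n_I"),
    lower = c(mu1 = 1e-4, mu2 = 1e-4, K1 = 1e-4, K2 = 1e-4,
              K_I = 1, n_I = 0.5),
    upper = c(mu1 = 2, mu2 = 2, K1 = 10, K2 = 10, K_I = 1e3, n_I = 10)
  ),
  monod = list(
    fn = function(c, p) mu_monod(c, p[["mu_max"]], p[["K"]]),
    pars = c("mu_max", "K"),
    lower = c(mu_max = 1e-4, K = 1e-4),
    upper = c(mu_max = 2, K = 10)
  ),
  teissier = list(
    fn = function(c, p) mu_teissier(c, p[["mu_max"]], p[["K"]]),
    pars = c("mu_max", "K"),
    lower = c(mu_max = 1e-4, K = 1e-4),
    upper = c(mu_max = 2, K = 10)
  )
)

# Gauss-Newton standard errors at the optimum: sigma^2 (J'J)^-1 with a
# forward-difference Jacobian of the residual vector; NA when the
# curvature is singular (unidentified directions, e.g. inactive terms)
fit_std_errors <- function(resid_fn, par, rss, df) {
  f0 <- resid_fn(par)
  jac <- vapply(seq_along(par), function(i) {
    h <- 1e-7 * max(abs(par[i]), 1)
    p2 <- par
    p2[i] <- p2[i] + h
    (resid_fn(p2) - f0) / h
  }, numeric(length(f0)))
  sigma2 <- rss / max(df, 1)
  cov <- tryCatch(sigma2 * solve(crossprod(jac)),
                  error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(par)) else sqrt(diag(cov))
  names(se) <- names(par)
  se
}

# deterministic multi-start grid: n geometric interior points per parameter
start_grid <- function(lower, upper, n = 3) {
  pts <- purrr::map2(lower, upper, function(a, b) {
    exp(seq(log(a), log(b), length.out = n + 2))[2:(n + 1)]
  })
  grid <- expand.grid(pts, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(lower)
  grid
}

#' Fit a growth kinetic to replicate growth-rate observations
#'
#' Unweighted least squares of a kinetic model on replicate-level
#' `(concentration, mu)` pairs — individual experiment results, not
#' per-concentration means, so replicate scatter (including zero-growth
#' replicates entered as `mu = 0`) shapes the fit. Optimization uses
#' bounded Levenberg–Marquardt ([minpack.lm::nls.lm()]) started from a
#' deterministic geometric grid of initial guesses (`n_starts` values per
#' parameter); the converged start with the smallest residual sum of
#' squares wins, so fitting is reproducible without a seed.
#'
#' @param observations Tibble with columns `concentration` (mmol/L) and
#'   `mu` (1/h, zero allowed), one row per replicate experiment.
#' @param model One of `"single"`, `"two"`, `"monod"`, `"teissier"`.
#' @param include_zero_growth Keep `mu = 0` replicates in the fit
#'   (default `TRUE`).
#' @param n_starts Initial-guess values per parameter (default 3).
#'
#' @return An object of class `kinetic_fit`: parameter estimates,
#'   standard errors from the local curvature, residual sum of squares,
#'   convergence diagnostics and the start grid used. Supports
#'   [predict()], [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_kinetics <- function(observations,
                         model = c("single", "two", "monod", "teissier"),
                         include_zero_growth = TRUE, n_starts = 3) {
  model <- match.arg(model)
  spec <- kinetic_models[[model]]
  obs <- tibble::as_tibble(observations)
  if (!all(c("concentration", "mu") %in% names(obs))) {
    stop("`observations` needs columns `concentration` and `mu`.",
         call. = FALSE)
  }
  if (any(obs$concentration < 0) || any(obs$mu < 0)) {
    stop("Concentrations and growth rates must be non-negative.",
         call. = FALSE)
  }
  if (!include_zero_growth) {
    obs <- dplyr::filter(obs, .data$mu > 0)
  }
  n_par <- length(spec$pars)
  if (nrow(obs) < n_par + 1) {
    stop(sprintf(
      "Under-determined fit: %d observation(s) for %d parameters; need at least %d.",
      nrow(obs), n_par, n_par + 1
    ), call. = FALSE)
  }
  if (dplyr::n_distinct(obs$concentration) < 3) {
    stop("Need observations at >= 3 distinct concentrations.", call. = FALSE)
  }
  resid_fn <- function(par) {
    obs$mu - spec$fn(obs$concentration, as.list(par))
  }
  grid <- start_grid(spec$lower, spec$upper, n_starts)
  attempts <- purrr::map(seq_len(nrow(grid)), function(i) {
    start <- unlist(grid[i, , drop = TRUE])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = spec$lower, upper = spec$upper,
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) e
    )
    # info codes 1-4 signal convergence of the Levenberg-Marquardt run
    if (inherits(fit, "error")) {
      list(ok = FALSE, rss = Inf, message = conditionMessage(fit))
    } else if (!(fit$info %in% 1:4)) {
      list(ok = FALSE, rss = sum(fit$fvec^2), message = fit$message)
    } else {
      list(ok = TRUE, rss = sum(fit$fvec^2), fit = fit)
    }
  })
  ok <- purrr::map_lgl(attempts, "ok")
  if (!any(ok)) {
    info <- sprintf("start %d: rss %.4g (%s)",
                    seq_along(attempts),
                    purrr::map_dbl(attempts, "rss"),
                    purrr::map_chr(attempts, "message"))
    stop("Kinetic fit failed to converge from every start:\n",
         paste(utils::head(info, 8), collapse = "\n"), call. = FALSE)
  }
  rss_all <- purrr::map_dbl(attempts, function(a) if (a$ok) a$rss else Inf)
  best <- attempts[[which.min(rss_all)]]$fit
  coefs <- best$par
  se <- fit_std_errors(resid_fn, coefs, sum(best$fvec^2),
                       nrow(obs) - length(coefs))
  if (model == "two" && coefs[["K1"]] > coefs[["K2"]]) {
    # identifiability convention K1 <= K2: swap the two branches
    coefs[c("mu1", "mu2", "K1", "K2")] <- coefs[c("mu2", "mu1", "K2", "K1")]
    se[c("mu1", "mu2", "K1", "K2")] <- se[c("mu2", "mu1", "K2", "K1")]
  }
  at_bound <- names(coefs)[
    coefs <= spec$lower[names(coefs)] * (1 + 1e-6) |
      coefs >= spec$upper[names(coefs)] * (1 - 1e-6)
  ]
  if (length(at_bound) > 0) {
    warning("Parameter(s) at fit bounds: ",
            paste(at_bound, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      model = model, coefficients = coefs, std_errors = se,
      rss = sum(stats::resid(best)^2), n_obs = nrow(obs),
      df_residual = nrow(obs) - length(coefs), data = obs,
      n_starts = nrow(grid), n_converged = sum(ok),
      at_bound = at_bound, start_grid = tibble::as_tibble(grid)
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> model '%s', %d observations\n",
              x$model, x$n_obs))
  print(round(x$coefficients, 5))
  cat(sprintf("RSS %.5g on %d df (%d/%d starts converged)\n",
              x$rss, x$df_residual, x$n_converged, x$n_starts))
  invisible(x)
}

#' Predict growth rates from a fitted kinetic
#'
#' @param object A `kinetic_fit`.
#' @param concentration Concentrations (mmol/L) at which to evaluate the
#'   fitted curve; defaults to the fitted data's concentrations.
#' @param ... Unused.
#' @return Predicted growth rates, 1/h.
#' @export
predict.kinetic_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration
  kinetic_models[[object$model]]$fn(concentration,
                                    as.list(object$coefficients))
}

#' Tidy a kinetic fit into a parameter table
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors)
  )
}

#' One-row fit summary
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `rss`, `sigma`, `n_obs`, `n_par`,
#'   `n_converged`, `n_starts`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, rss = x$rss,
    sigma = sqrt(x$rss / max(x$df_residual, 1)),
    n_obs = x$n_obs, n_par = length(x$coefficients),
    n_converged = x$n_converged, n_starts = x$n_starts
  )
}

#' Export a fit report as JSON
#'
#' @param fit A `kinetic_fit`.
#' @param path Output file path.
#' @return `fit`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  jsonlite::write_json(
    list(
      model = fit$model,
      estimates = as.list(fit$coefficients),
      std_errors = as.list(fit$std_errors),
      rss = fit$rss, n_obs = fit$n_obs,
      n_starts = fit$n_starts, n_converged = fit$n_converged,
      at_bound = fit$at_bound,
      start_grid = fit$start_grid
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(fit)
}
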