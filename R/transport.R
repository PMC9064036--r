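#' Transport parameters of the growth channel
#'
#' Physical constants for the diffusive transport-limitation estimate.
#' All quantities are SI; the defaults describe protocatechuate (PCA)
#' diffusing in water into a cell-packed microfluidic growth channel:
#' diffusivity `D`, the half-saturation concentration `g_bar` fitted in
#' prior monolayer-chamber work, the nutrient penetration depth `l_g`,
#' the areal cell density `rho`, the chamber height `h`, and the growth
#' channel length `l`.
#'
#' @param D Diffusivity, m^2/s (default 2.8e-10).
#' @param g_bar Half-saturation concentration, mol/m^3 (default 0.0199,
#'   i.e. 19.9 umol/L).
#' @param l_g Penetration depth, m (default 3.78e-6).
#' @param rho Areal cell density, 1/m^2 (default 0.66e12, i.e.
#'   0.66 um^-2).
#' @param h Chamber height, m (default 0.8e-6).
#' @param l Growth-channel length, m (default 20e-6).
#' @return A list of class `transport_params`.
#' @export
transport_params <- function(D = 2.8e-10, g_bar = 0.0199, l_g = 3.78e-6,
                             rho = 0.66e12, h = 0.8e-6, l = 20e-6) {
  p <- list(D = D, g_bar = g_bar, l_g = l_g, rho = rho, h = h, l = l)
  bad <- names(p)[!purrr::map_lgl(p, function(x) {
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  })]
  if (length(bad) > 0) {
    stop("Transport parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (l <= l_g) {
    warning("Channel length `l` does not exceed the penetration depth ",
            "`l_g`; the transport estimate assumes l > l_g.", call. = FALSE)
  }
  structure(p, class = "transport_params")
}

#' Per-cell nutrient uptake rate
#'
#' Inverts the penetration-depth relation
#' \eqn{l_g^2 = D \bar g h / (\rho u)} for the saturated single-cell
#' uptake rate: \deqn{u = \frac{D \bar g h}{\rho\, l_g^2}.}
#'
#' @param p A [transport_params()] object.
#' @return Uptake rate per cell, mol/s.
#' @examples
#' single_cell_uptake(transport_params()) # ~4.7e-19 mol/s
#' @export
single_cell_uptake <- function(p) {
  stopifnot(inherits(p, "transport_params"))
  p$D * p$g_bar * p$h / (p$rho * p$l_g^2)
}

#' Colony volumetric uptake rate
#'
#' Converts a per-cell uptake rate into an uptake per unit colony volume
#' for a cell monolayer of areal density `rho` in a chamber of height
#' `h`: \deqn{\hat U = u \rho / h.}
#'
#' @param u Per-cell uptake, mol/s.
#' @param rho Areal cell density, 1/m^2.
#' @param h Chamber height, m.
#' @return Volumetric uptake, mol/(s m^3).
#' @export
volumetric_uptake <- function(u, rho, h) {
  if (any(c(u, rho, h) <= 0) || any(!is.finite(c(u, rho, h)))) {
    stop("`u`, `rho` and `h` must be strictly positive.", call. = FALSE)
  }
  u * rho / h
}

#' Steady-state nutrient profile along a consuming channel
#'
#' One-dimensional diffusion with zeroth-order (saturated) volumetric
#' consumption `U_hat` in a channel of length `l` open at both ends with
#' inlet concentration `c_in` at both openings:
#' \deqn{c(x) = c_{in} - \frac{\hat U\, x (l - x)}{2 D},}
#' clipped at 0. The profile is symmetric about the channel centre,
#' where the concentration drop is largest, \eqn{\hat U l^2 / (8D)}.
#'
#' @param x Position(s) along the channel, m, in `[0, l]`.
#' @param c_in Inlet concentration, mol/m^3.
#' @param U_hat Volumetric uptake, mol/(s m^3).
#' @param D Diffusivity, m^2/s.
#' @param l Channel length, m.
#' @return Concentration(s) at `x`, mol/m^3.
#' @export
concentration_profile <- function(x, c_in, U_hat, D, l) {
  stopifnot(D > 0, l > 0, U_hat >= 0, c_in >= 0)
  if (any(x < -1e-15 | x > l * (1 + 1e-12))) {
    stop("`x` must lie within [0, l].", call. = FALSE)
  }
  pmax(0, c_in - U_hat * x * (l - x) / (2 * D))
}

#' Critical inlet concentration for diffusive transport limitation
#'
#' The inlet concentration below which diffusion through the channel
#' openings can no longer keep the channel centre adequately supplied,
#' under zeroth-order (saturated) uptake. Two conventions are exposed:
#' `"half_center"` (default) is the inlet concentration at which the
#' centre concentration falls to half the inlet value, giving
#' \eqn{c_{crit} = \hat U l^2 / (4D)}; `"center_drop"` reports the
#' concentration drop at the centre itself, \eqn{\hat U l^2 / (8D)}.
#'
#' @param U_hat Volumetric uptake, mol/(s m^3).
#' @param D Diffusivity, m^2/s.
#' @param l Channel length, m.
#' @param convention `"half_center"` or `"center_drop"` (see Details).
#' @return Critical concentration in mmol/L (numerically equal to
#'   mol/m^3).
#' @export
critical_concentration <- function(U_hat, D, l,
                                   convention = c("half_center",
                                                  "center_drop")) {
  convention <- match.arg(convention)
  if (any(c(U_hat, D, l) <= 0) || any(!is.finite(c(U_hat, D, l)))) {
    stop("`U_hat`, `D` and `l` must be strictly positive.", call. = FALSE)
  }
  denom <- if (convention == "half_center") 4 else 8
  U_hat * l^2 / (denom * D) # mol/m^3 == mmol/L
}

#' Full transport-limitation report
#'
#' Computes the per-cell uptake, the volumetric uptake, the critical
#' inlet concentration (both conventions) and a sampled steady-state
#' concentration profile at the critical inlet concentration.
#'
#' @param p A [transport_params()] object.
#' @param n_profile Number of sample points of the profile (default 41).
#' @return A list with elements `u_mol_per_s`, `U_hat_mol_per_s_m3`,
#'   `c_crit_mmol_per_L`, `c_crit_center_drop_mmol_per_L`, and `profile`
#'   (tibble `x_um`, `c_mmol_per_L`).
#' @export
transport_report <- function(p, n_profile = 41) {
  stopifnot(inherits(p, "transport_params"))
  u <- single_cell_uptake(p)
  U_hat <- volumetric_uptake(u, p$rho, p$h)
  c_crit <- critical_concentration(U_hat, p$D, p$l)
  x <- seq(0, p$l, length.out = n_profile)
  profile <- tibble::tibble(
    x_um = x * 1e6,
    c_mmol_per_L = concentration_profile(x, c_crit, U_hat, p$D, p$l)
  )
  list(
    u_mol_per_s = u,
    U_hat_mol_per_s_m3 = U_hat,
    c_crit_mmol_per_L = c_crit,
    c_crit_center_drop_mmol_per_L =
      critical_concentration(U_hat, p$D, p$l, "center_drop"),
    profile = profile
  )
}
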