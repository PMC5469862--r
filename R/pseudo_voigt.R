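#' Pseudo-Voigt line shape (unit area)
#'
#' Linear Gaussian-Lorentzian mix commonly used to model Raman bands.
#' Both components are normalised to unit area so that the profile can be
#' scaled directly by an integrated band area.
#'
#' @param x Wavenumber axis (1/cm).
#' @param center Band centre (1/cm).
#' @param fwhm Full width at half maximum (1/cm), > 0.
#' @param eta Lorentzian fraction in [0, 1]; 0 is pure Gaussian.
#' @return Numeric vector of densities (area under the curve is 1).
#' @examples
#' x <- seq(3000, 3800, by = 1)
#' y <- pseudo_voigt(x, 3429, 200, 0.25)
#' @export
pseudo_voigt <- function(x, center, fwhm, eta = 0) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- x - center
  k <- 4 * log(2)
  g <- sqrt(k / pi) / fwhm * exp(-k * u^2 / fwhm^2)
  l <- 2 * fwhm / (pi * (fwhm^2 + 4 * u^2))
  (1 - eta) * g + eta * l
}

# Peak (at-centre) density of a unit-area pseudo-Voigt; amplitude = area * this.
pv_peak_density <- function(fwhm, eta) {
  (1 - eta) * sqrt(4 * log(2) / pi) / fwhm + eta * 2 / (pi * fwhm)
}

# Model intensities for a set of bands: sum_i area_i * pv(x; c_i, w_i, eta_i).
# `par` is a data.frame/list with columns area, center, fwhm, eta.
pv_model <- function(x, par) {
  y <- numeric(length(x))
  for (i in seq_along(par$area)) {
    y <- y + par$area[i] * pseudo_voigt(x, par$center[i], par$fwhm[i], par$eta[i])
  }
  y
}

# Analytic Jacobian of pv_model with respect to the packed parameter vector
# (area_1..n, center_1..n, fwhm_1..n, eta_1..n). Returns length(x) x 4n matrix.
pv_jacobian <- function(x, par) {
  n <- length(par$area)
  J <- matrix(0, nrow = length(x), ncol = 4L * n)
  k <- 4 * log(2)
  cg <- sqrt(k / pi)
  for (i in seq_len(n)) {
    a <- par$area[i]; c0 <- par$center[i]; w <- par$fwhm[i]; e <- par$eta[i]
    u <- x - c0
    g <- cg / w * exp(-k * u^2 / w^2)
    D <- w^2 + 4 * u^2
    l <- 2 * w / (pi * D)
    dg_dc <- g * (2 * k * u / w^2)
    dg_dw <- g * (-1 / w + 2 * k * u^2 / w^3)
    dl_dc <- 16 * w * u / (pi * D^2)
    dl_dw <- (8 * u^2 - 2 * w^2) / (pi * D^2)
    pv <- (1 - e) * g + e * l
    J[, i]           <- pv
    J[, n + i]       <- a * ((1 - e) * dg_dc + e * dl_dc)
    J[, 2L * n + i]  <- a * ((1 - e) * dg_dw + e * dl_dw)
    J[, 3L * n + i]  <- a * (l - g)
  }
  J
}
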