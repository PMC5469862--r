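#' Physical constants used by the flux calculations
#'
#' @format List with `D_Na`, the sodium diffusion coefficient at 25 C
#'   (1.33e-8 cm^2/s), and `F`, the Faraday constant (96485.332 C/mol).
#' @export
transport_constants <- function() {
  list(D_Na = 1.33e-8, F = 96485.332)
}

#' Mean cytosolic concentration change from a fitted gradient
#'
#' Analytic mean of the fitted linear delta[Na+](z) profile over the cell
#' thickness: (1/t) * integral_0^t (intercept + slope z) dz
#' = intercept + slope * t / 2.
#'
#' @param fit A [fit_gradient()] result (or any list with `slope` and
#'   `intercept` in mM/um and mM).
#' @param t Cell thickness (micrometres), > 0.
#' @return Mean concentration change (mM).
#' @export
mean_concentration_change <- function(fit, t) {
  if (!is.numeric(t) || t <= 0) stop("thickness t must be positive")
  fit$intercept + fit$slope * t / 2
}

#' Sodium flux from the intracellular concentration gradient (Fick's law)
#'
#' The stored gradient uses instrument coordinates (z increasing from the
#' basolateral support toward the apical membrane); the flux convention
#' takes z positive from the apical to the basolateral surface, so the
#' gradient is negated before applying J = -D * d[Na+]/dz. With the unit
#' conversion 1 mM/um = 1e-2 mol/cm^4 this reduces to
#' J = D * slope_instrument * 1e-2.
#'
#' @param gradient_instrument d(delta[Na+])/dz in mM per micrometre,
#'   instrument coordinates (positive = concentration rising apically).
#' @param D Diffusion coefficient (cm^2/s), default sodium at 25 C.
#' @return Flux in mol s^-1 cm^-2 (positive = net apical-to-basolateral
#'   transport).
#' @export
sodium_flux <- function(gradient_instrument, D = transport_constants()$D_Na) {
  if (!is.finite(gradient_instrument) || !is.finite(D)) {
    stop("gradient and D must be finite")
  }
  if (D <= 0) stop("diffusion coefficient must be positive")
  D * gradient_instrument * 1e-2
}

#' Equivalent short-circuit current from a sodium flux
#'
#' I_sc = J * F, expressed in microamperes per cm^2. Comparable to the
#' short-circuit current increase measured across an epithelium in an
#' Ussing chamber.
#'
#' @param J Sodium flux (mol s^-1 cm^-2).
#' @param F Faraday constant (C/mol).
#' @return Current density (uA cm^-2).
#' @export
short_circuit_current <- function(J, F = transport_constants()$F) {
  if (!is.finite(J)) stop("flux must be finite")
  J * F * 1e6
}

#' Assemble the full flux result for a treated-vs-control comparison
#'
#' @param gradient A [fit_gradient()] result (instrument coordinates).
#' @param t Cell thickness (um).
#' @param D,F Physical constants, see [transport_constants()].
#' @return Object of class `flux_result`: `mean_delta_conc` (mM, equal for
#'   Na+ and Cl- under electroneutrality), `gradient_instrument` and
#'   `gradient_paper_convention` (mM/um), `pearson_r`, `D`, `F`, `J`
#'   (mol s^-1 cm^-2), `I_sc` (uA cm^-2), `thickness`.
#' @export
flux_result <- function(gradient, t, D = transport_constants()$D_Na,
                        F = transport_constants()$F) {
  J <- sodium_flux(gradient$slope, D)
  structure(list(mean_delta_conc = mean_concentration_change(gradient, t),
                 gradient_instrument = gradient$slope,
                 gradient_paper_convention = -gradient$slope,
                 pearson_r = gradient$pearson_r,
                 D = D, F = F, J = J,
                 I_sc = short_circuit_current(J, F),
                 thickness = t),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("Transcellular sodium transport estimate\n")
  cat(sprintf("  cell thickness:            %.1f um\n", x$thickness))
  cat(sprintf("  gradient (apical->baso):   %.3f mM/um (Pearson %.3f)\n",
              x$gradient_paper_convention, x$pearson_r))
  cat(sprintf("  mean delta[Na+]=[Cl-]:     %.2f mM\n", x$mean_delta_conc))
  cat(sprintf("  flux delta-J_Na:           %.3e mol s^-1 cm^-2\n", x$J))
  cat(sprintf("  short-circuit delta-I_sc:  %.2f uA cm^-2\n", x$I_sc))
  invisible(x)
}
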