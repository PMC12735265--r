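#' Frozen (solid) fraction of tissue at a given temperature
#'
#' Piecewise-linear phase fraction: 0 above the upper phase-transition
#' temperature, 1 below the lower one, and a linear ramp across the mushy
#' interval. Continuous and non-increasing in temperature.
#'
#' @param T temperature, °C (vectorised).
#' @param p a [tissue_params()] object.
#' @return Numeric vector of solid fractions in \[0, 1\].
#' @export
frozen_fraction <- function(T, p) {
  stopifnot(inherits(p, "tissue_params"))
  if (any(!is.finite(T))) stop("frozen_fraction: non-finite temperature",
                               call. = FALSE)
  f <- (p$T_mu - T) / (p$T_mu - p$T_ml)
  pmin(1, pmax(0, f))
}

#' Phase-dependent thermal conductivity
#'
#' Three-branch piecewise form: unfrozen value above `T_mu`, frozen value
#' below `T_ml`, arithmetic mean of the two inside the mushy interval
#' (endpoints inclusive to the mushy branch).
#'
#' @inheritParams frozen_fraction
#' @return Conductivity, W/(m·°C), vectorised over `T`.
#' @export
tissue_conductivity <- function(T, p) {
  stopifnot(inherits(p, "tissue_params"))
  if (any(!is.finite(T))) stop("tissue_conductivity: non-finite temperature",
                               call. = FALSE)
  k <- rep((p$k_u + p$k_f) / 2, length(T))
  k[T > p$T_mu] <- p$k_u
  k[T < p$T_ml] <- p$k_f
  k
}

# phase-dependent density (unfrozen above, frozen below, mean in mushy zone)
tissue_density <- function(T, p) {
  rho <- rep((p$rho_u + p$rho_f) / 2, length(T))
  rho[T > p$T_mu] <- p$rho_u
  rho[T < p$T_ml] <- p$rho_f
  rho
}

#' Effective volumetric heat capacity
#'
#' Returns \eqn{\rho(T) c(T)} in J/(m^3·°C) with the latent heat of freezing
#' added inside the mushy interval as \eqn{Q_{lf}/(T_{mu}-T_{ml})} (effective
#' heat capacity method). Integrating this capacity across the mushy interval
#' recovers the sensible heat plus `Q_lf` exactly.
#'
#' @inheritParams frozen_fraction
#' @return Volumetric heat capacity, J/(m^3·°C), vectorised over `T`.
#' @export
volumetric_heat_capacity <- function(T, p) {
  stopifnot(inherits(p, "tissue_params"))
  if (any(!is.finite(T))) stop("volumetric_heat_capacity: non-finite temperature",
                               call. = FALSE)
  mushy <- (p$rho_u + p$rho_f) / 2 * (p$c_u + p$c_f) / 2 +
    p$Q_lf / (p$T_mu - p$T_ml)
  C <- rep(mushy, length(T))
  C[T > p$T_mu] <- p$rho_u * p$c_u
  C[T < p$T_ml] <- p$rho_f * p$c_f
  C
}

#' Volumetric enthalpy of tissue
#'
#' Integral of [volumetric_heat_capacity()] from a fixed reference
#' temperature (−200 °C, below any temperature reachable by the load curve).
#' Piecewise linear and continuous; used by the solver's enthalpy-chord
#' capacity and the energy-balance instrumentation.
#'
#' @inheritParams frozen_fraction
#' @return Volumetric enthalpy, J/m^3, vectorised over `T`.
#' @export
tissue_enthalpy <- function(T, p) {
  stopifnot(inherits(p, "tissue_params"))
  Tref <- -200
  Cf <- p$rho_f * p$c_f
  Cu <- p$rho_u * p$c_u
  Cm <- (p$rho_u + p$rho_f) / 2 * (p$c_u + p$c_f) / 2 +
    p$Q_lf / (p$T_mu - p$T_ml)
  H_ml <- Cf * (p$T_ml - Tref)             # enthalpy at T_ml
  H_mu <- H_ml + Cm * (p$T_mu - p$T_ml)    # enthalpy at T_mu
  H <- numeric(length(T))
  lo <- T < p$T_ml
  hi <- T > p$T_mu
  mid <- !lo & !hi
  H[lo] <- Cf * (T[lo] - Tref)
  H[mid] <- H_ml + Cm * (T[mid] - p$T_ml)
  H[hi] <- H_mu + Cu * (T[hi] - p$T_mu)
  H
}

# secant (chord) capacity between two temperatures: conserves latent heat
# exactly when cells cross the mushy interval within one time step
chord_capacity <- function(Ta, Tb, p) {
  dT <- Ta - Tb
  small <- abs(dT) < 1e-9
  C <- volumetric_heat_capacity(Ta, p)
  idx <- which(!small)
  if (length(idx))
    C[idx] <- (tissue_enthalpy(Ta[idx], p) - tissue_enthalpy(Tb[idx], p)) /
      dT[idx]
  C
}

#' Perfusion and metabolic volumetric heat source
#'
#' The Pennes source term \eqn{w_b \rho_b c_b (T_b - T) + Q_m}. With
#' `frozen_shutdown = TRUE` (the default) the whole term is scaled by
#' \eqn{1 - } [frozen_fraction()], so fully frozen tissue neither perfuses
#' nor metabolises; with `FALSE` the term is applied unscaled at all
#' temperatures.
#'
#' @inheritParams frozen_fraction
#' @param frozen_shutdown logical; scale the source by the unfrozen fraction.
#' @return Volumetric heat source, W/m^3, vectorised over `T`.
#' @export
perfusion_metabolic_source <- function(T, p, frozen_shutdown = TRUE) {
  stopifnot(inherits(p, "tissue_params"))
  s <- p$w_b * p$rho_b * p$c_b * (p$T_b - T) + p$Q_m
  if (isTRUE(frozen_shutdown)) s <- s * (1 - frozen_fraction(T, p))
  s
}
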