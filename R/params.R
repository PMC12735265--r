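#' Tissue thermophysical parameter set
#'
#' Bundles the phase-dependent thermophysical constants of the tissue model:
#' unfrozen/frozen conductivity, specific heat and density, the volumetric
#' latent heat of freezing spread over the mushy interval
#' \eqn{[T_{ml}, T_{mu}]}, and the perfusion/metabolic source constants of the
#' Pennes equation. Defaults are the packaged liver/phantom tissue values.
#'
#' @param k_u,k_f thermal conductivity of unfrozen / frozen tissue, W/(m·°C).
#' @param c_u,c_f specific heat of unfrozen / frozen tissue, J/(kg·°C).
#' @param rho_u,rho_f density of unfrozen / frozen tissue, kg/m^3.
#' @param Q_lf volumetric latent heat of the phase transition, J/m^3.
#' @param T_mu,T_ml upper / lower phase-transition temperature, °C
#'   (`T_ml < T_mu`; tissue is liquid above `T_mu`, solid below `T_ml`,
#'   mushy in between).
#' @param w_b blood perfusion rate, 1/s.
#' @param rho_b blood density, kg/m^3.
#' @param c_b blood specific heat, J/(kg·°C).
#' @param T_b arterial blood temperature, °C.
#' @param Q_m metabolic volumetric heat generation, W/m^3.
#' @return An object of class `tissue_params`.
#' @export
#' @examples
#' p <- tissue_params()
#' tissue_conductivity(c(10, -4, -20), p)
tissue_params <- function(k_u = 0.5, k_f = 2,
                          c_u = 3600, c_f = 1800,
                          rho_u = 1000, rho_f = 998,
                          Q_lf = 250e6,
                          T_mu = -1, T_ml = -8,
                          w_b = 5e-4, rho_b = 1000, c_b = 3600,
                          T_b = 37, Q_m = 4200) {
  p <- list(k_u = k_u, k_f = k_f, c_u = c_u, c_f = c_f,
            rho_u = rho_u, rho_f = rho_f, Q_lf = Q_lf,
            T_mu = T_mu, T_ml = T_ml,
            w_b = w_b, rho_b = rho_b, c_b = c_b, T_b = T_b, Q_m = Q_m)
  for (nm in c("k_u", "k_f", "c_u", "c_f", "rho_u", "rho_f", "Q_lf")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("tissue_params: '", nm, "' must be strictly positive", call. = FALSE)
  }
  if (!is.finite(T_mu) || !is.finite(T_ml) || T_ml >= T_mu)
    stop("tissue_params: phase interval requires T_ml < T_mu", call. = FALSE)
  if (w_b < 0) stop("tissue_params: w_b must be >= 0", call. = FALSE)
  if (Q_m < 0) stop("tissue_params: Q_m must be >= 0", call. = FALSE)
  if (rho_b <= 0 || c_b <= 0)
    stop("tissue_params: blood properties must be positive", call. = FALSE)
  structure(p, class = "tissue_params")
}

#' Thermal damage kinetics parameter set
#'
#' Parameters of the threshold/time damage model: below the damage threshold
#' temperature `T_dc` the raw damage accumulator grows at rate `1/t_dc`, so a
#' cell held continuously below threshold reaches full damage after `t_dc`
#' seconds. `T_nc` is the necrosis temperature used for lethal-isotherm
#' reporting and `L_dc` the damage enthalpy of the optional damage heat
#' source (disabled by default so latent heat is released only once, through
#' the effective heat capacity).
#'
#' @param T_dc damage threshold temperature, °C.
#' @param t_dc damage time constant, s (> 0).
#' @param T_nc necrosis temperature, °C (`T_nc <= T_dc`).
#' @param L_dc damage enthalpy, J/kg.
#' @param apply_damage_enthalpy logical; register the damage enthalpy term as
#'   a heat source in the thermal solve (default `FALSE`).
#' @return An object of class `damage_params`.
#' @export
damage_params <- function(T_dc = -20, t_dc = 60, T_nc = -50, L_dc = 250e3,
                          apply_damage_enthalpy = FALSE) {
  if (!is.finite(t_dc) || t_dc <= 0)
    stop("damage_params: t_dc must be > 0", call. = FALSE)
  if (T_nc > T_dc)
    stop("damage_params: requires T_nc <= T_dc", call. = FALSE)
  structure(list(T_dc = T_dc, t_dc = t_dc, T_nc = T_nc, L_dc = L_dc,
                 apply_damage_enthalpy = isTRUE(apply_damage_enthalpy)),
            class = "damage_params")
}

#' Cryoprobe construction material parameters
#'
#' Thermophysical constants of the probe shaft materials (nitinol tube,
#' polyurethane insulation), used only by the optional conjugate mode in
#' which shaft cells are thermally resolved instead of insulated.
#'
#' @param nitinol,pu lists with elements `k` (W/(m·K)), `rho` (kg/m^3),
#'   `c` (J/(kg·K)).
#' @return An object of class `probe_material_params`.
#' @export
probe_material_params <- function(nitinol = list(k = 21.9, rho = 4506, c = 522),
                                  pu = list(k = 0.18, rho = 930, c = 1900)) {
  for (m in list(nitinol, pu)) {
    if (any(!is.finite(unlist(m[c("k", "rho", "c")]))) ||
        any(unlist(m[c("k", "rho", "c")]) <= 0))
      stop("probe_material_params: all properties must be positive",
           call. = FALSE)
  }
  structure(list(nitinol = nitinol, pu = pu), class = "probe_material_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters (unfrozen | frozen):\n")
  cat(sprintf("  k   = %.3g | %.3g W/(m.C)\n", x$k_u, x$k_f))
  cat(sprintf("  c   = %.4g | %.4g J/(kg.C)\n", x$c_u, x$c_f))
  cat(sprintf("  rho = %.4g | %.4g kg/m^3\n", x$rho_u, x$rho_f))
  cat(sprintf("  Q_lf = %.3g J/m^3 over [%g, %g] C\n", x$Q_lf, x$T_ml, x$T_mu))
  cat(sprintf("  perfusion w_b = %.3g /s, rho_b = %g, c_b = %g, T_b = %g C\n",
              x$w_b, x$rho_b, x$c_b, x$T_b))
  cat(sprintf("  metabolic Q_m = %g W/m^3\n", x$Q_m))
  invisible(x)
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf(
    "Damage kinetics: T_dc = %g C, t_dc = %g s, T_nc = %g C, L_dc = %g J/kg%s\n",
    x$T_dc, x$t_dc, x$T_nc, x$L_dc,
    if (x$apply_damage_enthalpy) " (damage enthalpy source ON)" else ""))
  invisible(x)
}
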