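#' Two-phase Stefan (Neumann) freezing-front setup
#'
#' Sharp-interface idealization of one-dimensional freezing of a semi-infinite
#' domain: a cold wall at `wall_C` is applied at x = 0 to tissue initially at
#' `initial_C`; the freezing front at `freeze_C` advances as
#' \eqn{x(t) = 2\lambda\sqrt{\kappa_f t}}. Phase properties are taken from a
#' [tissue_params()] object (perfusion and metabolism are ignored; the mushy
#' interval is collapsed, with the whole volumetric latent heat `Q_lf`
#' released at the front).
#'
#' @param wall_C wall temperature, °C (below `freeze_C`).
#' @param initial_C initial temperature, °C (above `freeze_C`).
#' @param freeze_C freezing temperature, °C.
#' @param tissue a [tissue_params()] supplying the solid/liquid property
#'   pairs and the latent heat.
#' @return Object of class `stefan_setup` with the solved similarity root
#'   `lambda`.
#' @export
#' @examples
#' s <- stefan_setup(-150, 25, 0)
#' stefan_front_position(s, c(0, 150, 600))
stefan_setup <- function(wall_C, initial_C, freeze_C = 0,
                         tissue = tissue_params()) {
  if (!(wall_C < freeze_C && freeze_C < initial_C))
    stop("stefan_setup: requires wall_C < freeze_C < initial_C", call. = FALSE)
  ks <- tissue$k_f; kl <- tissue$k_u
  Cs <- tissue$rho_f * tissue$c_f
  Cl <- tissue$rho_u * tissue$c_u
  kap_s <- ks / Cs; kap_l <- kl / Cl
  Lvol <- tissue$Q_lf
  dTs <- freeze_C - wall_C
  dTl <- initial_C - freeze_C
  resid <- function(lam) {
    ks * dTs / sqrt(pi * kap_s) * exp(-lam^2) / erf(lam) -
      kl * dTl / sqrt(pi * kap_l) *
        exp(-lam^2 * kap_s / kap_l) / erfc(lam * sqrt(kap_s / kap_l)) -
      Lvol * lam * sqrt(kap_s)
  }
  # bracket: residual -> +Inf as lam -> 0+, and negative for large lam
  hi <- 1
  while (resid(hi) > 0 && hi < 50) hi <- hi * 2
  if (resid(hi) > 0)
    stop("stefan_setup: no bracketed root for the similarity parameter ",
         "(unphysical parameter combination)", call. = FALSE)
  lam <- uniroot(resid, c(1e-8, hi), tol = 1e-10)$root
  structure(list(wall_C = wall_C, initial_C = initial_C, freeze_C = freeze_C,
                 tissue = tissue, kappa_s = kap_s, kappa_l = kap_l,
                 lambda = lam, residual = resid),
            class = "stefan_setup")
}

#' Analytic freezing-front position
#'
#' @param setup a [stefan_setup()].
#' @param t time, s (>= 0, vectorised).
#' @return Front position, m: \eqn{2\lambda\sqrt{\kappa_f t}}.
#' @export
stefan_front_position <- function(setup, t) {
  stopifnot(inherits(setup, "stefan_setup"))
  if (any(t < 0)) stop("stefan_front_position: t must be >= 0", call. = FALSE)
  2 * setup$lambda * sqrt(setup$kappa_s * t)
}

#' Analytic Stefan temperature profile
#'
#' Closed-form Neumann similarity temperature at position `x` and time `t`.
#' Used by tests to cross-check the transient solver pointwise.
#'
#' @param setup a [stefan_setup()].
#' @param x position, m (>= 0, vectorised).
#' @param t time, s (> 0, scalar).
#' @return Temperature, °C.
#' @export
stefan_temperature <- function(setup, x, t) {
  stopifnot(inherits(setup, "stefan_setup"), t > 0)
  lam <- setup$lambda
  eta_s <- x / (2 * sqrt(setup$kappa_s * t))
  eta_l <- x / (2 * sqrt(setup$kappa_l * t))
  Tout <- numeric(length(x))
  front <- stefan_front_position(setup, t)
  sol <- x <= front
  Tout[sol] <- setup$wall_C +
    (setup$freeze_C - setup$wall_C) * erf(eta_s[sol]) / erf(lam)
  Tout[!sol] <- setup$initial_C -
    (setup$initial_C - setup$freeze_C) *
      erfc(eta_l[!sol]) / erfc(lam * sqrt(setup$kappa_s / setup$kappa_l))
  Tout
}

#' Conduction-free perfusion relaxation (lumped closed form)
#'
#' Exact solution of the Pennes equation with conduction removed:
#' \deqn{T(t) = T_{ss} + (T_0 - T_{ss}) e^{-w_b\rho_b c_b t/(\rho c)}}
#' with steady state \eqn{T_{ss} = T_b + Q_m/(w_b\rho_b c_b)}. Valid above
#' the phase-transition interval (constant liquid-phase properties). When
#' `w_b = 0` the degenerate linear drift \eqn{T_0 + Q_m t/(\rho c)} is
#' returned.
#'
#' @param t time, s (vectorised).
#' @param tissue a [tissue_params()].
#' @param T0 initial temperature, °C.
#' @return Temperature, °C.
#' @export
lumped_perfusion_temperature <- function(t, tissue = tissue_params(), T0 = 37) {
  stopifnot(inherits(tissue, "tissue_params"))
  rc <- tissue$rho_u * tissue$c_u
  wbc <- tissue$w_b * tissue$rho_b * tissue$c_b
  if (wbc == 0) return(T0 + tissue$Q_m * t / rc)
  Tss <- tissue$T_b + tissue$Q_m / wbc
  Tss + (T0 - Tss) * exp(-wbc * t / rc)
}

#' Grid-convergence harness
#'
#' Re-runs the same single-probe scenario on a sequence of grid spacings
#' (descending) over a reduced domain and reports the temperature at a fixed
#' probe-relative monitor point (by default 5 mm axially beyond the tip) at
#' the final time, together with successive refinement differences.
#'
#' @param spacings grid spacings, m, in strictly descending order.
#' @param extent_m domain extent 3-vector, m; should be (near-)divisible by
#'   every spacing.
#' @param depth probe insertion depth, m.
#' @param monitor_offset axial distance beyond the probe tip of the monitor
#'   point, m.
#' @param end_time simulated duration, s.
#' @param dt time step, s.
#' @param tissue,curve tissue parameters and probe load curve.
#' @param radius probe radius, m.
#' @param initial_C initial temperature, °C.
#' @return data.frame with `spacing_m`, `T_monitor_C`, `diff_C`
#'   (NA for the first row).
#' @export
run_grid_convergence <- function(spacings, extent_m = c(0.03, 0.03, 0.045),
                                 depth = 0.02, monitor_offset = 5e-3,
                                 end_time = 120, dt = 1,
                                 tissue = tissue_params(),
                                 curve = load_curve(start_C = 37),
                                 radius = 0.85e-3, initial_C = 37) {
  if (any(diff(spacings) >= 0))
    stop("run_grid_convergence: spacings must be strictly descending",
         call. = FALSE)
  res <- lapply(spacings, function(h) {
    shape <- pmax(3L, as.integer(round(extent_m / h)))
    # center the probe on a cell-center column so the discrete probe sits
    # identically (up to resolution) at every spacing
    ext <- shape * h
    g <- sim_grid(h, shape,
                  origin = c(-(floor(shape[1] / 2) + 0.5) * h,
                             -(floor(shape[2] / 2) + 0.5) * h, -ext[3]))
    lay <- make_layout("single", depth = depth, radius = radius)
    mon <- matrix(c(0, 0, -depth - monitor_offset), 1)
    ctrl <- solver_config(dt = dt, end_time = end_time, initial_C = initial_C,
                          snapshot_interval = end_time,
                          trace_interval = end_time)
    tr <- run_simulation(g, lay, tissue = tissue, curve = curve,
                         control = ctrl, monitors = mon)
    interp_field(tr$final$T, normalize_monitors(mon, g), g)
  })
  Tm <- vapply(res, identity, numeric(1))
  data.frame(spacing_m = spacings, T_monitor_C = Tm,
             diff_C = c(NA, abs(diff(Tm))))
}
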