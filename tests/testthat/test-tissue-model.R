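test_that("frozen fraction is a continuous ramp across the mushy interval", {
  p <- tissue_params()
  expect_equal(frozen_fraction(0, p), 0)
  expect_equal(frozen_fraction(-20, p), 1)
  expect_equal(frozen_fraction(-4.5, p), 0.5)  # midpoint of [-8, -1]
  expect_equal(frozen_fraction(p$T_mu, p), 0)
  expect_equal(frozen_fraction(p$T_ml, p), 1)
  # monotone non-increasing in T
  Ts <- seq(-30, 20, by = 0.1)
  expect_true(all(diff(frozen_fraction(Ts, p)) <= 0))
  expect_error(frozen_fraction(NaN, p), "non-finite")
})

test_that("conductivity follows the three-branch piecewise form", {
  p <- tissue_params()
  expect_equal(tissue_conductivity(10, p), 0.5)
  expect_equal(tissue_conductivity(-20, p), 2)
  expect_equal(tissue_conductivity(-4, p), 1.25)  # (0.5 + 2) / 2
  # interval endpoints take the mushy branch
  expect_equal(tissue_conductivity(c(-1, -8), p), c(1.25, 1.25))
  expect_equal(tissue_conductivity(-1 + 1e-9, p), 0.5)
})

test_that("volumetric heat capacity carries the latent term in the mushy zone", {
  p <- tissue_params()
  expect_equal(volumetric_heat_capacity(10, p), 1000 * 3600)
  expect_equal(volumetric_heat_capacity(-20, p), 998 * 1800)
  expect_equal(volumetric_heat_capacity(-4, p), 999 * 2700 + 250e6 / 7)
})

test_that("enthalpy integrates the capacity exactly (latent heat conservation)", {
  p <- tissue_params()
  # crossing the whole mushy interval recovers sensible + latent heat
  dH <- tissue_enthalpy(p$T_mu, p) - tissue_enthalpy(p$T_ml, p)
  sensible <- (p$rho_u + p$rho_f) / 2 * (p$c_u + p$c_f) / 2 *
    (p$T_mu - p$T_ml)
  expect_equal(dH, sensible + p$Q_lf)
  # numeric quadrature of the capacity matches enthalpy differences
  for (pair in list(c(-30, 15), c(-5, -2), c(-12, 3))) {
    Ts <- seq(pair[1], pair[2], length.out = 20001)
    num <- sum(volumetric_heat_capacity((Ts[-1] + Ts[-length(Ts)]) / 2, p)) *
      diff(Ts)[1]
    expect_equal(num, diff(tissue_enthalpy(pair, p)), tolerance = 1e-4)
  }
})

test_that("perfusion/metabolic source matches the Pennes term with shutdown", {
  p <- tissue_params()
  expect_equal(perfusion_metabolic_source(37, p), 4200)
  expect_equal(perfusion_metabolic_source(30, p, frozen_shutdown = TRUE),
               0.0005 * 1000 * 3600 * 7 + 4200)
  expect_equal(perfusion_metabolic_source(-20, p, frozen_shutdown = TRUE), 0)
  expect_equal(perfusion_metabolic_source(-20, p, frozen_shutdown = FALSE),
               0.0005 * 1000 * 3600 * 57 + 4200)
  # half-frozen at the mushy midpoint
  expect_equal(perfusion_metabolic_source(-4.5, p, frozen_shutdown = TRUE),
               0.5 * perfusion_metabolic_source(-4.5, p, FALSE))
})

test_that("parameter constructors enforce physical invariants", {
  expect_error(tissue_params(T_mu = -8, T_ml = -1), "T_ml < T_mu")
  expect_error(tissue_params(k_u = 0), "strictly positive")
  expect_error(tissue_params(Q_lf = -1), "strictly positive")
  expect_error(tissue_params(w_b = -1e-4), "w_b")
  expect_error(damage_params(t_dc = 0), "t_dc")
  expect_error(damage_params(T_nc = -10, T_dc = -20), "T_nc <= T_dc")
  expect_error(probe_material_params(nitinol = list(k = -1, rho = 1, c = 1)),
               "positive")
  # defaults are the packaged table values
  p <- tissue_params()
  expect_identical(c(p$k_u, p$k_f, p$c_u, p$c_f, p$rho_u, p$rho_f),
                   c(0.5, 2, 3600, 1800, 1000, 998))
  expect_identical(c(p$Q_lf, p$T_mu, p$T_ml, p$w_b, p$c_b, p$Q_m),
                   c(250e6, -1, -8, 5e-4, 3600, 4200))
  d <- damage_params()
  expect_identical(c(d$T_dc, d$t_dc, d$T_nc, d$L_dc), c(-20, 60, -50, 250e3))
  pm <- probe_material_params()
  expect_equal(pm$nitinol$k, 21.9)
  expect_equal(pm$pu$rho, 930)
})
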