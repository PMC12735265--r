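test_that("uniform blood-temperature state with no metabolism is stationary", {
  tis <- tissue_params(Q_m = 0)
  tr <- no_probe_run(tis, end_time = 10, dt = 1, initial_C = 37)
  expect_equal(max(abs(tr$final$T - 37)), 0, tolerance = 1e-10)
})

test_that("insulated source-free runs conserve enthalpy to machine level", {
  tis <- tissue_params(w_b = 0, Q_m = 0)
  g <- sim_grid(2e-3, c(8, 8, 8))
  co <- cryosim:::grid_coords(g)
  # smooth nonuniform all-liquid initial field drives real internal fluxes
  T0 <- 20 + 7 * sin(co$x / g$extent[1] * 6) * cos(co$y / g$extent[2] * 5) +
    5 * (co$z / g$extent[3])
  tr <- no_probe_run(tis, end_time = 20, dt = 1, shape = c(8, 8, 8),
                     initial_field = T0, lin_tol = 1e-12)
  rep <- energy_balance_report(tr)
  expect_true(all(rep$rel_residual <= 1e-8))
  # total enthalpy before == after
  H <- function(T) sum(tissue_enthalpy(as.vector(T), tis)) * g$cell_volume
  expect_equal(H(tr$final$T), H(T0), tolerance = 1e-10)
})

test_that("conduction-free cooling follows the lumped perfusion closed form", {
  tis <- tissue_params(k_u = 1e-9, k_f = 1e-9)
  tr <- no_probe_run(tis, end_time = 300, dt = 1, initial_C = 30)
  expect_equal(tr$final$T[2, 2, 2],
               lumped_perfusion_temperature(300, tis, 30), tolerance = 2e-3)
})

test_that("probe runs respect the comparison principle and balance energy", {
  tr <- tiny_axi_run(end_time = 60, dt = 1)
  # minimum over time bounded below by the load-curve minimum
  expect_gte(min(vapply(tr$snapshots, function(s) min(s$T), numeric(1))),
             min(evaluate_load_curve(tr$curve, seq(0, 60))))
  rep <- energy_balance_report(tr)
  expect_true(all(rep$rel_residual <= 0.01))
  expect_true(all(is.finite(tr$final$T)))
})

test_that("compiled and reference implicit paths agree", {
  a <- tiny_axi_run(end_time = 20, dt = 1, method = "implicit")
  b <- tiny_axi_run(end_time = 20, dt = 1, method = "reference")
  expect_lt(max(abs(a$final$T - b$final$T)), 1e-4)
})

test_that("explicit mode cross-checks the implicit path and guards stability", {
  # all-liquid smooth relaxation (no phase change): both integrators converge
  tis <- tissue_params(w_b = 0, Q_m = 0)
  g <- sim_grid(2e-3, c(8, 8, 8))
  co <- cryosim:::grid_coords(g)
  T0 <- 25 + 10 * sin(co$x * 500) * sin(co$y * 500)
  ex <- no_probe_run(tis, end_time = 4, dt = 0.2, shape = c(8, 8, 8),
                     initial_field = T0, method = "explicit")
  im <- no_probe_run(tis, end_time = 4, dt = 0.05, shape = c(8, 8, 8),
                     initial_field = T0, method = "implicit",
                     lin_tol = 1e-11)
  expect_lt(max(abs(ex$final$T - im$final$T)), 0.02)
  # a dt above the stability limit is refused with a diagnostic
  expect_error(no_probe_run(tis, end_time = 40, dt = 20, shape = c(8, 8, 8),
                            initial_field = T0, method = "explicit"),
               "unstable")
})

test_that("damage kinetics integrate the threshold/time law", {
  dmg <- damage_params()
  st <- list(T = array(-30, c(2, 2, 1)), alpha = array(0, c(2, 2, 1)))
  st <- update_damage(st, dmg, dt = 30)
  expect_equal(unique(as.vector(st$alpha)), 0.5)
  expect_equal(unique(as.vector(st$theta_d)), 0.5)
  st <- update_damage(st, dmg, dt = 60)  # 90 s total below threshold
  expect_equal(unique(as.vector(st$alpha)), 1.5)
  expect_equal(unique(as.vector(st$theta_d)), 1)
  # above threshold: no accumulation
  st2 <- list(T = array(-10, c(2, 2, 1)), alpha = array(0.2, c(2, 2, 1)))
  st2 <- update_damage(st2, dmg, dt = 1000)
  expect_equal(unique(as.vector(st2$alpha)), 0.2)
  expect_error(update_damage(st2, dmg, dt = 0), "dt")
})

test_that("damage accumulator is monotone and capped along a trajectory", {
  tr <- tiny_axi_run(end_time = 120, dt = 2)
  al <- lapply(tr$snapshots, `[[`, "alpha")
  for (i in seq_along(al)[-1])
    expect_true(all(al[[i]] >= al[[i - 1]] - 1e-12))
  th <- tr$final$theta_d
  expect_true(all(th >= 0 & th <= 1))
  # theta == 1 only where alpha >= 1 (cumulative time below threshold >= t_dc)
  expect_true(all(abs(th - pmin(tr$final$alpha, 1)) < 1e-12))
})

test_that("trajectory bookkeeping: snapshots, traces and zero-duration runs", {
  g <- axi_grid(2e-3, nr = 10, nz = 12)
  lay <- make_layout("single", depth = 0.012, radius = 1.1e-3)
  ctrl <- solver_config(dt = 1, end_time = 0, initial_C = 25)
  tr0 <- run_simulation(g, lay, control = ctrl)
  expect_length(tr0$snapshots, 1)
  expect_equal(tr0$times, 0)

  ctrl <- solver_config(dt = 1, end_time = 30, initial_C = 25,
                        snapshot_interval = 10, trace_interval = 5)
  mon <- matrix(c(4e-3, 0, -6e-3), 1)
  tr <- run_simulation(g, lay, curve = load_curve(), control = ctrl,
                       monitors = mon)
  expect_equal(tr$times, c(0, 10, 20, 30))
  expect_equal(tr$traces$t_s, seq(0, 30, by = 5))
  expect_true(all(c("T1_C", "theta1") %in% names(tr$traces)))
  expect_error(run_simulation(g, lay, control = ctrl,
                              monitors = matrix(c(1, 0, -0.005), 1)),
               "outside")
})

test_that("nine-probe field stays invariant under quarter-turn rotation", {
  g <- sim_grid(2e-3, c(33, 33, 16))
  lay <- make_layout("nine", spacing = 0.01, depth = 0.02,
                     active_length = 0.012, radius = 1.1e-3)
  ctrl <- solver_config(dt = 2, end_time = 60, initial_C = 25,
                        snapshot_interval = 60)
  tr <- run_simulation(g, lay, curve = load_curve(), control = ctrl)
  Tf <- tr$final$T
  Trot <- aperm(Tf[, rev(seq_len(dim(Tf)[2])), , drop = FALSE], c(2, 1, 3))
  expect_lt(max(abs(Tf - Trot)), 1e-6)
})
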