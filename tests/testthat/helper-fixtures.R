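# small scenario builders shared across the suite

# sharp-interface tissue for freezing-front checks: narrow mushy interval,
# no perfusion or metabolism
stefan_tissue <- function() {
  tissue_params(T_mu = 0, T_ml = -0.2, w_b = 0, Q_m = 0)
}

# tiny axisymmetric single-probe scenario (seconds to run)
tiny_axi_run <- function(end_time = 30, dt = 1, h = 2e-3, nr = 12, nz = 15,
                         method = "implicit", initial_C = 25, ...) {
  g <- axi_grid(h, nr = nr, nz = nz)
  lay <- make_layout("single", depth = 0.012, active_length = 0.012,
                     radius = 1.1e-3)
  ctrl <- solver_config(dt = dt, end_time = end_time, initial_C = initial_C,
                        snapshot_interval = max(end_time, dt),
                        method = method, ...)
  run_simulation(g, lay, curve = load_curve(start_C = initial_C),
                 control = ctrl)
}

# probe-free insulated box (for conservation / equilibrium checks)
no_probe_run <- function(tissue, end_time = 10, dt = 1, shape = c(6, 6, 6),
                         h = 2e-3, initial_C = 37, initial_field = NULL, ...) {
  g <- sim_grid(h, shape)
  lay <- probe_layout("custom", NA_real_, list())
  ctrl <- solver_config(dt = dt, end_time = end_time, initial_C = initial_C,
                        snapshot_interval = max(end_time, dt), ...)
  run_simulation(g, lay, tissue = tissue, control = ctrl,
                 initial_field = initial_field)
}

# synthetic radial temperature field T = slope * r + offset on a grid
# centered at `center` (cartesian); returns the array
radial_field <- function(grid, slope = 1e4, offset = -50,
                         center = c(0, 0, -grid$extent[3] / 2)) {
  co <- cryosim:::grid_coords(grid)
  r <- sqrt((co$x - center[1])^2 + (co$y - center[2])^2 +
              (co$z - center[3])^2)
  slope * r + offset
}
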