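test_that("isotherm extraction recovers an analytic sphere", {
  g <- sim_grid(1e-3, c(24, 24, 24))
  Tf <- radial_field(g, slope = 1e4, offset = -50)  # 0 C at r = 5 mm
  reg <- extract_isotherm_region(Tf, 0, g)
  expect_equal(reg$n_components, 1)
  expect_false(reg$boundary_clipped)
  r_true <- 5e-3
  expect_equal(reg$volume_m3, 4 / 3 * pi * r_true^3, tolerance = 0.05)
  # surface points sit on the sphere within one cell
  ctr <- c(0, 0, -g$extent[3] / 2)
  rp <- sqrt(rowSums(sweep(reg$points[, 1:3], 2, ctr)^2))
  expect_lt(max(abs(rp - r_true)), g$spacing)
  ax <- measure_axes(reg)
  expect_lt(abs(ax$longitudinal_m - 2 * r_true), g$spacing)
  expect_lt(abs(ax$transverse_m - 2 * r_true), g$spacing)
  # interpolated and voxel volumes agree within a surface shell
  shell <- 4 * pi * r_true^2 * g$spacing
  expect_lt(abs(reg$volume_m3 - reg$volume_voxel_m3), shell)
})

test_that("degenerate fields: all-warm empty and all-cold full domain", {
  g <- sim_grid(1e-3, c(10, 10, 10))
  warm <- array(37, g$shape)
  reg <- extract_isotherm_region(warm, 0, g)
  expect_equal(sum(reg$mask), 0)
  expect_equal(reg$volume_m3, 0)
  expect_equal(reg$n_components, 0)
  expect_error(measure_axes(reg), "empty")
  cold <- array(-50, g$shape)
  regc <- extract_isotherm_region(cold, 0, g)
  expect_equal(sum(regc$mask), length(cold))
  expect_equal(regc$volume_voxel_m3, prod(g$extent), tolerance = 1e-12)
  expect_true(regc$boundary_clipped)
  expect_error(extract_isotherm_region(array(NA_real_, g$shape), 0, g),
               "non-finite")
})

test_that("caliper axes of an axis-aligned ellipsoid match its diameters", {
  g <- sim_grid(1e-3, c(32, 32, 40))
  co <- cryosim:::grid_coords(g)
  ctr <- c(0, 0, -g$extent[3] / 2)
  a <- 12.5e-3; b <- 6e-3  # semi-axes: long along z (probe axis)
  Tf <- 50 * (((co$x - ctr[1]) / b)^2 + ((co$y - ctr[2]) / b)^2 +
                ((co$z - ctr[3]) / a)^2) - 50
  reg <- extract_isotherm_region(Tf, 0, g)
  ax <- measure_axes(reg, probe_axis = c(0, 0, 1))
  expect_lt(abs(ax$longitudinal_m - 0.025), 1.5e-3)
  expect_lt(abs(ax$transverse_m - 0.012), 1.5e-3)
  # quarter-turn rotation about the probe axis leaves the calipers unchanged
  Trot <- aperm(Tf[, rev(seq_len(dim(Tf)[2])), , drop = FALSE], c(2, 1, 3))
  ax2 <- measure_axes(extract_isotherm_region(Trot, 0, g), c(0, 0, 1))
  expect_equal(ax2$longitudinal_m, ax$longitudinal_m, tolerance = 1e-9)
  expect_equal(ax2$transverse_m, ax$transverse_m, tolerance = 1e-9)
})

test_that("disjoint cold regions: axes come from the largest component", {
  g <- sim_grid(1e-3, c(40, 20, 20))
  co <- cryosim:::grid_coords(g)
  ctrA <- c(-12e-3, 0, -10e-3); ctrB <- c(10e-3, 0, -10e-3)
  rA <- sqrt((co$x - ctrA[1])^2 + (co$y - ctrA[2])^2 + (co$z - ctrA[3])^2)
  rB <- sqrt((co$x - ctrB[1])^2 + (co$y - ctrB[2])^2 + (co$z - ctrB[3])^2)
  Tf <- pmin(rA * 1e4 - 60, rB * 1e4 - 30)  # radii 6 mm and 3 mm
  reg <- extract_isotherm_region(Tf, 0, g)
  expect_equal(reg$n_components, 2)
  ax <- measure_axes(reg)
  expect_lt(abs(ax$longitudinal_m - 0.012), 1.5e-3)
  expect_lt(abs(ax$transverse_m - 0.012), 1.5e-3)
})

test_that("warm-zone volume finds interstitial pockets inside the hull", {
  g <- sim_grid(1e-3, c(30, 30, 30))
  co <- cryosim:::grid_coords(g)
  ctr <- c(0, 0, -g$extent[3] / 2)
  r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
  Tf <- array(37, g$shape)
  Tf[r <= 10e-3] <- -50          # frozen ball
  pocket <- r <= 3e-3
  Tf[pocket] <- -30              # sub-lethal pocket at the center
  wz <- warm_zone_volume(Tf, g, hull_level = 0, lethal_level = -40)
  expect_equal(wz, sum(pocket) * g$cell_volume, tolerance = 1e-12)
  # fully lethal ball has no warm zone
  Tf[pocket] <- -50
  expect_equal(warm_zone_volume(Tf, g, 0, -40), 0)
  # uniform warm field: no hull, no warm zone
  expect_equal(warm_zone_volume(array(37, g$shape), g, 0, -40), 0)
  expect_error(warm_zone_volume(Tf, g, 0, 10), "below")
})

test_that("warm-zone volume is monotone non-increasing in the lethal level", {
  g <- sim_grid(1e-3, c(24, 24, 24))
  Tf <- radial_field(g, slope = 5e3, offset = -55)
  lv <- c(-50, -40, -30, -20, -10)
  wz <- vapply(lv, function(l) warm_zone_volume(Tf, g, 0, l), numeric(1))
  expect_true(all(diff(wz) <= 1e-15))
})

test_that("merge tracking counts components along a trajectory", {
  # two probes far apart on a coarse grid: two ice balls, never merging
  g <- sim_grid(2e-3, c(33, 17, 12))
  lay <- probe_layout("custom", NA, list(
    probe(entry_point = c(-0.02, 0, 0), insertion_depth = 0.014,
          radius = 1.1e-3),
    probe(entry_point = c(0.02, 0, 0), insertion_depth = 0.014,
          radius = 1.1e-3)))
  ctrl <- solver_config(dt = 2, end_time = 60, initial_C = 25,
                        snapshot_interval = 20)
  tr <- run_simulation(g, lay, curve = load_curve(), control = ctrl)
  mg <- track_merge_events(tr)
  expect_equal(mg$components[1], 0)          # nothing frozen at t = 0
  expect_true(all(mg$components[-1] == 2))   # independent balls, no fusion
  expect_false(any(mg$merge_event))
})

test_that("dimensional error is the mean relative axis discrepancy", {
  expect_equal(dimensional_error(c(2.5, 1.2), c(2.5, 1.2)), 0)
  expect_equal(dimensional_error(c(2.5, 1.2), c(2.6, 1.25)),
               mean(c(0.1 / 2.6, 0.05 / 1.25)) * 100)
  expect_equal(dimensional_error(3, 4), 25)
  expect_error(dimensional_error(c(1, 2), c(1, 0)), "> 0")
  expect_error(dimensional_error(c(1, 2), 1), "length")
})

test_that("thermocouple sampling interpolates trilinearly", {
  g <- sim_grid(2e-3, c(8, 8, 8))
  co <- cryosim:::grid_coords(g)
  lin <- 3 + 100 * co$x + 50 * co$y - 20 * co$z  # exactly linear field
  traj <- structure(list(
    grid = g,
    snapshots = list(list(t = 0, T = lin, alpha = lin * 0)),
    times = 0), class = "cryo_trajectory")
  ctr_cell <- c(co$x[4, 4, 4], co$y[4, 4, 4], co$z[4, 4, 4])
  mid <- ctr_cell + c(1e-3, 0, 0)  # midway to the next cell along x
  out <- sample_thermocouples(traj, rbind(ctr_cell, mid))
  expect_equal(out$T1_C, lin[4, 4, 4])
  expect_equal(out$T2_C, (lin[4, 4, 4] + lin[5, 4, 4]) / 2)
  # linear fields are reproduced exactly anywhere in the interior
  pt <- c(1.3e-3, -2.1e-3, -7.7e-3)
  out2 <- sample_thermocouples(traj, rbind(pt))
  expect_equal(out2$T1_C, 3 + 100 * pt[1] + 50 * pt[2] - 20 * pt[3],
               tolerance = 1e-9)
})

test_that("iceball metrics table reports per-level rows", {
  g <- sim_grid(1e-3, c(24, 24, 24))
  Tf <- radial_field(g, slope = 1e4, offset = -50)
  m <- iceball_metrics(Tf, g, levels = c(0, -20, -40))
  expect_equal(nrow(m), 3)
  expect_true(all(diff(m$volume_m3) < 0))  # colder isotherm, smaller region
  expect_true(all(m$components == 1))
  # warm zone between each level and the hull shrinks with colder levels
  expect_true(all(m$warm_zone_m3[m$level_C < 0] >= 0))
})
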