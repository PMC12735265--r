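test_that("layout patterns produce the documented probe arrangements", {
  s <- make_layout("single", depth = 0.02, radius = 0.85e-3)
  expect_length(s$probes, 1)
  tip <- s$probes[[1]]$entry_point + s$probes[[1]]$axis *
    s$probes[[1]]$insertion_depth
  expect_equal(tip[3], -0.02)

  n <- make_layout("nine", spacing = 0.01)
  pos <- layout_positions(n)
  expect_equal(nrow(pos), 9)
  expect_setequal(round(pos$x_cm, 6), c(-1, 0, 1))
  expect_equal(max(dist(cbind(pos$x_cm, pos$y_cm))), 2 * sqrt(2),
               tolerance = 1e-12)

  f <- make_layout("five", spacing = 0.01)
  pf <- layout_positions(f)
  d0 <- sqrt(pf$x_cm^2 + pf$y_cm^2)
  expect_equal(sort(d0), c(0, 1, 1, 1, 1))

  sv <- make_layout("seven", spacing = 0.01)
  ps <- layout_positions(sv)
  ds <- sqrt(ps$x_cm^2 + ps$y_cm^2)
  expect_equal(sort(ds), c(0, rep(1, 6)), tolerance = 1e-12)
})

test_that("layouts are symmetric under their point groups", {
  for (pat in c("five", "seven", "nine")) {
    lay <- make_layout(pat, spacing = 0.01)
    pos <- as.matrix(layout_positions(lay)[, 1:2])
    ang <- switch(pat, five = pi / 2, seven = pi / 3, nine = pi / 2)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    rot <- pos %*% R
    # rotated set equals the original set (as sets of points)
    d <- as.matrix(dist(rbind(pos, rot)))
    nearest <- apply(d[1:nrow(pos), (nrow(pos) + 1):(2 * nrow(pos))], 1, min)
    expect_lt(max(nearest), 1e-9)
  }
})

test_that("layout construction rejects invalid geometry", {
  expect_error(make_layout("nine", spacing = 1e-3, radius = 0.6e-3),
               "spacing")
  expect_error(make_layout("five"), "spacing is required")
  expect_error(make_layout("hex"), "arg")
  expect_error(probe(active_length = 0.03, insertion_depth = 0.02),
               "active_length")
  expect_error(probe_layout("nine", 0.01, list(probe())), "requires 9")
})

test_that("load curve is the documented piecewise-linear freeze-thaw cycle", {
  lc <- load_curve(start_C = 25, plateau_C = -150, ramp_s = 60,
                   freeze_s = 900, thaw_C = 20, thaw_s = 300)
  expect_equal(evaluate_load_curve(lc, 0), 25)
  expect_equal(evaluate_load_curve(lc, 30), -62.5)
  expect_equal(evaluate_load_curve(lc, 70), -150)
  expect_equal(evaluate_load_curve(lc, 900), -150)
  expect_equal(evaluate_load_curve(lc, 1050), -65)
  expect_equal(evaluate_load_curve(lc, 1200), 20)
  expect_equal(evaluate_load_curve(lc, 2000), 20)
  # continuity across the segment joints
  for (tj in c(60, 900, 1200)) {
    expect_equal(evaluate_load_curve(lc, tj - 1e-7),
                 evaluate_load_curve(lc, tj + 1e-7), tolerance = 1e-4)
  }
  expect_error(evaluate_load_curve(lc, -1), ">= 0")
  expect_error(load_curve(start_C = -160, plateau_C = -150), "plateau")
})

test_that("rasterization agrees with a brute-force point-in-cylinder test", {
  g <- sim_grid(2e-3, c(16, 16, 12))
  lay <- make_layout("five", spacing = 0.012, depth = 0.016,
                     active_length = 0.01, radius = 2.2e-3)
  m <- rasterize_layout(lay, g)
  # independent brute-force classification over every cell
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(g$shape[a]) - 0.5) *
                 g$spacing)
  act <- array(FALSE, g$shape); ins <- array(FALSE, g$shape)
  for (i in seq_len(g$shape[1])) for (j in seq_len(g$shape[2]))
    for (k in seq_len(g$shape[3])) {
      pt <- c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
      for (p in lay$probes) {
        lat <- sqrt(sum((pt[1:2] - p$entry_point[1:2])^2))
        inside <- lat <= p$radius && pt[3] >= -p$insertion_depth && pt[3] <= 0
        if (inside) {
          ins[i, j, k] <- TRUE
          if (pt[3] <= -p$insertion_depth + p$active_length)
            act[i, j, k] <- TRUE
        }
      }
    }
  expect_identical(m$active, act)
  expect_identical(m$shaft, ins & !act)
  expect_false(any(m$active & m$shaft))
  expect_gt(sum(m$active), 0)
  # voxelized active volume approximates the true cylinder volume
  vol_vox <- sum(m$active) * g$cell_volume
  vol_true <- 5 * pi * 2.2e-3^2 * 0.01
  expect_lt(abs(vol_vox - vol_true) / vol_true, 0.5)
})

test_that("rasterization rejects probes outside or under-resolved", {
  g <- sim_grid(2e-3, c(10, 10, 10))
  far <- probe_layout("custom", NA,
                      list(probe(entry_point = c(0.5, 0, 0))))
  expect_error(rasterize_layout(far, g), "outside")
  deep <- probe_layout("custom", NA,
                       list(probe(insertion_depth = 0.5, radius = 0.85e-3)))
  expect_error(rasterize_layout(deep, g), "outside|below")
  # radius far smaller than the grid spacing, axis between cell centers
  g2 <- sim_grid(4e-3, c(10, 10, 10), origin = c(0, 0, -0.04))
  thin <- probe_layout("custom", NA,
                       list(probe(entry_point = c(0.002 + 1e-4, 0.002, 0),
                                  insertion_depth = 0.02, radius = 1e-5)))
  expect_error(rasterize_layout(thin, g2), "no active cells")
})

test_that("axisymmetric rasterization captures the on-axis probe", {
  g <- axi_grid(1e-3, nr = 20, nz = 30)
  lay <- make_layout("single", depth = 0.02, radius = 0.85e-3)
  m <- rasterize_layout(lay, g)
  # only the innermost ring (r_c = 0.5 mm <= 0.85 mm) over the top 2 cm
  expect_equal(sum(m$active), 20)
  expect_true(all(which(m$active, arr.ind = TRUE)[, 1] == 1))
  expect_error(rasterize_layout(make_layout("nine", spacing = 0.01), g),
               "single probe")
})
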