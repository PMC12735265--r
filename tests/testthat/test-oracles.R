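test_that("Stefan similarity root matches an independent residual scan", {
  s <- stefan_setup(-150, 25, 0, stefan_tissue())
  # independent: fine scan for the sign change of the transcendental residual
  lam <- seq(1e-4, 3, by = 1e-4)
  res <- vapply(lam, s$residual, numeric(1))
  flip <- which(diff(sign(res)) != 0)[1]
  expect_lt(abs(s$lambda - lam[flip]), 2e-4)
  # root is a genuine zero
  expect_lt(abs(s$residual(s$lambda)), 1e-4 * abs(s$residual(s$lambda / 2)))
})

test_that("Stefan front obeys the similarity scaling", {
  s <- stefan_setup(-150, 25, 0, stefan_tissue())
  expect_equal(stefan_front_position(s, 0), 0)
  expect_equal(stefan_front_position(s, 4 * 137),
               2 * stefan_front_position(s, 137))
  expect_error(stefan_setup(10, 25, 0), "wall_C < freeze_C")
})

test_that("Stefan temperature profile is continuous and bracketed", {
  s <- stefan_setup(-150, 25, 0, stefan_tissue())
  x <- seq(0, 0.06, by = 1e-4)
  Tp <- stefan_temperature(s, x, 300)
  expect_equal(Tp[1], -150, tolerance = 1e-6)
  expect_true(all(diff(Tp) >= -1e-9))        # monotone from wall to far field
  expect_true(all(Tp <= 25 + 1e-9))
  xf <- stefan_front_position(s, 300)
  expect_equal(stefan_temperature(s, xf, 300), 0, tolerance = 1e-6)
})

test_that("lumped perfusion relaxation has the right limits", {
  p <- tissue_params()
  expect_equal(lumped_perfusion_temperature(0, p, 30), 30)
  expect_equal(lumped_perfusion_temperature(1e7, p, 30),
               37 + 4200 / (5e-4 * 1000 * 3600), tolerance = 1e-6)
  Tss <- 37 + 4200 / 1800
  expect_equal(lumped_perfusion_temperature(c(10, 1000), p, Tss),
               c(Tss, Tss))
  # zero perfusion degenerates to a linear metabolic drift
  p0 <- tissue_params(w_b = 0)
  expect_equal(lumped_perfusion_temperature(3600, p0, 30),
               30 + 4200 * 3600 / (1000 * 3600))
})

test_that("grid-convergence harness is deterministic and well-formed", {
  tab <- run_grid_convergence(c(3.2e-3, 1.6e-3),
                              extent_m = c(0.0192, 0.0192, 0.0288),
                              depth = 0.0144, end_time = 30, dt = 2,
                              radius = 1.7e-3)
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$diff_C[1]))
  expect_true(tab$diff_C[2] >= 0)
  tab2 <- run_grid_convergence(c(3.2e-3, 1.6e-3),
                               extent_m = c(0.0192, 0.0192, 0.0288),
                               depth = 0.0144, end_time = 30, dt = 2,
                               radius = 1.7e-3)
  expect_identical(tab, tab2)
  expect_error(run_grid_convergence(c(1e-3, 2e-3)), "descending")
})
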