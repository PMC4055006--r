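test_that("remanence calibration inverts the on-axis closed form", {
  expect_equal(calibrate_remanence(0.6, 4e-3, 8e-3), 1.341641,
               tolerance = 1e-6)
  expect_equal(calibrate_remanence(0, 4e-3, 8e-3), 0)
  # round trip: calibrated magnet has exactly the target at the face center
  mag <- magnet_spec(surface_field = 0.6)
  expect_equal(on_axis_field(0, mag), 0.6, tolerance = 1e-12)
  expect_warning(calibrate_remanence(2.5, 4e-3, 8e-3), "not physical")
})

test_that("flank calibration puts the target just outside the edge", {
  mag <- magnet_spec(surface_field = 0.6, calibration = "flank")
  f <- field_rz(mag$radius + mag$edge_margin, 0, mag)
  expect_equal(f$B_mag, 0.6, tolerance = 1e-9)
  # flank maximum exceeds the face-center field, so Br is smaller here
  expect_lt(mag$remanence, magnet_spec()$remanence)
})

test_that("on-axis field matches the closed form and decays", {
  mag <- magnet_spec()
  expect_equal(on_axis_field(1e-3, mag), 0.450, tolerance = 1e-3 / 0.45)
  z <- seq(0, 20e-3, by = 0.5e-3)
  expect_true(all(diff(on_axis_field(z, mag)) < 0))
  expect_lt(on_axis_field(1, mag), 1e-4)
  expect_error(on_axis_field(-1e-3, mag), "non-negative")
})

test_that("field_at agrees with the on-axis closed form and is axisymmetric", {
  mag <- magnet_spec()
  z <- c(0.5e-3, 1e-3, 3e-3, 10e-3)
  fa <- field_at(cbind(0, 0, z), mag)
  expect_lt(max(abs(fa$B[, 3] - on_axis_field(z, mag))), 1e-6)
  expect_lt(max(abs(fa$B[, 1:2])), 1e-12)  # radial component zero on axis
  # same (r, z) at different azimuths: identical magnitude, rotated vector
  r <- 5e-3
  th <- c(0, 0.7, 2.1, 4.4)
  pts <- cbind(r * cos(th), r * sin(th), 1e-3)
  fb <- field_at(pts, mag)
  expect_lt(diff(range(fb$B_mag)), 1e-12)
})

test_that("field matches the brute-force surface-charge quadrature oracle", {
  mag <- magnet_spec()
  set.seed(7)
  n <- 50
  pts <- cbind(runif(n, -12e-3, 12e-3), runif(n, -12e-3, 12e-3),
               runif(n, 1e-3, 12e-3))
  B <- field_at(pts, mag)$B
  Bo <- oracle_field(pts, mag$radius, mag$length, mag$remanence)
  rel <- sqrt(rowSums((B - Bo)^2)) / sqrt(rowSums(Bo^2))
  expect_lt(max(rel), 1e-3)
})

test_that("evaluation inside the magnet body is rejected, edge is clamped", {
  mag <- magnet_spec()
  expect_error(field_at(c(0, 0, -4e-3), mag), "inside the magnet")
  expect_error(field_rz(2e-3, -1e-3, mag), "inside the magnet")
  near_edge <- field_rz(mag$radius + 1e-5, 1e-5, mag)
  expect_true(near_edge$clamped)
  expect_true(is.finite(near_edge$B_mag))
})

test_that("gradient matches the analytic on-axis derivative and div B = 0", {
  mag <- magnet_spec()
  g <- gradient_at(c(0, 0, 1e-3), mag)
  # analytic d/dz of the on-axis closed form
  R <- mag$radius; L <- mag$length; z <- 1e-3
  dBdz <- (mag$remanence / 2) *
    (R^2 / ((z + L)^2 + R^2)^1.5 - R^2 / (z^2 + R^2)^1.5)
  expect_equal(g$grad[3, 3, 1], dBdz, tolerance = 5e-3)
  set.seed(21)
  pts <- cbind(runif(20, -10e-3, 10e-3), runif(20, -10e-3, 10e-3),
               runif(20, 1e-3, 10e-3))
  g <- gradient_at(pts, mag)
  for (k in 1:20) {
    J <- g$grad[, , k]
    expect_lt(abs(sum(diag(J))), 1e-3 * sqrt(sum(J^2)))
  }
})

test_that("a uniform stub source has zero gradient", {
  g <- gradient_at(cbind(1e-3, 2e-3, 3e-3), field_fun = function(p)
    matrix(rep(c(0.1, 0, 0.2), each = nrow(p)), ncol = 3))
  expect_equal(max(abs(g$grad)), 0)
  expect_equal(max(abs(g$dBmag)), 0)
})

test_that("gradient stencils may not cross the magnet surface", {
  mag <- magnet_spec()
  expect_error(gradient_at(c(0, 0, 5e-7), mag, h = 1e-6), "stencil")
})

test_that("field map profiles decay away from the magnet", {
  mag <- magnet_spec()
  # fixed working height z = 1 mm, radial profile beyond the flank
  fm <- field_map(mag, r = seq(5e-3, 15e-3, by = 0.5e-3), z = 1e-3)
  expect_true(all(diff(fm$B_mag) < 0))
  expect_true(all(fm$dB_dr < 0))
  # fixed radius, increasing height
  fz <- field_map(mag, r = 2e-3, z = seq(0.5e-3, 15e-3, by = 0.5e-3))
  expect_true(all(diff(fz$B_mag) < 0))
  empty <- field_map(mag, r = numeric(0), z = 1e-3)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("r_m", "z_m", "B_mag", "dB_dr") %in% names(empty)))
})
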