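test_that("poiseuille profile has the right extremes and flux average", {
  tube <- tube_geometry()
  fl <- flow_spec(4e-3)
  expect_equal(poiseuille_velocity(0, fl, tube), 2 * 4e-3)
  expect_equal(poiseuille_velocity(tube$inner_radius, fl, tube), 0)
  # cross-section average recovers the mean velocity
  f <- function(rho) poiseuille_velocity(rho, fl, tube) * 2 * pi * rho
  avg <- integrate(f, 0, tube$inner_radius, rel.tol = 1e-12)$value /
    (pi * tube$inner_radius^2)
  expect_equal(avg, 4e-3, tolerance = 1e-10)
  plug <- flow_spec(4e-3, profile = "plug")
  expect_equal(poiseuille_velocity(c(0, 1e-3), plug, tube), c(4e-3, 4e-3))
  expect_error(poiseuille_velocity(2e-3, fl, tube), "within")
})

test_that("unlabeled cells pass straight through; wall-seeded cells are captured", {
  tube <- tube_geometry()
  fl <- flow_spec(4e-3)
  tr <- integrate_trajectory(cell_spec(iron_mass = 0), c(0, 0.5e-3, 0),
                             fl, tube)
  expect_equal(tr$fate, "exited")
  expect_equal(tr$end[2], 0.5e-3, tolerance = 1e-9)  # no transverse motion
  # seeded touching the wall right under the magnet
  rho0 <- tube$inner_radius - cell_spec()$diameter / 2
  tr2 <- integrate_trajectory(cell_spec(), c(10e-3, -rho0, 0), fl, tube)
  expect_equal(tr2$fate, "captured")
  expect_equal(tr2$t_end, 0)
})

test_that("uniform-force plug-flow capture matches the slab oracle", {
  # 10 parameter sets spanning capture fractions well inside (0, 1)
  params <- expand.grid(u = c(0.3e-3, 0.6e-3, 1.2e-3, 2.4e-3, 4e-3),
                        v = c(4e-3, 12e-3))
  tube <- tube_geometry()
  cell <- cell_spec(diameter = 1e-6)   # near-point cell
  msat <- magnetocapture:::.saturation_moment(cell$iron_mass)
  mobility <- 1 / (3 * pi * 1e-3 * cell$diameter)
  H <- 2 * (tube$inner_radius - cell$diameter / 2)
  n <- 2000
  for (i in seq_len(nrow(params))) {
    u <- params$u[i]
    v <- params$v[i]
    g <- u / (msat * mobility)        # gradient giving drift u
    inl <- cbind(0, seq(-H / 2 + H / (2 * n), H / 2 - H / (2 * n),
                        length.out = n), 0)
    res <- simulate_capture(flow = flow_spec(v, "plug"), tube = tube,
                            population = cell, inlet = inl,
                            field_stub = list(grad = c(0, -g, 0), bmag = 0.45),
                            footprint_radius = Inf)
    expected <- slab_capture_fraction(u, v, tube$length, H)
    expect_lt(abs(res$CE / 100 - expected), 0.01)
  }
})

test_that("the capture threshold height matches the closed form to < 1%", {
  tube <- tube_geometry()
  cell <- cell_spec(diameter = 1e-6)
  msat <- magnetocapture:::.saturation_moment(cell$iron_mass)
  mobility <- 1 / (3 * pi * 1e-3 * cell$diameter)
  u <- 0.5e-3
  v <- 8e-3
  g <- u / (msat * mobility)
  rho_max <- tube$inner_radius - cell$diameter / 2
  ystar <- u * tube$length / v - rho_max  # analytic fate boundary
  for (off in c(-0.01, 0.01) * 2 * rho_max) {
    tr <- integrate_trajectory(cell, c(0, ystar + off, 0),
                               flow_spec(v, "plug"), tube,
                               field_stub = list(grad = c(0, -g, 0),
                                                 bmag = 0.45),
                               footprint_radius = Inf)
    expect_equal(tr$fate, if (off < 0) "captured" else "exited")
  }
})

test_that("capture bookkeeping: conservation, CE formula, reproducibility", {
  res <- simulate_capture(300, flow_spec(20e-3), seed = 42)
  expect_equal(res$Q1 + res$Q2 + res$flagged, res$n)
  expect_equal(res$flagged, 0)
  expect_equal(res$CE, 100 * res$Q1 / (res$Q1 + res$Q2))
  expect_true(res$CE >= 0 && res$CE <= 100)
  # identical config + seed reproduces the result bit for bit
  res2 <- simulate_capture(300, flow_spec(20e-3), seed = 42)
  expect_identical(res$outcomes, res2$outcomes)
})

test_that("zero-moment population gives CE = 0; overwhelming magnet gives 100", {
  none <- simulate_capture(100, flow_spec(20e-3),
                           population = cell_spec(iron_mass = 0), seed = 1)
  expect_equal(none$CE, 0)
  strong <- suppressWarnings(magnet_spec(remanence = 100 * 1.3416))
  all_in <- simulate_capture(100, flow_spec(4e-3), magnet = strong, seed = 1)
  expect_equal(all_in$CE, 100)
})

test_that("CE is monotone in velocity, iron load, and remanence (paired)", {
  vel <- ce_velocity_curve(c(4e-3, 40e-3, 400e-3), n = 250, seed = 5,
                           mode = "midplane")
  expect_true(all(diff(vel$ce_percent) <= 0))
  ce_iron <- vapply(c(5e-15, 21.77e-15, 60e-15), function(fe)
    simulate_capture(250, flow_spec(20e-3),
                     population = cell_spec(iron_mass = fe), seed = 5,
                     mode = "midplane")$CE, 0)
  expect_true(all(diff(ce_iron) >= 0))
  ce_br <- vapply(c(0.5, 1.34, 1.9), function(br)
    simulate_capture(250, flow_spec(20e-3),
                     magnet = magnet_spec(remanence = br), seed = 5,
                     mode = "midplane")$CE, 0)
  expect_true(all(diff(ce_br) >= 0))
})

test_that("capture_efficiency implements 100 Q1 / (Q1 + Q2)", {
  expect_equal(capture_efficiency(85, 15), 85.0)
  expect_equal(capture_efficiency(0, 100), 0)
  expect_equal(capture_efficiency(1, 0), 100)
  expect_error(capture_efficiency(0, 0), "positive")
  expect_error(capture_efficiency(-1, 5), "non-negative")
})

test_that("ce_velocity_curve rows and determinism under a fixed seed", {
  one <- ce_velocity_curve(20e-3, n = 50, seed = 9, mode = "midplane")
  expect_equal(nrow(one), 1)
  two <- ce_velocity_curve(c(20e-3, 20e-3), n = 50, seed = 9,
                           mode = "midplane")
  expect_equal(two$ce_percent[1], two$ce_percent[2])
})
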