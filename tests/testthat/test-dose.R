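test_that("beam and shift constructors validate their invariants", {
  expect_error(beam_spec(c(1, 1, 0), c(0, 0, 0), 50, 30, 10, 2), "unit 3-vector")
  expect_error(beam_spec(c(1, 0, 0), c(0, 0, 0), 20, 30, 10, 2), "nominal_range")
  expect_error(beam_spec(c(1, 0, 0), c(0, 0, 0), 50, 30, -1, 2), "sigmas")
  expect_error(fraction_shift(tx = Inf), "finite")
  expect_error(fraction_shift(yaw = 181), "rotations")
  expect_silent(fraction_shift(yaw = 180))
})

test_that("zero beams or zero weights give a zero dose grid", {
  ph <- tiny_phantom()
  expect_equal(compute_dose(ph, list()), array(0, ph$grid$shape))
  expect_equal(compute_dose(ph, list(tiny_beam(weight = 0))),
               array(0, ph$grid$shape))
})

test_that("mid-plateau on-axis dose equals the closed form", {
  b <- tiny_beam(weight = 0.7)
  # point on axis at depth R - M/2 is the beam isocenter itself
  d <- compute_dose_at(matrix(c(0, 0, 0), 1), list(b))
  expect_equal(d, 0.7, tolerance = 1e-9)
  # and anywhere on the plateau with r_perp = 0
  d2 <- compute_dose_at(matrix(c(10, 0, 0), 1), list(b))  # depth R - M/2 + 10
  expect_equal(d2, 0.7, tolerance = 1e-9)
})

test_that("distal 50% falloff depth scales with range_scale", {
  b <- tiny_beam()
  axis_dose <- function(depth_mm, rs) {
    # convert depth to the on-axis point x with d = x + R - M/2
    x <- depth_mm - (b$nominal_range_mm - b$modulation_mm / 2)
    compute_dose_at(matrix(c(x, 0, 0), 1), list(b), range_scale = rs)
  }
  d50 <- function(rs) stats::uniroot(function(z) axis_dose(z, rs) - 0.5,
                                     c(b$nominal_range_mm * rs - 1,
                                       b$nominal_range_mm * rs + 15),
                                     tol = 1e-10)$root
  expect_lt(abs(d50(1.035) - 1.035 * d50(1)), 1)  # half a voxel (1 mm)
  # strict monotonicity of the falloff depth in range_scale
  expect_true(d50(0.965) < d50(1) && d50(1) < d50(1.035))
})

test_that("dose is linear in beam weights", {
  ph <- tiny_phantom()
  sh <- fraction_shift(1, -2, 0.5, yaw = 3, pitch = -2, roll = 1)
  b1 <- tiny_beam(weight = 0.4)
  b2 <- beam_spec(c(0, 1, 0), c(2, 0, -2), 40, 20, 8, 1.5, weight = 0.6)
  d12 <- compute_dose(ph, list(b1, b2), sh)
  d1 <- compute_dose(ph, list(b1), sh)
  d2 <- compute_dose(ph, list(b2), sh)
  expect_equal(d12, d1 + d2, tolerance = 1e-12)
  b1x2 <- b1; b1x2$weight <- 0.8
  expect_equal(compute_dose(ph, list(b1x2), sh), 2 * d1, tolerance = 1e-12)
})

test_that("translating anatomy and beams together leaves metrics unchanged", {
  ph <- tiny_phantom()
  t <- c(4, -6, 2)
  b <- tiny_beam()
  bt <- b; bt$isocenter <- b$isocenter + t
  mask <- ph$structures$T$mask
  pts <- voxel_centers(ph$grid)[as.vector(mask), , drop = FALSE]
  d0 <- compute_dose_at(pts, list(b))
  dt <- compute_dose_at(sweep(pts, 2, -t), list(bt))
  expect_equal(dvh_metrics(d0, rep(TRUE, length(d0)), 60),
               dvh_metrics(dt, rep(TRUE, length(dt)), 60), tolerance = 1e-12)
})

test_that("nominal dose is reproduced bit-identically across calls", {
  ph <- tiny_phantom()
  b <- list(tiny_beam())
  expect_identical(compute_dose(ph, b), compute_dose(ph, b))
})

test_that("range_scale outside [0.8, 1.2] and bad beams are rejected", {
  ph <- tiny_phantom()
  expect_error(compute_dose(ph, list(tiny_beam()), range_scale = 0.5),
               "range_scale")
  expect_error(compute_dose_at(matrix(0, 1, 3), list(1)), "beam_spec")
})

test_that("normalize_plan hits the prescription and is idempotent and scale-invariant", {
  ph <- tiny_phantom()   # prescription 60 Gy
  beams <- list(tiny_beam(weight = 30),
                beam_spec(c(-1, 0, 0), c(0, 0, 0), 50, 30, 12, 2, weight = 30))
  n1 <- normalize_plan(ph, beams)
  d95 <- d_at_volume(compute_dose(ph, n1$beams), ph$structures$T$mask, 95)
  expect_equal(d95, 60, tolerance = 0.01)

  # idempotence: renormalizing a normalized plan gives scale 1
  n2 <- normalize_plan(ph, n1$beams)
  expect_equal(n2$scale, 1, tolerance = 1e-6)

  # scale invariance: doubling weights first changes nothing after normalization
  doubled <- lapply(beams, function(b) { b$weight <- 2 * b$weight; b })
  n3 <- normalize_plan(ph, doubled)
  expect_equal(compute_dose(ph, n3$beams), compute_dose(ph, n1$beams),
               tolerance = 1e-12)

  # all-zero nominal dose is a normalization error
  expect_error(normalize_plan(ph, list(tiny_beam(weight = 0))), "normalization")
})
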