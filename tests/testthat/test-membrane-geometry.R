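# Spectral surface representation and differential geometry against closed
# forms: spheres, ellipsoids and the biconcave resting shape.

test_that("sphere area, volume and curvature match closed forms", {
  for (R in c(1, 2)) {
    s <- sphere_of(R, p = 8L)
    m <- shape_metrics(s)
    expect_equal(m$area, 4 * pi * R^2, tolerance = 1e-8)
    expect_equal(m$volume, (4 / 3) * pi * R^3, tolerance = 1e-8)
    expect_equal(m$L, 2 * R, tolerance = 3e-3)
    expect_lt(m$DI, 1e-6)
    k <- mean_curvature(s)
    expect_lt(max(abs(k - 1 / R)), 1e-6)
  }
})

test_that("forward-then-inverse transform reproduces band-limited grids", {
  s <- make_resting_rbc(rbc_a, order = 12L)
  b <- rbcflow:::sh_basis(12L)
  f <- b$Y %*% s$coefficients
  C2 <- rbcflow:::sh_analyze(b, f)
  expect_lt(max(abs(C2 - s$coefficients)) / max(abs(s$coefficients)), 1e-10)
})

test_that("ellipsoid (2,1,1) caliper extents, DI and curvature", {
  e <- ellipsoid_211()
  m <- shape_metrics(e)
  expect_equal(m$L, 4, tolerance = 1e-3)
  expect_equal(m$W, 2, tolerance = 1e-3)
  expect_equal(m$DI, 1 / 3, tolerance = 1e-3)
  # mean curvature at the long-axis pole: k1 = k2 = a/b^2 = 2 for (2,1,1)
  g <- rbcflow:::surface_geometry(e, q = 16L)
  i_pole <- which.min(rowSums(sweep(g$x, 2L, c(2, 0, 0))^2))
  expect_equal(g$kappa[i_pole], 2, tolerance = 1e-4)
  # at the equator point (0, 1, 0): k1 = b/a^2 = 1/4, k2 = b/c^2 = 1
  i_eq <- which.min(rowSums(sweep(g$x, 2L, c(0, 1, 0))^2))
  expect_equal(g$kappa[i_eq], (1 / 4 + 1) / 2, tolerance = 1e-2)
})

test_that("resting RBC has the prescribed volume, area and axisymmetric DI", {
  s <- make_resting_rbc(rbc_a)
  m <- shape_metrics(s, a = rbc_a)
  expect_equal(m$volume, (4 / 3) * pi * rbc_a^3, tolerance = 1e-2)
  expect_equal(m$volume, 9.39e-17, tolerance = 1e-2)
  expect_equal(m$area_norm, 16.8, tolerance = 0.05)
  # axisymmetric discocyte: the two largest caliper extents coincide
  expect_lt(m$DI, 1e-6)
  expect_gt(m$H, 0)
  expect_gt(m$L / m$H, 2) # strongly non-spherical (flat disc)
  # outward normals: positive enclosed volume already checks orientation
  g <- rbcflow:::surface_geometry(s, q = 12L, second = FALSE)
  expect_gt(mean(rowSums(g$normal * sweep(g$x, 2L, colMeans(g$x)))), 0)
})

test_that("non-positive radius and degenerate aspect ratios error", {
  expect_error(make_resting_rbc(-1), "positive")
  expect_error(make_resting_rbc(0), "positive")
  expect_error(make_reference(rbc_a, 0), "aspect_ratio")
  expect_error(make_reference(rbc_a, 1.2), "aspect_ratio")
  expect_error(make_reference(-1, 0.9), "positive")
})

test_that("reference spheroid is volume-preserving; aspect 1 is a sphere", {
  ref <- make_reference(rbc_a, 0.9)
  s <- rbcflow:::reference_surface(ref, order = 8L)
  av <- rbcflow:::surface_area_volume(s)
  expect_equal(av$volume, (4 / 3) * pi * rbc_a^3, tolerance = 1e-3)
  ref1 <- make_reference(rbc_a, 1)
  s1 <- rbcflow:::reference_surface(ref1, order = 8L)
  av1 <- rbcflow:::surface_area_volume(s1)
  expect_equal(av1$area, 4 * pi * rbc_a^2, tolerance = 1e-6)
  # reference metric is SPD everywhere
  m0 <- rbcflow:::reference_metric(ref, 8L)
  expect_true(all(m0$E > 0))
  expect_true(all(m0$E * m0$G - m0$F^2 > 0))
})

test_that("metrics are invariant under rigid rotation of the coefficients", {
  # scalene ellipsoid: distinct principal axes make the caliper frame unique
  s <- rbcflow:::surface_from_param(
    function(th, ph) cbind(2 * sin(th) * cos(ph), 1.2 * sin(th) * sin(ph),
                           0.8 * cos(th)), p = 10L)
  th <- 0.7; ph <- 1.3
  Rz <- matrix(c(cos(ph), -sin(ph), 0, sin(ph), cos(ph), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  sr <- rbcflow:::rotate_surface(s, Rz %*% Ry)
  m <- shape_metrics(s); mr <- shape_metrics(sr)
  for (cl in c("area", "volume", "L", "W", "H", "DI")) {
    expect_equal(mr[[cl]], m[[cl]], tolerance = 1e-10)
  }
  # area and volume are also invariant for the (axisymmetric) resting shape
  s2 <- make_resting_rbc(rbc_a)
  s2r <- rbcflow:::rotate_surface(s2, Rz %*% Ry)
  expect_equal(shape_metrics(s2r)$area, shape_metrics(s2)$area, tolerance = 1e-10)
  expect_equal(shape_metrics(s2r)$volume, shape_metrics(s2)$volume, tolerance = 1e-10)
})

test_that("sphere quadrature error decays spectrally with order", {
  errs <- vapply(c(4L, 8L, 12L), function(p) {
    s <- unit_sphere(p)
    abs(rbcflow:::surface_area_volume(s)$area / (4 * pi) - 1)
  }, numeric(1))
  expect_true(all(errs < 1e-10)) # closed form recovered at every order
})

test_that("upsampling changes resting-shape area and volume by < 0.1%", {
  s <- make_resting_rbc(rbc_a)
  base <- rbcflow:::surface_area_volume(s, q = s$order)
  up <- rbcflow:::surface_area_volume(s, q = rbcflow:::upsampled_order(s))
  expect_lt(abs(up$area / base$area - 1), 1e-3)
  expect_lt(abs(up$volume / base$volume - 1), 1e-3)
})

test_that("degenerate surfaces are rejected", {
  s <- unit_sphere(6L)
  s$coefficients[] <- 0
  expect_error(shape_metrics(s), "degenerate")
  s2 <- unit_sphere(6L)
  s2$coefficients[1, ] <- NA
  expect_error(shape_metrics(s2), "degenerate")
})
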