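# Boundary-integral coupling: far-field evaluation, layer-potential
# identities, the velocity solve, and short dynamic runs.

test_that("far-field velocity: uniform, shear, rotation decompositions", {
  n <- 5L
  times <- c(0, 1)
  # uniform flow
  h <- far_field_history(times, matrix(rep(c(1, 0, 0), each = 2), 2, 3),
                         matrix(0, 2, 9))
  pts <- matrix(stats::rnorm(n * 3), n, 3)
  u <- far_field_velocity(h, 0.5, pts)
  expect_equal(u, matrix(c(1, 0, 0), n, 3, byrow = TRUE))
  # simple shear du1/dx2 = k at (0, d, 0)
  k <- 7
  g <- rep(0, 9); g[2] <- k
  hs <- far_field_history(times, matrix(0, 2, 3), rbind(g, g))
  us <- far_field_velocity(hs, 0.3, matrix(c(0, 2, 0), 1, 3))
  expect_equal(drop(us), c(k * 2, 0, 0))
  # rigid rotation: antisymmetric gradient has zero rate of strain
  ga <- c(0, 1, 0, -1, 0, 0, 0, 0, 0)
  ha <- far_field_history(times, matrix(0, 2, 3), rbind(ga, ga))
  G <- matrix(ga, 3, 3, byrow = TRUE)
  expect_equal(G + t(G), matrix(0, 3, 3))
  expect_error(far_field_velocity(h, 2, pts), "outside")
  # linear interpolation between samples is exact for linear histories
  h2 <- far_field_history(c(0, 1), rbind(c(0, 0, 0), c(2, 0, 0)), matrix(0, 2, 9))
  expect_equal(drop(far_field_velocity(h2, 0.25, matrix(0, 1, 3))), c(0.5, 0, 0))
})

test_that("history validation: ordering and incompressibility", {
  expect_error(far_field_history(c(0, 0), matrix(0, 2, 3), matrix(0, 2, 9)),
               "increasing")
  g <- rep(0, 9); g[1] <- 1 # pure dilation: trace 1
  expect_error(far_field_history(c(0, 1), matrix(0, 2, 3), rbind(g, g)),
               "traceless")
})

test_that("Stokeslet kernel is symmetric: G_ij(x, x0) = G_ji(x0, x)", {
  set.seed(11)
  Gfun <- function(x, x0) {
    r <- x - x0; rn <- sqrt(sum(r^2))
    diag(3) / rn + outer(r, r) / rn^3
  }
  for (k in 1:5) {
    x <- stats::rnorm(3); x0 <- stats::rnorm(3)
    expect_lt(max(abs(Gfun(x, x0) - t(Gfun(x0, x)))), 1e-12)
  }
})

test_that("double layer of a constant density reproduces -4 pi u on-surface", {
  s <- sphere_of(1, p = 8L)
  N <- (8 + 1) * (2 * 8 + 2)
  cvec <- c(0.3, -1.2, 2.0)
  u <- matrix(cvec, N, 3, byrow = TRUE)
  dl <- double_layer(s, u)
  expect_lt(max(abs(sweep(dl, 2, -4 * pi * cvec))), 1e-6)
  # linearity and zero map
  expect_true(all(double_layer(s, 0 * u) == -0))
  # biconcave surface too (identity holds on any smooth closed surface)
  rb <- make_resting_rbc(1, order = 8L)
  Nb <- (8 + 1) * (2 * 8 + 2)
  ub <- matrix(cvec, Nb, 3, byrow = TRUE)
  dlb <- double_layer(rb, ub)
  expect_lt(max(abs(sweep(dlb, 2, -4 * pi * cvec))) / (4 * pi * max(abs(cvec))), 1e-4)
})

test_that("single layer: constant density on the unit sphere and linearity", {
  s <- sphere_of(1, p = 8L)
  N <- (8 + 1) * (2 * 8 + 2)
  cvec <- c(1, -0.5, 0.25)
  f <- matrix(cvec, N, 3, byrow = TRUE)
  sl <- single_layer(s, f)
  # Stokes drag closed form: int G dS = (16 pi / 3) R I on the surface
  expect_lt(max(abs(sweep(sl, 2, (16 * pi / 3) * cvec))) / (16 * pi / 3), 1e-8)
  expect_equal(single_layer(s, 2 * f), 2 * sl, tolerance = 1e-12)
  expect_true(all(single_layer(s, 0 * f) == 0))
})

test_that("uniform normal single layer is flow-free outside a sphere", {
  s <- sphere_of(1, p = 8L)
  g <- rbcflow:::surface_geometry(s, q = 8L, second = FALSE)
  f <- 2.5 * g$normal
  targets <- rbind(c(3, 0.5, 0.2), c(0.1, -2.5, 1.0))
  sl <- single_layer(s, f, targets = targets)
  expect_lt(max(abs(sl)) / 2.5, 1e-10)
})

test_that("membrane velocity: trivial and contrast-free reductions", {
  s <- sphere_of(1, p = 8L)
  N <- (8 + 1) * (2 * 8 + 2)
  mat1 <- membrane_material(a = 1, G = 1, EB = 0, c0 = 0, mu = 1, lambda_visc = 1)
  uinf <- matrix(stats::rnorm(N * 3), N, 3)
  # delta_f = 0, lambda = 1: u = u_inf exactly (prefactor 2/(1+1) = 1)
  mv <- membrane_velocity(s, matrix(0, N, 3), uinf, mat1)
  expect_equal(mv$u, uinf, tolerance = 1e-12)
  expect_identical(mv$iterations, 0L)
  # quiescent: u = 0 for any lambda
  mat15 <- membrane_material(a = 1, G = 1, EB = 0, c0 = 0, mu = 1, lambda_visc = 1.5)
  mv0 <- membrane_velocity(s, matrix(0, N, 3), matrix(0, N, 3), mat15)
  expect_lt(max(abs(mv0$u)), 1e-14)
  # lambda -> 1 limit agrees with the explicit lambda = 1 path
  g <- rbcflow:::surface_geometry(s, q = 8L, second = FALSE)
  ushear <- cbind(g$x[, 2], 0 * g$x[, 1], 0 * g$x[, 1])
  mat1p <- membrane_material(a = 1, G = 1, EB = 0, c0 = 0, mu = 1,
                             lambda_visc = 1 + 1e-12)
  u_a <- membrane_velocity(s, matrix(0, N, 3), ushear, mat1)$u
  u_b <- membrane_velocity(s, matrix(0, N, 3), ushear, mat1p)$u
  expect_lt(max(abs(u_a - u_b)), 1e-8)
})

test_that("quiescent relaxation is dissipative and conserves volume", {
  mat <- table1_material()
  ref <- make_reference(rbc_a, 0.9)
  s <- make_resting_rbc(rbc_a, order = 8L)
  h <- far_field_history(c(0, 1), matrix(0, 2, 3), matrix(0, 2, 9))
  res <- advance_cell(s, ref, mat, h, dt = 2e-6, t_end = 2e-4,
                      record_stride = 20L, filter_strength = 0.1)
  expect_identical(res$stability, "stable")
  r <- res$records
  # membrane speed decays as the shape relaxes
  expect_lt(r$u_max[nrow(r)], 0.7 * r$u_max[2])
  expect_lt(abs(r$volume[nrow(r)] / r$volume[1] - 1), 1e-6)
  # capillary number trace is mu gdot a / G (zero here)
  expect_true(all(r$Ca == 0))
})

test_that("stability monitor flags the documented failure modes", {
  s <- make_resting_rbc(rbc_a, order = 8L)
  A0 <- rbcflow:::surface_area_volume(s)$area
  expect_identical(stability_monitor(s, A0)$flag, "stable")
  s_nan <- s; s_nan$coefficients[5, 2] <- NaN
  expect_identical(stability_monitor(s_nan, A0)$flag, "unstable")
  s_big <- s; s_big$coefficients <- s$coefficients * 2 # area x4 > 3x
  expect_identical(stability_monitor(s_big, A0)$flag, "unstable")
  expect_match(stability_monitor(s_big, A0)$reason, "area")
  # synthetic tail-energy ramp
  s_tail <- s
  ltop <- rbcflow:::sh_degrees(8L) >= 7L
  s_tail$coefficients[ltop, ] <- 0.35 * max(abs(s$coefficients))
  mon <- stability_monitor(s_tail, A0 * 100) # disable the area trigger
  expect_identical(mon$flag, "unstable")
  expect_match(mon$reason, "tail")
})

test_that("advected shear run records a positive, finite Ca trace", {
  mat <- table1_material()
  ref <- make_reference(rbc_a, 0.9)
  s <- make_resting_rbc(rbc_a, order = 8L)
  gdot <- 1000
  g <- rep(0, 9); g[2] <- gdot
  h <- far_field_history(c(0, 1), matrix(0, 2, 3), rbind(g, g))
  res <- advance_cell(s, ref, mat, h, dt = 2e-6, t_end = 6e-5,
                      record_stride = 10L, filter_strength = 0.1)
  expect_identical(res$stability, "stable")
  ca <- res$records$Ca[-1]
  expect_true(all(abs(ca - mat$mu * gdot * rbc_a / mat$G) < 1e-12))
  expect_equal(mean(ca), 0.188, tolerance = 1e-2)
})
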