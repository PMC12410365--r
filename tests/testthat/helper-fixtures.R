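# Shared fixtures, built in code. Sizes are kept small: geometry oracles are
# resolution-independent, and the dynamic checks only need the qualitative
# regime, not production resolution.

rbc_a <- 2.82e-6

table1_material <- function(...) membrane_material(a = rbc_a, ...)

unit_sphere <- function(p = 8L) {
  rbcflow:::reference_surface(make_reference(1, 1), order = p)
}

sphere_of <- function(R, p = 8L) {
  s <- unit_sphere(p)
  s$coefficients <- s$coefficients * R
  s
}

ellipsoid_211 <- function(p = 12L) {
  rbcflow:::surface_from_param(
    function(th, ph) cbind(2 * sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
    p = p
  )
}

# small pipe fixture reused across tracking/fixtures/pipeline tests
small_pipe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- make_pipe_mesh(1e-3, 4e-3, 1e-4, axial_edge = 4e-4)
      m <- make_pulsatile_frames(m, Umax = 0.4, T = 0.5, Nf = 8L, waveform = "sine")
      m <- project_gradients(m)
      m <- fourier_series(m)
      cache <<- m
    }
    cache
  }
})

steady_pipe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- make_pipe_mesh(1e-3, 4e-3, 1e-4, axial_edge = 4e-4)
      m <- make_pulsatile_frames(m, Umax = 0.4, T = 0.5, Nf = 1L, waveform = "steady")
      cache <<- project_gradients(m)
    }
    cache
  }
})

# deformation-record cohort with known structure for damage statistics
synthetic_records <- function(n_cells = 10L, n_times = 20L, seed = 42L) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_cells), function(cid) {
    base <- stats::runif(1, 1.0, 1.2)
    tibble::tibble(
      cell_id = cid,
      time = seq(0, by = 1e-4, length.out = n_times),
      dt_i = rep(1e-4, n_times),
      max_areal_strain = base + stats::runif(n_times, 0, 0.5),
      mean_areal_strain = base + stats::runif(n_times, 0, 0.2),
      max_shear_strain = 1 + stats::rexp(n_times, 2),
      mean_shear_strain = 1 + stats::rexp(n_times, 3),
      area_ratio = base + stats::runif(n_times, -0.05, 0.2),
      length_ratio = 1 + stats::rexp(n_times, 4),
      DI = stats::runif(n_times, 0, 0.5),
      gdot = stats::runif(n_times, 100, 2e4)
    )
  })
}
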