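# Synthetic data generation: structured cylindrical-pipe tetrahedral meshes
# with labelled boundaries, analytic pulsatile Poiseuille frames, and
# shunt-passage-like shear-rate histories. Everything is generated in code,
# deterministically, so every downstream stage can be exercised without
# external data.

# Triangulated disk of radius R built from nr concentric rings (ring k has
# 6k nodes, aligned at angle 0). Each annulus is triangulated by the
# umbrella rule: every outer edge fans to the angularly nearest inner node,
# every inner edge to the nearest outer node (6k + 6(k-1) triangles).
disk_triangulation <- function(R, nr) {
  pts_list <- list(matrix(c(0, 0), 1L, 2L))
  ring_start <- integer(nr + 1L); ring_n <- integer(nr + 1L)
  ring_start[1] <- 1L; ring_n[1] <- 1L
  for (k in seq_len(nr)) {
    nk <- 6L * k
    ang <- 2 * pi * (0:(nk - 1L)) / nk
    pts_list[[k + 1L]] <- R * k / nr * cbind(cos(ang), sin(ang))
    ring_start[k + 1L] <- ring_start[k] + ring_n[k]
    ring_n[k + 1L] <- nk
  }
  pts <- do.call(rbind, pts_list)
  tri_list <- vector("list", nr)
  for (k in seq_len(nr)) {
    is <- ring_start[k]; ni <- ring_n[k]
    os <- ring_start[k + 1L]; no <- ring_n[k + 1L]
    o <- 0:(no - 1L)
    o2 <- (o + 1L) %% no
    mid_o <- 2 * pi * (o + 0.5) / no
    nearest_i <- if (ni == 1L) rep(0L, no) else (round(mid_o * ni / (2 * pi)) %% ni)
    t_outer <- cbind(os + o, os + o2, is + nearest_i)
    if (ni > 1L) {
      i <- 0:(ni - 1L)
      i2 <- (i + 1L) %% ni
      mid_i <- 2 * pi * (i + 0.5) / ni
      nearest_o <- round(mid_i * no / (2 * pi)) %% no
      t_inner <- cbind(is + i2, is + i, os + nearest_o)
      tri_list[[k]] <- rbind(t_outer, t_inner)
    } else {
      tri_list[[k]] <- t_outer
    }
  }
  list(points = pts, triangles = do.call(rbind, tri_list))
}

#' Cylindrical pipe mesh fixture
#'
#' Watertight structured tetrahedral mesh of a cylinder (axis z, inlet at
#' z = 0, outlet at z = `length`), with boundary faces labelled `inlet`,
#' `outlet` and `wall`. Built by triangulating the cross-section disk,
#' extruding in z and splitting each prism into three positively oriented
#' tetrahedra.
#'
#' @param R pipe radius, m.
#' @param length pipe length, m.
#' @param target_edge target in-plane (cross-section) edge length, m.
#' @param axial_edge target axial layer thickness, m (defaults to
#'   `target_edge`; axial refinement can be chosen independently because the
#'   fixture profiles are z-invariant).
#' @return a [tet_flow_field()] skeleton with a single zero-velocity frame.
#' @export
make_pipe_mesh <- function(R, length, target_edge, axial_edge = target_edge) {
  stopifnot(R > 0, length > 0, target_edge > 0, axial_edge > 0)
  nr <- max(2L, as.integer(round(R / target_edge)))
  nz <- max(2L, as.integer(round(length / axial_edge)))
  if (nr > 200L || nz > 2000L) stop("infeasible resolution", call. = FALSE)
  disk <- disk_triangulation(R, nr)
  npl <- nrow(disk$points) # nodes per layer
  zs <- seq(0, length, length.out = nz + 1L)
  nodes <- do.call(rbind, lapply(zs, function(z) cbind(disk$points, z)))
  # Each prism (triangle extruded one layer) splits into 3 tets with quad
  # diagonals through the smallest global vertex of each quad face
  # (Dompierre et al. rule), which makes the split conforming. Because the
  # top layer ids are bottom ids + npl, the case taken is layer-independent:
  # split layer 1 and replicate with offsets.
  tris <- disk$triangles
  amin <- max.col(-tris, ties.method = "first")
  rot <- function(k) tris[cbind(seq_len(nrow(tris)), ((amin - 1L + k) %% 3L) + 1L)]
  b1 <- rot(0L); b2 <- rot(1L); b3 <- rot(2L)
  t1 <- b1 + npl; t2 <- b2 + npl; t3 <- b3 + npl
  cond <- b2 < b3 # = min(V2, V6) < min(V3, V5) since tops exceed bottoms
  T3a <- rbind(cbind(b1, b2, b3, t3), cbind(b1, b2, t3, t2), cbind(b1, t2, t3, t1))
  T3b <- rbind(cbind(b1, b2, b3, t2), cbind(b1, t2, b3, t3), cbind(b1, t2, t3, t1))
  sel <- rep(cond, 3L)
  tets1 <- T3a
  tets1[!sel, ] <- T3b[!sel, ]
  tets <- do.call(rbind, lapply(seq_len(nz) - 1L, function(l) tets1 + l * npl))
  # fix orientation (positive volume); swapping the last two vertices leaves
  # the face set (hence conformity) unchanged
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("mesh error: degenerate tetrahedra", call. = FALSE)
  # boundary faces: those appearing exactly once across all tets
  face_idx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(fi) tets[, face_idx[fi, ]]))
  fa <- pmin(faces[, 1], faces[, 2], faces[, 3])
  fc <- pmax(faces[, 1], faces[, 2], faces[, 3])
  fb <- faces[, 1] + faces[, 2] + faces[, 3] - fa - fc
  nn <- as.numeric(nrow(nodes)) + 1
  key <- (as.numeric(fa) * nn + as.numeric(fb)) * nn + as.numeric(fc)
  single <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  bnd <- faces[single, , drop = FALSE]
  zc <- (nodes[bnd[, 1], 3] + nodes[bnd[, 2], 3] + nodes[bnd[, 3], 3]) / 3
  ztol <- length * 1e-9
  lab <- ifelse(zc < ztol, "inlet",
                ifelse(zc > length - ztol, "outlet", "wall"))
  boundary <- data.frame(n1 = bnd[, 1], n2 = bnd[, 2], n3 = bnd[, 3],
                         label = lab, stringsAsFactors = FALSE)
  field <- tet_flow_field(nodes, tets, boundary,
                          frames = matrix(0, nrow(nodes), 3), period = 1)
  field$R <- R; field$length <- length
  field
}

#' Pulsatile Poiseuille frames on a pipe mesh
#'
#' Fills a pipe fixture with `u(r, t) = Umax w(t) (1 - r^2/R^2) e_z` at `Nf`
#' uniform sample times over one period (divergence-free by construction,
#' flux `pi R^2 Umax w(t) / 2`).
#'
#' @param mesh a [make_pipe_mesh()] result.
#' @param Umax peak centreline speed, m/s.
#' @param T period, s.
#' @param Nf number of uniformly spaced frames (>= 4 for unsteady).
#' @param waveform periodic modulation `w(t)`: a function of time, or one of
#'   `"steady"` (w = 1), `"sine"` (`w = 1 + 0.5 sin(2 pi t/T)`), or
#'   `"pulsatile"` (a cardiac-like multi-harmonic series whose amplitudes
#'   decay roughly as 1/k^2, so it is nearly but not exactly band-limited).
#' @return the mesh as a [tet_flow_field()] with frames and period set.
#' @export
make_pulsatile_frames <- function(mesh, Umax, T = 0.5, Nf = 8L,
                                  waveform = "sine") {
  stopifnot(inherits(mesh, "tet_flow_field"), Nf >= 1L)
  w <- if (is.function(waveform)) waveform
  else switch(waveform,
              steady = function(t) rep(1, length(t)),
              sine = function(t) 1 + 0.5 * sin(2 * pi * t / T),
              pulsatile = function(t) {
                tau <- 2 * pi * t / T
                1 + 0.5 * sin(tau) + 0.15 * sin(2 * tau) + 0.05 * cos(3 * tau) +
                  0.005 * sin(5 * tau) + 0.0025 * cos(6 * tau)
              },
              stop("unknown waveform", call. = FALSE))
  R <- mesh$R
  r2 <- rowSums(mesh$nodes[, 1:2, drop = FALSE]^2)
  prof <- Umax * pmax(1 - r2 / R^2, 0)
  ts <- T * (0:(Nf - 1L)) / Nf
  mesh$frames <- lapply(ts, function(t) cbind(0, 0, prof * w(t)))
  mesh$period <- T
  mesh$waveform <- w
  mesh
}

#' Shunt-passage-like shear-rate profile
#'
#' Parameters of a synthetic velocity-gradient history emulating a cell's
#' passage through a high-shear shunt: a physiological baseline shear rate
#' with millisecond-scale excursions to supraphysiological values.
#'
#' @param baseline baseline shear rate, 1/s (default 1e3).
#' @param peak peak shear rate, 1/s (default 4e4; the solver's stability
#'   bound sits near 5.77e4).
#' @param pulse_start pulse onset time, s.
#' @param pulse_duration pulse plateau duration, s (default 1e-3).
#' @param ramp cosine-taper ramp time on each side of the pulse, s.
#' @param shape `"smooth_bump"` (cosine-tapered plateau) or `"plateau"`.
#' @param flow_type `"simple_shear"` or `"extension"` tensor layout.
#' @param seed RNG seed recorded with the profile (generation itself is
#'   deterministic).
#' @return an object of class `shear_history_profile`.
#' @export
shear_history_profile <- function(baseline = 1e3, peak = 4e4,
                                  pulse_start = 2e-3, pulse_duration = 1e-3,
                                  ramp = 5e-4,
                                  shape = c("smooth_bump", "plateau"),
                                  flow_type = c("simple_shear", "extension"),
                                  seed = 1L) {
  shape <- match.arg(shape)
  flow_type <- match.arg(flow_type)
  if (!(peak >= baseline && baseline > 0)) {
    stop("need peak >= baseline > 0", call. = FALSE)
  }
  structure(list(baseline = baseline, peak = peak, pulse_start = pulse_start,
                 pulse_duration = pulse_duration, ramp = ramp, shape = shape,
                 flow_type = flow_type, seed = seed),
            class = "shear_history_profile")
}

#' Far-field history from a shear profile
#'
#' Builds the traceless velocity-gradient time series whose Frobenius norm
#' follows the profile's shear-rate trace; the capillary number trace is
#' `Ca(t) = mu gdot(t) a / G`.
#'
#' @param profile a [shear_history_profile()].
#' @param duration total history length, s.
#' @param dt sample spacing, s (default 1e-5).
#' @param material a [membrane_material()] for the stability warning bound
#'   (optional).
#' @param a characteristic radius used for the Ca warning, m.
#' @param ca_bound warn if peak Ca exceeds this (default 10.85, the
#'   stability bound at 57,700 1/s under the default material).
#' @return a [far_field_history()].
#' @export
make_shear_history <- function(profile, duration = 6e-3, dt = 1e-5,
                               material = NULL, a = 2.82e-6,
                               ca_bound = 10.85) {
  stopifnot(inherits(profile, "shear_history_profile"))
  times <- seq(0, duration, by = dt)
  g <- shear_rate_trace(profile, times)
  if (!is.null(material)) {
    ca_peak <- material$mu * max(g) * a / material$G
    if (ca_peak > ca_bound) {
      warning(sprintf("peak Ca %.3g exceeds the stability bound %.3g; the run will proceed and the stability monitor will flag it",
                      ca_peak, ca_bound))
    }
  }
  n <- length(times)
  gradU <- matrix(0, n, 9)
  if (profile$flow_type == "simple_shear") {
    gradU[, 2] <- g # du1/dx2, Frobenius norm = g
  } else {
    gradU[, 1] <- g / sqrt(2)
    gradU[, 5] <- -g / sqrt(2) # planar extension, Frobenius norm = g
  }
  far_field_history(times, matrix(0, n, 3), gradU)
}

# Shear-rate trace gdot(t) of a profile (cosine-tapered ramps).
shear_rate_trace <- function(profile, times) {
  b <- profile$baseline; pk <- profile$peak
  t0 <- profile$pulse_start; dur <- profile$pulse_duration; rmp <- profile$ramp
  if (dur <= 0 && rmp <= 0) return(rep(b, length(times)))
  up0 <- t0 - rmp; up1 <- t0
  dn0 <- t0 + dur; dn1 <- t0 + dur + rmp
  f <- numeric(length(times))
  if (profile$shape == "plateau") {
    f <- ifelse(times >= t0 & times <= dn0, 1, 0)
  } else {
    f <- ifelse(times < up0 | times > dn1, 0,
         ifelse(times < up1, 0.5 * (1 - cos(pi * (times - up0) / max(rmp, 1e-300))),
         ifelse(times <= dn0, 1,
                0.5 * (1 + cos(pi * (times - dn0) / max(rmp, 1e-300))))))
  }
  b + (pk - b) * f
}
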