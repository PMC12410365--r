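# Massless Lagrangian advection of RBC proxies through a flow field:
# search-box host location, flux-weighted inlet seeding, forward-Euler
# advection with wall reflection, and velocity-gradient history extraction.

#' Build a search-box index over a tetrahedral mesh
#'
#' A coarse uniform Cartesian grid over the mesh bounding box; each box
#' lists every element whose bounding box overlaps it, so a host-element
#' query only inspects the candidate list of the query point's box.
#'
#' @param field a [tet_flow_field()].
#' @param boxes_per_axis integer (scalar or 3-vector); default scales with
#'   the cube root of the element count.
#' @return an object of class `search_box_index`.
#' @export
build_search_index <- function(field, boxes_per_axis = NULL) {
  stopifnot(inherits(field, "tet_flow_field"))
  M <- nrow(field$tets)
  if (is.null(boxes_per_axis)) {
    boxes_per_axis <- max(1L, as.integer(round(M^(1 / 3) / 2)))
  }
  nb <- as.integer(rep_len(boxes_per_axis, 3L))
  lo <- apply(field$nodes, 2L, min)
  hi <- apply(field$nodes, 2L, max)
  tets0 <- field$tets - 1L
  bx <- build_search_boxes(field$nodes, tets0, nb, lo, hi)
  structure(
    list(nb = nb, lo = lo, hi = hi, ptr = bx$ptr, elems = bx$elems,
         tets0 = tets0, tinv = tet_inverse_matrices(field$nodes, field$tets),
         nodes = field$nodes, tets = field$tets),
    class = "search_box_index"
  )
}

#' Locate host elements
#'
#' Returns the element containing each point: all barycentric coordinates
#' `>= -1e-12`, with face/edge ties resolved to the lowest element id;
#' `NA` when no candidate qualifies (point outside the mesh).
#'
#' @param x positions, `n x 3` matrix, m.
#' @param index a [build_search_index()] result.
#' @param tol barycentric tolerance (default 1e-12).
#' @return integer vector of 1-based element ids (`NA` = none).
#' @export
locate_host <- function(x, index, tol = 1e-12) {
  x <- matrix(as.numeric(x), ncol = 3L)
  h <- locate_hosts_cpp(x, index$nodes, index$tets0, index$tinv,
                        index$ptr, index$elems, index$nb, index$lo,
                        index$hi, tol)
  h[h == 0L] <- NA_integer_
  h
}

#' Flux-weighted seeding schedule
#'
#' Distributes `np_total` particles over the time steps of one period in
#' proportion to the volume of fluid entering the inlet in each step
#' (largest-remainder rounding); steps with bulk backflow get zero.
#'
#' @param times step times covering one period (length `m + 1` edges or
#'   `m` step starts with uniform spacing), s.
#' @param flux inlet volumetric flux at `times`, m^3/s (positive = inflow).
#' @param np_total total particles per period.
#' @return a tibble with `time`, `inflow` (volume increment, m^3) and `np`
#'   per step; `sum(np) == np_total`.
#' @export
make_seeding_schedule <- function(times, flux, np_total) {
  stopifnot(length(times) == length(flux), np_total >= 0)
  m <- length(times) - 1L
  if (m < 1L) stop("need at least two time samples", call. = FALSE)
  dV <- diff(times) * (flux[-length(flux)] + flux[-1]) / 2
  pos <- pmax(dV, 0)
  if (sum(pos) <= 0) {
    stop("no net inflow over the period: cannot seed particles", call. = FALSE)
  }
  ideal <- np_total * pos / sum(pos)
  np <- floor(ideal)
  rem <- np_total - sum(np)
  if (rem > 0) {
    ord <- order(ideal - np, decreasing = TRUE)
    np[ord[seq_len(rem)]] <- np[ord[seq_len(rem)]] + 1L
  }
  tibble::tibble(time = times[-length(times)], inflow = dV, np = as.integer(np))
}

#' Inlet flux of a stored flow field
#'
#' Integral of `u . n` over the inlet faces (n pointing into the domain) at
#' the requested times.
#'
#' @param field a [tet_flow_field()].
#' @param times evaluation times, s.
#' @return numeric vector of fluxes, m^3/s.
#' @export
inlet_flux <- function(field, times) {
  faces <- field$boundary[field$boundary$label == "inlet", ]
  v0 <- field$nodes[faces$n1, , drop = FALSE]
  v1 <- field$nodes[faces$n2, , drop = FALSE]
  v2 <- field$nodes[faces$n3, , drop = FALSE]
  cr <- cross_rows(v1 - v0, v2 - v0)
  # orient into the domain: inward = away from the boundary face towards the
  # mesh interior; use the domain centroid as reference
  ctr <- colMeans(field$nodes)
  fc <- (v0 + v1 + v2) / 3
  sgn <- sign(rowSums(cr * sweep(fc, 2L, ctr)))
  cr <- cr * ifelse(sgn > 0, -1, 1) # flip outward-pointing normals
  vapply(times, function(t) {
    u <- if (length(field$frames) == 1L) field$frames[[1]] else evaluate_time(field, t)
    um <- (u[faces$n1, , drop = FALSE] + u[faces$n2, , drop = FALSE] +
             u[faces$n3, , drop = FALSE]) / 3
    sum(rowSums(um * cr)) / 2
  }, numeric(1))
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Sample inlet positions with velocity-proportional density
#'
#' Rejection sampling on the inlet faces with density proportional to the
#' local inward normal velocity, so more particles enter where the flow is
#' faster (keeping the seeded volume density uniform). A uniform inflow
#' reduces to uniform-by-area sampling.
#'
#' @param field a [tet_flow_field()].
#' @param t time at which to read the inlet velocity, s.
#' @param n number of positions.
#' @param seed explicit RNG seed.
#' @param eps small inward offset (fraction of face size) so samples start
#'   strictly inside the domain (default 1e-3).
#' @return `n x 3` matrix of positions.
#' @export
sample_inlet_positions <- function(field, t, n, seed, eps = 1e-3) {
  stopifnot(n >= 0)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  faces <- field$boundary[field$boundary$label == "inlet", ]
  u <- if (length(field$frames) == 1L) field$frames[[1]] else evaluate_time(field, t)
  v0 <- field$nodes[faces$n1, , drop = FALSE]
  v1 <- field$nodes[faces$n2, , drop = FALSE]
  v2 <- field$nodes[faces$n3, , drop = FALSE]
  cr <- cross_rows(v1 - v0, v2 - v0)
  area2 <- sqrt(rowSums(cr^2)) # 2x area
  ctr <- colMeans(field$nodes)
  fc <- (v0 + v1 + v2) / 3
  inward <- cr * ifelse(sign(rowSums(cr * sweep(fc, 2L, ctr))) > 0, -1, 1)
  inward <- inward / sqrt(rowSums(inward^2))
  vn <- cbind(rowSums(u[faces$n1, , drop = FALSE] * inward),
              rowSums(u[faces$n2, , drop = FALSE] * inward),
              rowSums(u[faces$n3, , drop = FALSE] * inward))
  vn <- pmax(vn, 0)
  wface <- area2 / 2 * rowMeans(vn)
  if (sum(wface) <= 0) stop("zero total inflow at t: cannot seed", call. = FALSE)
  vmaxf <- pmax(apply(vn, 1L, max), .Machine$double.eps)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  out <- matrix(0, n, 3)
  got <- 0L
  while (got < n) {
    todo <- n - got
    f <- sample.int(nrow(faces), todo, replace = TRUE, prob = wface)
    r1 <- stats::runif(todo); r2 <- stats::runif(todo)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]; r2[flip] <- 1 - r2[flip]
    w0 <- 1 - r1 - r2
    pts <- w0 * v0[f, , drop = FALSE] + r1 * v1[f, , drop = FALSE] +
      r2 * v2[f, , drop = FALSE]
    vloc <- w0 * vn[f, 1] + r1 * vn[f, 2] + r2 * vn[f, 3]
    acc <- stats::runif(todo) < vloc / vmaxf[f]
    nacc <- sum(acc)
    if (nacc > 0L) {
      sel <- which(acc)
      pin <- pts[sel, , drop = FALSE] +
        eps * sqrt(area2[f[sel]]) * inward[f[sel], , drop = FALSE]
      out[got + seq_len(nacc), ] <- pin
      got <- got + nacc
    }
  }
  out
}

#' Frobenius shear rate of a velocity-gradient tensor
#'
#' `gdot = sqrt(sum_ij (du_i/dx_j)^2)`, the 2-norm of the velocity-gradient
#' tensor; invariant under orthogonal changes of frame.
#'
#' @param gradU a 3x3 matrix, a length-9 vector, or an `n x 9` matrix of
#'   row-major tensors.
#' @return scalar or vector of shear rates, 1/s.
#' @export
shear_rate <- function(gradU) {
  if (is.matrix(gradU) && ncol(gradU) == 9L) sqrt(rowSums(gradU^2))
  else sqrt(sum(gradU^2))
}

# Wall/outlet helper structures for the advection kernel.
boundary_structures <- function(field) {
  wall <- field$boundary[field$boundary$label == "wall", ]
  outlet <- field$boundary[field$boundary$label == "outlet", ]
  wall_faces <- as.matrix(wall[, c("n1", "n2", "n3")]) - 1L
  storage.mode(wall_faces) <- "integer"
  outlet_faces <- as.matrix(outlet[, c("n1", "n2", "n3")]) - 1L
  storage.mode(outlet_faces) <- "integer"
  wn <- sort(unique(as.vector(wall_faces)))
  # CSR: faces incident to each wall node
  inc <- data.frame(node = as.vector(wall_faces),
                    face = rep(seq_len(nrow(wall_faces)) - 1L, 3L))
  inc <- inc[order(inc$node, inc$face), ]
  cnt <- tabulate(match(inc$node, wn), nbins = length(wn))
  ptr <- c(0L, cumsum(cnt))
  list(wall_faces = wall_faces, outlet_faces = outlet_faces,
       wall_node_ids = as.integer(wn), wn_ptr = as.integer(ptr),
       wn_faces = as.integer(inc$face))
}

#' Reflect a wall-crossing displacement
#'
#' Specular reflection of the portion of a particle displacement beyond the
#' wall: the crossed triangle is found by segment-triangle intersection and
#' the remaining displacement is mirrored about its plane, preserving total
#' path length (angle of incidence = angle of reflection).
#'
#' @param prev previous (inside) position, length-3.
#' @param attempted attempted (outside) position, length-3.
#' @param triangles list with matrices `v0`, `v1`, `v2` (`m x 3` vertex
#'   rows), or a [tet_flow_field()] whose wall faces are used.
#' @return list with `corrected` position, `crossing` point and `hit` flag.
#' @export
reflect_at_wall <- function(prev, attempted, triangles) {
  if (inherits(triangles, "tet_flow_field")) {
    w <- triangles$boundary[triangles$boundary$label == "wall", ]
    triangles <- list(v0 = triangles$nodes[w$n1, , drop = FALSE],
                      v1 = triangles$nodes[w$n2, , drop = FALSE],
                      v2 = triangles$nodes[w$n3, , drop = FALSE])
  }
  res <- reflect_segment_cpp(as.numeric(prev), as.numeric(attempted),
                             triangles$v0, triangles$v1, triangles$v2)
  if (!isTRUE(res$hit)) {
    return(list(hit = FALSE, corrected = as.numeric(attempted),
                crossing = NULL))
  }
  list(hit = TRUE, corrected = res$corrected, crossing = res$crossing,
       triangle = res$triangle)
}

#' Advect particles through a flow field
#'
#' Forward-Euler integration of `dx/dt = u(x, t)` on a stored tetrahedral
#' field: per step the host element is located through the search boxes, the
#' velocity (and velocity gradient) is interpolated and recorded, particles
#' crossing outlets are retired with exit status `"outlet"`, and wall
#' crossings are reflected specularly.
#'
#' @param field a [tet_flow_field()] (run [project_gradients()] and, for
#'   unsteady fields, [fourier_series()] first).
#' @param x0 initial positions, `n x 3`.
#' @param dt step size, s (default 5e-5).
#' @param t_end tracking horizon, s (default 3 periods).
#' @param t0 release time, s.
#' @param record_stride store every k-th sample (default 1).
#' @param index optional prebuilt [build_search_index()].
#' @param record `"full"` (positions, velocities, gradients) or `"summary"`
#'   (shear-rate histories only).
#' @return an object of class `particle_trajectories`: list with the tidy
#'   `history` tibble (particle, time, position, velocity, `gdot`, and
#'   gradient columns g11..g33 for `record = "full"`) and a `particles`
#'   tibble (exit status, exit time).
#' @export
advect <- function(field, x0, dt = 5e-5, t_end = 3 * field$period, t0 = 0,
                   record_stride = 1L, index = NULL,
                   record = c("full", "summary")) {
  record <- match.arg(record)
  stopifnot(inherits(field, "tet_flow_field"), dt > 0)
  if (is.null(field$gradients)) field <- project_gradients(field)
  steady <- length(field$frames) == 1L
  if (!steady && is.null(field$fourier)) field <- fourier_series(field)
  if (is.null(index)) index <- build_search_index(field)
  bs <- boundary_structures(field)
  x <- matrix(as.numeric(x0), ncol = 3L)
  n <- nrow(x)
  host <- locate_host(x, index)
  host[is.na(host)] <- 0L
  host <- as.integer(host)
  status <- integer(n)
  status[host == 0L] <- 2L
  nsteps <- max(1L, round((t_end - t0) / dt))
  nrec <- length(seq(0L, nsteps - 1L, by = record_stride))
  hist_list <- vector("list", nrec)
  exit_time <- rep(NA_real_, n)
  ri <- 0L
  # the advection kernel updates pos/host/status in place: deep-copy the
  # caller's matrix so x0 is never mutated
  pos <- x + 0
  for (k in seq_len(nsteps)) {
    t <- t0 + (k - 1L) * dt
    u_nodal <- if (steady) field$frames[[1]] else evaluate_time(field, t)
    g_nodal <- if (steady) field$gradients[[1]] else evaluate_time(field, t, "gradient")
    prev_status <- status + 0L
    pos_rec <- pos + 0 # positions at time t, before the in-place update
    st <- advect_step_cpp(pos, host, status, u_nodal, g_nodal,
                          field$nodes, index$tets0, index$tinv, index$ptr,
                          index$elems, index$nb, index$lo, index$hi,
                          bs$wall_faces, bs$wn_ptr, bs$wn_faces,
                          bs$wall_node_ids, bs$outlet_faces, dt, 1e-12,
                          TRUE)
    newly_exited <- which(prev_status == 0L & status != 0L)
    exit_time[newly_exited] <- t + dt
    if ((k - 1L) %% record_stride == 0L) {
      ri <- ri + 1L
      act <- which(prev_status == 0L)
      if (record == "full") {
        hist_list[[ri]] <- tibble::tibble(
          particle = act, time = t,
          x = pos_rec[act, 1], y = pos_rec[act, 2], z = pos_rec[act, 3],
          ux = st$vel[act, 1], uy = st$vel[act, 2], uz = st$vel[act, 3],
          gdot = sqrt(rowSums(st$grad[act, , drop = FALSE]^2)),
          g11 = st$grad[act, 1], g12 = st$grad[act, 2], g13 = st$grad[act, 3],
          g21 = st$grad[act, 4], g22 = st$grad[act, 5], g23 = st$grad[act, 6],
          g31 = st$grad[act, 7], g32 = st$grad[act, 8], g33 = st$grad[act, 9]
        )
      } else {
        hist_list[[ri]] <- tibble::tibble(
          particle = act, time = t,
          gdot = sqrt(rowSums(st$grad[act, , drop = FALSE]^2))
        )
      }
    }
    if (all(status != 0L)) break
  }
  history <- dplyr::bind_rows(hist_list[seq_len(ri)])
  particles <- tibble::tibble(
    particle = seq_len(n),
    exit_status = c("active", "outlet", "frozen")[status + 1L],
    exit_time = exit_time
  )
  structure(list(history = history, particles = particles, dt = dt,
                 t0 = t0, t_end = t_end, field_period = field$period),
            class = "particle_trajectories")
}

#' @export
print.particle_trajectories <- function(x, ...) {
  tab <- table(x$particles$exit_status)
  cat(sprintf("<particle_trajectories> %d particles, %d samples; %s\n",
              nrow(x$particles), nrow(x$history),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
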