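# Background flow fields queried by the particle tracker: analytic flows and
# stored time-periodic fields on tetrahedral meshes with Fourier temporal
# reconstruction and continuous (L2-projected) nodal velocity gradients.

#' Tetrahedral flow field
#'
#' A tetrahedral mesh with labelled boundary faces and per-node velocity
#' frames sampled uniformly over one period.
#'
#' @param nodes numeric matrix `n x 3` of node positions, m.
#' @param tets integer matrix `m x 4` of 1-based connectivity.
#' @param boundary data frame with columns `n1`, `n2`, `n3` (1-based node
#'   ids) and `label` (one of `"inlet"`, `"outlet"`, `"wall"`).
#' @param frames list of `n x 3` velocity matrices (m/s), one per uniformly
#'   spaced sample time over the period; a single frame denotes steady flow.
#' @param period period T, s (ignored for steady fields).
#' @return an object of class `tet_flow_field`.
#' @export
tet_flow_field <- function(nodes, tets, boundary, frames, period = 1) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L)
  if (!is.data.frame(boundary) ||
      !all(c("n1", "n2", "n3", "label") %in% names(boundary))) {
    stop("`boundary` needs columns n1, n2, n3, label", call. = FALSE)
  }
  bad <- setdiff(unique(boundary$label), c("inlet", "outlet", "wall"))
  if (length(bad)) {
    stop("unknown boundary labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"
    stopifnot(nrow(f) == nrow(nodes), ncol(f) == 3L)
    f
  })
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) {
    stop(sprintf("%d inverted (non-positive volume) tetrahedra", sum(vol <= 0)),
         call. = FALSE)
  }
  structure(
    list(nodes = nodes, tets = tets, boundary = boundary, frames = frames,
         period = period, volumes = vol, gradients = NULL, index = NULL,
         fourier = NULL),
    class = "tet_flow_field"
  )
}

#' @export
print.tet_flow_field <- function(x, ...) {
  cat(sprintf("<tet_flow_field> %d nodes, %d tets, %d frame(s), period %.3g s\n",
              nrow(x$nodes), nrow(x$tets), length(x$frames), x$period))
  cat("  boundary faces:", paste(sprintf("%s %d", names(table(x$boundary$label)),
                                         table(x$boundary$label)), collapse = ", "), "\n")
  invisible(x)
}

# Signed volumes of all tets (positive for right-handed connectivity).
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
     a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Per-element inverse edge matrices (row-major 3x3 per row), used for
# barycentric coordinates and element gradients. Closed-form (adjugate)
# inverse of the column matrix [e1 e2 e3], vectorized over elements.
tet_inverse_matrices <- function(nodes, tets) {
  e1 <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  e2 <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  e3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c23 <- cross_rows(e2, e3); c31 <- cross_rows(e3, e1); c12 <- cross_rows(e1, e2)
  det <- rowSums(e1 * c23)
  # rows of the inverse are the reciprocal vectors
  cbind(c23 / det, c31 / det, c12 / det)
}

#' Continuous nodal velocity gradients by L2 projection
#'
#' Projects the piecewise-constant element velocity gradients of each frame
#' onto a continuous nodal field. The default lumped-mass variant weights
#' incident element gradients by element volume; the consistent-mass variant
#' solves the full linear-FE mass system. Both are exact for globally affine
#' velocity fields.
#'
#' @param field a [tet_flow_field()].
#' @param lumped use the lumped (diagonal) mass matrix (default `TRUE`).
#' @return the field with `gradients` filled: a list (one per frame) of
#'   `n x 9` matrices, row-major `du_i/dx_j` (g11, g12, g13, g21, ...), 1/s.
#' @export
project_gradients <- function(field, lumped = TRUE) {
  stopifnot(inherits(field, "tet_flow_field"))
  nodes <- field$nodes; tets <- field$tets
  M <- nrow(tets); n <- nrow(nodes)
  tinv <- field_tinv(field)
  vol <- field$volumes
  idx <- as.vector(tets)                      # 4M node incidences
  wts <- rep(vol, 4L)
  denom_full <- numeric(n)
  ds <- rowsum(wts, idx)
  denom_full[as.integer(rownames(ds))] <- ds[, 1]
  # grad u (3x3) per element: du_i/dx_j = sum_v u_i(v) dN_v/dx_j
  # dN/dx of vertices 2..4 are the rows of tinv; vertex 1 is minus their sum.
  field$gradients <- lapply(field$frames, function(u) {
    ge <- matrix(0, M, 9)
    u1 <- u[tets[, 1], , drop = FALSE]; u2 <- u[tets[, 2], , drop = FALSE]
    u3 <- u[tets[, 3], , drop = FALSE]; u4 <- u[tets[, 4], , drop = FALSE]
    d2 <- u2 - u1; d3 <- u3 - u1; d4 <- u4 - u1
    for (i in 1:3) for (j in 1:3) {
      # du_i/dx_j = sum_k dcoef_k,i * tinv[, (k-1)*3 + j]
      ge[, (i - 1) * 3 + j] <- d2[, i] * tinv[, j] + d3[, i] * tinv[, 3 + j] +
        d4[, i] * tinv[, 6 + j]
    }
    if (lumped) {
      gn <- matrix(0, n, 9)
      num <- rowsum(ge[rep(seq_len(M), 4L), , drop = FALSE] * wts, idx)
      rid <- as.integer(rownames(num))
      gn[rid, ] <- num / denom_full[rid]
      gn
    } else {
      # consistent linear-FE mass matrix (same for every component)
      trip_i <- integer(16L * M); trip_j <- integer(16L * M); trip_x <- numeric(16L * M)
      pos <- 0L
      for (e in seq_len(M)) {
        vids <- tets[e, ]
        Me <- (vol[e] / 20) * (matrix(1, 4, 4) + diag(4))
        for (aa in 1:4) for (bb in 1:4) {
          pos <- pos + 1L
          trip_i[pos] <- vids[aa]; trip_j[pos] <- vids[bb]; trip_x[pos] <- Me[aa, bb]
        }
      }
      Mass <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(n, n))
      rhs <- matrix(0, n, 9)
      for (cmp in 1:9) {
        num <- tapply(rep(ge[, cmp], 4L) * wts / 4, idx, sum)
        rhs[as.integer(names(num)), cmp] <- as.vector(num)
      }
      as.matrix(Matrix::solve(Mass, rhs))
    }
  })
  field
}

field_tinv <- function(field) {
  tet_inverse_matrices(field$nodes, field$tets)
}

#' Fourier series of a periodic flow field
#'
#' Per-node complex Fourier coefficients of each velocity component (and of
#' the projected gradients when present) over the stored period. The inverse
#' transform reproduces the frames at the sample times to round-off.
#'
#' @param field a [tet_flow_field()] with `Nf >= 2` frames.
#' @return the field with a `fourier` element used by [evaluate_time()].
#' @export
fourier_series <- function(field) {
  stopifnot(inherits(field, "tet_flow_field"))
  Nf <- length(field$frames)
  if (Nf < 2L) stop("need at least 2 frames for a Fourier series", call. = FALSE)
  pack <- function(frames) {
    X <- do.call(cbind, lapply(frames, as.vector)) # (3n or 9n) x Nf
    t(stats::mvfft(t(X))) / Nf                     # coefficients, same shape
  }
  field$fourier <- list(
    Nf = Nf, n = nrow(field$nodes), u = pack(field$frames),
    grad = if (!is.null(field$gradients)) pack(field$gradients) else NULL
  )
  field
}

# Trigonometric interpolation weights at time t for Nf uniform samples over
# period T (even Nyquist handled as a pure cosine).
trig_weights <- function(Nf, Tper, t) {
  tau <- 2 * pi * (t / Tper)
  k <- 0:(Nf - 1L)
  kk <- ifelse(k <= Nf / 2, k, k - Nf)
  w <- exp(1i * kk * tau)
  if (Nf %% 2L == 0L) {
    ny <- Nf / 2 + 1L
    w[ny] <- cos(Nf / 2 * tau)
  }
  w
}

#' Evaluate a periodic field at an arbitrary time
#'
#' Trigonometric interpolation using all retained Fourier modes; exact at
#' the sample times and periodic: `evaluate_time(f, t) == evaluate_time(f,
#' t + T)`.
#'
#' @param field a [fourier_series()]-processed field.
#' @param t time, s (any real value; periodic extension).
#' @param what `"velocity"` or `"gradient"`.
#' @return `n x 3` velocities (m/s) or `n x 9` gradients (1/s).
#' @export
evaluate_time <- function(field, t, what = c("velocity", "gradient")) {
  what <- match.arg(what)
  if (is.null(field$fourier)) {
    if (length(field$frames) == 1L) {
      return(if (what == "velocity") field$frames[[1]]
             else field$gradients[[1]])
    }
    stop("call fourier_series() first", call. = FALSE)
  }
  fo <- field$fourier
  w <- trig_weights(fo$Nf, field$period, t)
  src <- if (what == "velocity") fo$u else {
    if (is.null(fo$grad)) stop("gradients not projected before fourier_series()", call. = FALSE)
    fo$grad
  }
  vals <- Re(src %*% w)
  matrix(vals, nrow = fo$n)
}

#' Analytic background flows
#'
#' Divergence-free closed-form flows: `simple_shear` (`du1/dx2 = gdot`),
#' `poiseuille` (axis-aligned Hagen-Poiseuille in a pipe of radius `R`,
#' centreline speed `Umax`), `planar_extension` (rate `edot`, stretching
#' along x, compressing along y), and `uniform`.
#'
#' @param kind flow type.
#' @param gdot shear rate, 1/s (`simple_shear`).
#' @param R pipe radius, m; `Umax` centreline speed, m/s; `axis` flow axis
#'   (3-vector, default z) (`poiseuille`).
#' @param edot extension rate, 1/s (`planar_extension`).
#' @param U uniform velocity (3-vector, m/s).
#' @return an object of class `analytic_flow`.
#' @export
analytic_flow <- function(kind = c("simple_shear", "poiseuille",
                                   "planar_extension", "uniform"),
                          gdot = NULL, R = NULL, Umax = NULL,
                          axis = c(0, 0, 1), edot = NULL, U = NULL) {
  kind <- match.arg(kind)
  pars <- switch(kind,
    simple_shear = { stopifnot(is.numeric(gdot)); list(gdot = gdot) },
    poiseuille = {
      stopifnot(is.numeric(R), R > 0, is.numeric(Umax))
      list(R = R, Umax = Umax, axis = axis / sqrt(sum(axis^2)))
    },
    planar_extension = { stopifnot(is.numeric(edot)); list(edot = edot) },
    uniform = { stopifnot(length(U) == 3L); list(U = as.numeric(U)) }
  )
  structure(c(list(kind = kind), pars), class = "analytic_flow")
}

#' Velocity of a flow at given positions
#'
#' Closed forms for [analytic_flow()]s; barycentric interpolation of nodal
#' values in the host element for [tet_flow_field()]s (points outside the
#' mesh yield `NA` rows).
#'
#' @param flow an [analytic_flow()] or [tet_flow_field()].
#' @param x positions, `n x 3` matrix, m.
#' @param t time, s.
#' @return `n x 3` velocity matrix, m/s.
#' @export
velocity_at <- function(flow, x, t = 0) UseMethod("velocity_at")

#' Velocity gradient of a flow at given positions
#'
#' @inheritParams velocity_at
#' @return `n x 9` matrix of row-major gradient tensors, 1/s.
#' @export
gradient_at <- function(flow, x, t = 0) UseMethod("gradient_at")

#' @export
velocity_at.analytic_flow <- function(flow, x, t = 0) {
  x <- matrix(as.numeric(x), ncol = 3L)
  n <- nrow(x)
  switch(flow$kind,
    simple_shear = cbind(flow$gdot * x[, 2], numeric(n), numeric(n)),
    poiseuille = {
      ax <- flow$axis
      xp <- x - outer(drop(x %*% ax), ax)
      r2 <- rowSums(xp^2)
      outer(flow$Umax * pmax(1 - r2 / flow$R^2, 0), ax)
    },
    planar_extension = cbind(flow$edot * x[, 1], -flow$edot * x[, 2], numeric(n)),
    uniform = matrix(flow$U, n, 3, byrow = TRUE)
  )
}

#' @export
gradient_at.analytic_flow <- function(flow, x, t = 0) {
  x <- matrix(as.numeric(x), ncol = 3L)
  n <- nrow(x)
  g <- matrix(0, n, 9)
  switch(flow$kind,
    simple_shear = { g[, 2] <- flow$gdot },
    poiseuille = {
      ax <- flow$axis
      xp <- x - outer(drop(x %*% ax), ax)
      # du_i/dx_j = -2 Umax/R^2 * ax_i * xp_j
      for (i in 1:3) for (j in 1:3) {
        g[, (i - 1) * 3 + j] <- -2 * flow$Umax / flow$R^2 * ax[i] * xp[, j]
      }
    },
    planar_extension = { g[, 1] <- flow$edot; g[, 5] <- -flow$edot },
    uniform = NULL
  )
  g
}

#' @export
velocity_at.tet_flow_field <- function(flow, x, t = 0) {
  interp_field(flow, x, t, "velocity")
}

#' @export
gradient_at.tet_flow_field <- function(flow, x, t = 0) {
  interp_field(flow, x, t, "gradient")
}

interp_field <- function(field, x, t, what) {
  x <- matrix(as.numeric(x), ncol = 3L)
  idx <- build_search_index(field)
  hosts <- locate_host(x, idx)
  nodal <- if (length(field$frames) == 1L && what == "velocity") field$frames[[1]]
    else if (length(field$frames) == 1L) {
      if (is.null(field$gradients)) stop("call project_gradients() first", call. = FALSE)
      field$gradients[[1]]
    } else evaluate_time(field, t, what)
  out <- matrix(NA_real_, nrow(x), ncol(nodal))
  ok <- which(hosts > 0L)
  for (i in ok) {
    e <- hosts[i]
    vids <- field$tets[e, ]
    v0 <- field$nodes[vids[1], ]
    Ti <- matrix(idx$tinv[e, ], 3, 3, byrow = TRUE)
    bc <- drop(Ti %*% (x[i, ] - v0))
    w <- c(1 - sum(bc), bc)
    out[i, ] <- colSums(w * nodal[vids, , drop = FALSE])
  }
  out
}
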