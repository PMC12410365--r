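# Spectral machinery: orthonormal real spherical harmonics on a
# Gauss-Legendre (latitude) x uniform (longitude) collocation lattice.
#
# Coefficient ordering: for l = 0..p, m = 0..l; m = 0 contributes one
# (zonal) entry, m > 0 contributes a cosine entry followed by a sine
# entry, giving (p + 1)^2 coefficients in total.

#' @useDynLib rbcflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = 2 * (e$vectors[1L, idx])^2)
}

# Normalized associated Legendre functions P_l^m (orthonormal over the
# sphere, no Condon-Shortley phase) together with first and second
# theta-derivatives, evaluated at angles theta (must avoid the poles).
# Returns list of three matrices [npts x npairs], pairs ordered (l, m),
# m inner loop 0..l.
alf_tables <- function(p, theta) {
  x <- cos(theta)
  sth <- sin(theta)
  npts <- length(theta)
  npair <- (p + 1L) * (p + 2L) / 2L
  P <- matrix(0, npts, npair)
  pair_idx <- function(l, m) l * (l + 1L) / 2L + m + 1L
  P[, 1L] <- 1 / sqrt(4 * pi)
  if (p >= 1L) {
    for (m in 1:p) { # diagonal P_m^m
      P[, pair_idx(m, m)] <- sqrt((2 * m + 1) / (2 * m)) * sth * P[, pair_idx(m - 1L, m - 1L)]
    }
    for (m in 0:(p - 1L)) {
      P[, pair_idx(m + 1L, m)] <- sqrt(2 * m + 3) * x * P[, pair_idx(m, m)]
    }
    if (p >= 2L) {
      for (l in 2:p) {
        ms <- 0:(l - 2L)
        for (m in ms) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          P[, pair_idx(l, m)] <- a * (x * P[, pair_idx(l - 1L, m)] - b * P[, pair_idx(l - 2L, m)])
        }
      }
    }
  }
  # dP/dtheta: sin(theta) P' = l cos(theta) P_l^m - c_lm P_{l-1}^m
  dP <- matrix(0, npts, npair)
  d2P <- matrix(0, npts, npair)
  for (l in 0:p) {
    for (m in 0:l) {
      j <- pair_idx(l, m)
      if (l == 0L) next
      if (m <= l - 1L) {
        c_lm <- sqrt((l^2 - m^2) * (2 * l + 1) / (2 * l - 1))
        pm1 <- P[, pair_idx(l - 1L, m)]
      } else {
        c_lm <- 0
        pm1 <- 0
      }
      dP[, j] <- (l * x * P[, j] - c_lm * pm1) / sth
    }
  }
  # P'' from differentiating the same relation:
  # P'' = ((l-1) cos(theta) P' - c_lm P'_{l-1}) / sin(theta) - l P
  for (l in 0:p) {
    for (m in 0:l) {
      j <- pair_idx(l, m)
      if (l == 0L) next
      if (m <= l - 1L) {
        c_lm <- sqrt((l^2 - m^2) * (2 * l + 1) / (2 * l - 1))
        dpm1 <- dP[, pair_idx(l - 1L, m)]
      } else {
        c_lm <- 0
        dpm1 <- 0
      }
      d2P[, j] <- ((l - 1) * x * dP[, j] - c_lm * dpm1) / sth - l * P[, j]
    }
  }
  list(P = P, dP = dP, d2P = d2P)
}

# Dense synthesis matrices at arbitrary (theta, phi) points for order p.
# which: subset of c("Y","Dt","Dp","Dtt","Dtp","Dpp").
sh_eval_matrices <- function(p, theta, phi, which = "Y") {
  stopifnot(length(theta) == length(phi))
  npts <- length(theta)
  ncoef <- (p + 1L)^2
  tabs <- alf_tables(p, theta)
  pair_idx <- function(l, m) l * (l + 1L) / 2L + m + 1L
  out <- lapply(which, function(w) matrix(0, npts, ncoef))
  names(out) <- which
  col <- 0L
  for (l in 0:p) {
    for (m in 0:l) {
      j <- pair_idx(l, m)
      Pj <- tabs$P[, j]; dPj <- tabs$dP[, j]; d2Pj <- tabs$d2P[, j]
      sc <- if (m == 0L) 1 else sqrt(2)
      cm <- cos(m * phi); sm <- sin(m * phi)
      nrep <- if (m == 0L) 1L else 2L
      for (k in seq_len(nrep)) {
        col <- col + 1L
        ang <- if (k == 1L) cm else sm
        dang <- if (k == 1L) -m * sm else m * cm
        d2ang <- -m^2 * ang
        if ("Y" %in% which) out$Y[, col] <- sc * Pj * ang
        if ("Dt" %in% which) out$Dt[, col] <- sc * dPj * ang
        if ("Dp" %in% which) out$Dp[, col] <- sc * Pj * dang
        if ("Dtt" %in% which) out$Dtt[, col] <- sc * d2Pj * ang
        if ("Dtp" %in% which) out$Dtp[, col] <- sc * dPj * dang
        if ("Dpp" %in% which) out$Dpp[, col] <- sc * Pj * d2ang
      }
    }
  }
  out
}

# Collocation basis for order p: nlat = p+1 Gauss-Legendre latitudes,
# nlon = 2p+2 uniform longitudes (longitude index runs fastest).
# Cached per (p, derivs) in the package environment.
.sht_cache <- new.env(parent = emptyenv())

sh_grid <- function(p) {
  gl <- gauss_legendre(p + 1L)
  theta_lat <- acos(rev(gl$x)) # decreasing x -> theta increasing from ~0 to ~pi
  w_lat <- rev(gl$w)
  nlon <- 2L * (p + 1L)
  phi_lon <- 2 * pi * (0:(nlon - 1L)) / nlon
  theta <- rep(theta_lat, each = nlon)
  w <- rep(w_lat, each = nlon) * (2 * pi / nlon)
  list(
    p = p, nlat = p + 1L, nlon = nlon,
    theta_lat = theta_lat, w_lat = w_lat, phi_lon = phi_lon,
    theta = theta,
    phi = rep(phi_lon, times = p + 1L),
    w = w,              # solid-angle weights: sum(w * f) ~ integral f dOmega
    wpar = w / sin(theta) # parameter-space weights: integral f dtheta dphi
  )
}

sh_basis <- function(p, derivs = TRUE) {
  key <- paste0("p", p, "_", if (derivs) "d" else "n")
  if (!is.null(.sht_cache[[key]])) return(.sht_cache[[key]])
  g <- sh_grid(p)
  which <- if (derivs) c("Y", "Dt", "Dp", "Dtt", "Dtp", "Dpp") else "Y"
  mats <- sh_eval_matrices(p, g$theta, g$phi, which)
  b <- c(g, mats)
  b$YtW <- t(b$Y * b$w) # analysis operator: coeffs = YtW %*% f
  .sht_cache[[key]] <- b
  b
}

# Basis of order p evaluated on the collocation grid of a (finer) order q,
# with analysis back onto order-p coefficients from that grid. Used for
# de-aliased evaluation of nonlinear terms (upsampling).
sh_resample_basis <- function(p, q, derivs = TRUE) {
  stopifnot(q >= p)
  key <- paste0("rs_p", p, "_q", q, "_", if (derivs) "d" else "n")
  if (!is.null(.sht_cache[[key]])) return(.sht_cache[[key]])
  g <- sh_grid(q)
  which <- if (derivs) c("Y", "Dt", "Dp", "Dtt", "Dtp", "Dpp") else "Y"
  mats <- sh_eval_matrices(p, g$theta, g$phi, which)
  b <- c(g, mats)
  b$p_coeff <- p
  # analysis of a grid function on the order-q lattice onto order-p modes
  b$YtW <- t(b$Y * b$w)
  .sht_cache[[key]] <- b
  b
}

sh_analyze <- function(basis, f) basis$YtW %*% as.matrix(f)

sh_synthesize <- function(basis, C, deriv = "Y") basis[[deriv]] %*% as.matrix(C)

# Degrees (l) associated with each coefficient row, used for filtering.
sh_degrees <- function(p) {
  l <- integer((p + 1L)^2)
  col <- 0L
  for (ll in 0:p) for (m in 0:ll) {
    nrep <- if (m == 0L) 1L else 2L
    for (k in seq_len(nrep)) { col <- col + 1L; l[col] <- ll }
  }
  l
}

# Rotate real SH coefficients so that the rotated expansion, evaluated at a
# point x, equals the original evaluated at Rz(alpha) x.
sh_rotate_z <- function(p, C, alpha) {
  C <- as.matrix(C)
  out <- C
  col <- 0L
  for (l in 0:p) for (m in 0:l) {
    if (m == 0L) { col <- col + 1L; next }
    cma <- cos(m * alpha); sma <- sin(m * alpha)
    ic <- col + 1L; is <- col + 2L
    out[ic, ] <- cma * C[ic, ] + sma * C[is, ]
    out[is, ] <- -sma * C[ic, ] + cma * C[is, ]
    col <- col + 2L
  }
  out
}
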