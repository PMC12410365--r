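# Membrane constitutive models: Skalak in-plane tension and Helfrich
# bending, evaluated pseudo-spectrally with de-aliasing on the upsampled
# lattice. The traction jump across the membrane is
#   delta_f = delta_f_tension + delta_f_bending,
# with delta_f_tension the surface divergence of the Cauchy tension tensor
# and delta_f_bending the variational (shape-equation) Helfrich force.

#' Membrane material parameters
#'
#' Default values are those used for the cell-resolved simulations: shear
#' modulus `G = 6e-5` N/m, dilatation ratio `C = 15`, bending modulus
#' `EB = 0.95e-18` J, spontaneous curvature `c0 = -2/a` 1/m, exterior
#' (whole-blood effective) viscosity `mu = 4e-3` Pa s and interior/exterior
#' viscosity ratio `lambda_visc = 1.5`.
#'
#' @param G membrane shear elastic modulus, N/m.
#' @param C dimensionless dilatation ratio (dilatation modulus over `G`);
#'   values above 10 give converged large-scale dynamics.
#' @param EB bending modulus, J.
#' @param c0 spontaneous curvature, 1/m. Defaults to `-2/a`.
#' @param mu exterior effective viscosity, Pa s.
#' @param lambda_visc interior-to-exterior viscosity ratio.
#' @param a characteristic RBC radius, m (used only for the `c0` default).
#' @param skalak_grouping `"skalak"` (default) uses
#'   \eqn{W_T = (G/4)(I_1^2 + 2 I_1 - 2 I_2 + C I_2^2)}; `"literal"` places
#'   the dilatation term outside the `G/4` factor, in which case `C` is read
#'   in N/m.
#' @return an object of class `membrane_material`.
#' @export
membrane_material <- function(G = 6e-5, C = 15, EB = 0.95e-18,
                              c0 = -2 / a, mu = 4e-3, lambda_visc = 1.5,
                              a = 2.82e-6,
                              skalak_grouping = c("skalak", "literal")) {
  skalak_grouping <- match.arg(skalak_grouping)
  if (G <= 0) stop("G must be positive", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  if (C <= 10) warning("dilatation ratios C <= 10 are below the converged range")
  if (EB < 0) stop("EB must be non-negative", call. = FALSE)
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (lambda_visc <= 0) stop("lambda_visc must be positive", call. = FALSE)
  structure(list(G = G, C = C, EB = EB, c0 = c0, mu = mu,
                 lambda_visc = lambda_visc, skalak_grouping = skalak_grouping),
            class = "membrane_material")
}

#' @export
print.membrane_material <- function(x, ...) {
  cat(sprintf("<membrane_material> G=%.3g N/m, C=%.3g, EB=%.3g J, c0=%.3g 1/m, mu=%.3g Pa s, lambda=%.3g\n",
              x$G, x$C, x$EB, x$c0, x$mu, x$lambda_visc))
  invisible(x)
}

# In-plane strain measures of `surface` relative to `reference` on the
# order-q lattice: right Cauchy-Green relative metric g0^{-1} g.
strain_fields <- function(surface, reference, q = surface$order) {
  g <- surface_geometry(surface, q = q, second = FALSE)
  m0 <- reference_metric(reference, q)
  det0 <- m0$E * m0$G - m0$F^2
  detg <- g$E * g$G - g$F^2
  tr <- (m0$G * g$E - 2 * m0$F * g$F + m0$E * g$G) / det0
  I1 <- tr - 2
  I2 <- detg / det0 - 1
  Js <- sqrt(pmax(detg / det0, 0))
  # lambda^2 are roots of x^2 - (I1+2) x + (I2+1)
  s <- I1 + 2
  disc <- pmax(s^2 - 4 * (I2 + 1), 0)
  l1sq <- (s + sqrt(disc)) / 2
  l2sq <- (s - sqrt(disc)) / 2
  list(geom = g, ref = m0, det0 = det0, detg = detg,
       I1 = I1, I2 = I2, Js = Js,
       lambda1 = sqrt(pmax(l1sq, 0)), lambda2 = sqrt(pmax(l2sq, 0)))
}

#' Principal membrane stretches
#'
#' Principal stretches of the deformed surface relative to the oblate
#' reference configuration, per collocation point.
#'
#' @param surface an [sh_surface()].
#' @param reference an [make_reference()] configuration sharing the same
#'   (theta, phi) material parameterization.
#' @param q lattice order on which to evaluate (defaults to the surface
#'   order).
#' @return an object of class `strain_state`: a list with per-point
#'   `lambda1 >= lambda2`, invariants `I1 = l1^2 + l2^2 - 2`,
#'   `I2 = l1^2 l2^2 - 1`, `areal_strain = l1 l2`, and
#'   `shear_strain = l1/l2`, plus area weights for surface averages.
#' @export
principal_stretches <- function(surface, reference, q = surface$order) {
  if (!inherits(surface, "sh_surface")) stop("`surface` must be an sh_surface", call. = FALSE)
  if (!inherits(reference, "rbc_reference")) {
    stop("`reference` must be an rbc_reference sharing the surface lattice", call. = FALSE)
  }
  sf <- strain_fields(surface, reference, q)
  b <- sf$geom$basis
  structure(
    list(lambda1 = sf$lambda1, lambda2 = sf$lambda2,
         I1 = sf$I1, I2 = sf$I2,
         areal_strain = sf$lambda1 * sf$lambda2,
         shear_strain = sf$lambda1 / sf$lambda2,
         area_weight = b$wpar * sf$geom$W,
         q = q),
    class = "strain_state"
  )
}

#' @export
print.strain_state <- function(x, ...) {
  cat(sprintf("<strain_state> %d points; areal strain [%.3f, %.3f]; shear strain [%.3f, %.3f]\n",
              length(x$lambda1), min(x$areal_strain), max(x$areal_strain),
              min(x$shear_strain), max(x$shear_strain)))
  invisible(x)
}

#' Skalak strain-energy density
#'
#' \eqn{W_T = (G/4)(I_1^2 + 2 I_1 - 2 I_2 + C I_2^2)} (default grouping),
#' energy per unit undeformed area, J/m^2.
#'
#' @param strain a [principal_stretches()] result (or any list with `I1`,
#'   `I2`).
#' @param material a [membrane_material()].
#' @return numeric vector of energy densities per point.
#' @export
skalak_energy_density <- function(strain, material) {
  I1 <- strain$I1; I2 <- strain$I2
  if (material$skalak_grouping == "skalak") {
    (material$G / 4) * (I1^2 + 2 * I1 - 2 * I2 + material$C * I2^2)
  } else {
    (material$G / 4) * (I1^2 + 2 * I1 - 2 * I2) + material$C * I2^2
  }
}

# Contravariant Cauchy tension components tau^{ab} of the Skalak law:
# tau = (G/Js)(I1+1) g0^{-1} + G Js (C I2 - 1) g^{-1}
# (per-point 2x2, symmetric), derived from the invariant form of the
# strain energy. For the "literal" grouping the dilatational coefficient
# becomes Js (2 C I2 / G' ...) handled via an effective C.
skalak_tension_contravariant <- function(sf, material) {
  G <- material$G
  Ceff <- if (material$skalak_grouping == "skalak") material$C else 4 * material$C / G
  coefA <- (G / sf$Js) * (sf$I1 + 1)
  coefB <- G * sf$Js * (Ceff * sf$I2 - 1)
  m0 <- sf$ref; g <- sf$geom
  # inverse metrics: [G,-F;-F,E]/det
  list(
    t11 = coefA * m0$G / sf$det0 + coefB * g$G / sf$detg,
    t12 = coefA * (-m0$F) / sf$det0 + coefB * (-g$F) / sf$detg,
    t22 = coefA * m0$E / sf$det0 + coefB * g$E / sf$detg
  )
}

# Mass-matrix style mapping from a coefficient-space energy gradient to a
# pointwise traction density on the base lattice: delta_f solves
#   Y' diag(wpar W) delta_f = gradE,   delta_f = diag(1/(wpar W)) Y B.
#
# Sign convention: delta_f is the jump in fluid traction across the
# membrane, which balances the internal membrane load (delta_f = -p); it
# therefore equals the +variational derivative of the elastic energy with
# respect to the surface map, delta_f = dE/dx per unit current area. An
# inflated sphere has an outward, Laplace-law tension traction, and the
# relaxation flow driven through the (negative-signed) single-layer term of
# the boundary-integral equation is dissipative.
grad_to_traction <- function(surface, gradE) {
  p <- surface$order
  key <- paste0("minv_p", p)
  if (is.null(.sht_cache[[key]])) {
    bp <- sh_basis(p)
    .sht_cache[[key]] <- solve(crossprod(bp$Y))
  }
  bp <- sh_basis(p)
  gb <- surface_geometry(surface, q = p, second = FALSE)
  B <- .sht_cache[[key]] %*% gradE
  (bp$Y %*% B) / (gb$basis$wpar * gb$W)
}

# Analytic gradient of the discrete Skalak tension energy
#   E_T(C) = sum_k wpar_k W0_k W_T(I1_k, I2_k)
# with respect to the surface coefficients C, evaluated on the order-q
# (de-aliased) lattice. Exact: the tension traction derived from it is the
# negative variational derivative of the discrete energy by construction.
skalak_energy_gradient <- function(surface, reference, material,
                                   q = upsampled_order(surface)) {
  sf <- strain_fields(surface, reference, q)
  g <- sf$geom; m0 <- sf$ref
  bq <- g$basis
  Gm <- material$G
  Ceff <- if (material$skalak_grouping == "skalak") material$C else 4 * material$C / Gm
  W0 <- sqrt(sf$det0)
  a_k <- bq$wpar * W0
  dW_dI1 <- (Gm / 4) * (2 * sf$I1 + 2)
  dW_dI2 <- (Gm / 4) * (-2 + 2 * Ceff * sf$I2)
  # I1 = (G0 E - 2 F0 F + E0 G)/det0 - 2 ; I2 = (E G - F^2)/det0 - 1
  dE_ <- a_k * (dW_dI1 * m0$G / sf$det0 + dW_dI2 * g$G / sf$det0)
  dF_ <- a_k * (dW_dI1 * (-2 * m0$F) / sf$det0 + dW_dI2 * (-2 * g$F) / sf$det0)
  dG_ <- a_k * (dW_dI1 * m0$E / sf$det0 + dW_dI2 * g$E / sf$det0)
  crossprod(bq$Dt, 2 * dE_ * g$xt + dF_ * g$xp) +
    crossprod(bq$Dp, dF_ * g$xt + 2 * dG_ * g$xp)
}

#' Skalak tension traction
#'
#' In-plane elastic traction jump of the Skalak law: the variational
#' derivative of the de-aliased discrete tension energy with respect to the
#' surface map (virtual-work construction), returned as a pointwise density
#' on the base lattice. This is the jump in fluid traction balancing the
#' membrane's internal load, equal to minus the surface divergence of the
#' Skalak Cauchy tension tensor (an inflated sphere carries an outward,
#' Laplace-law normal traction); it vanishes identically when the surface
#' coincides with the reference spheroid.
#'
#' @inheritParams principal_stretches
#' @param material a [membrane_material()].
#' @return matrix (base lattice points x 3), N/m^2.
#' @export
tension_traction <- function(surface, reference, material) {
  gradE <- skalak_energy_gradient(surface, reference, material)
  grad_to_traction(surface, gradE)
}

# Laplace-Beltrami of a scalar with order-p coefficients fC, evaluated with
# de-aliasing on the order-q lattice and returned on the base lattice.
surface_laplacian <- function(surface, fC, q = upsampled_order(surface)) {
  g <- surface_geometry(surface, q = q, second = FALSE)
  bq <- g$basis
  ft <- bq$Dt %*% fC
  fp <- bq$Dp %*% fC
  v1 <- (g$G * ft - g$F * fp) / g$W
  v2 <- (g$E * fp - g$F * ft) / g$W
  C1 <- bq$YtW %*% v1
  C2 <- bq$YtW %*% v2
  bp <- sh_basis(surface$order)
  gb <- surface_geometry(surface, q = surface$order, second = FALSE)
  (bp$Dt %*% C1 + bp$Dp %*% C2) / gb$W
}

#' Helfrich bending traction
#'
#' Variational force density of the Helfrich energy
#' \eqn{W_B = (E_B/2) \int (2\kappa - c_0)^2 dS} for a closed surface:
#' \deqn{\Delta f_B = E_B [ 2 \Delta_s \kappa +
#'   (2\kappa - c_0)(2\kappa^2 + c_0 \kappa - 2 K) ] n,}
#' with mean curvature \eqn{\kappa} (sphere positive), Gaussian curvature K
#' and outward normal n. Zero for a sphere of radius R when `c0 = 2/R`.
#'
#' @inheritParams tension_traction
#' @return matrix (base lattice points x 3), N/m^2.
#' @export
bending_traction <- function(surface, material) {
  EB <- material$EB
  if (EB == 0) {
    n <- (surface$order + 1L) * (2L * surface$order + 2L)
    return(matrix(0, n, 3))
  }
  gradE <- helfrich_energy_gradient(surface, material)
  grad_to_traction(surface, gradE)
}

# Analytic gradient of the discrete Helfrich energy
#   E_B(C) = (EB/2) sum_k wpar_k W_k (2 kappa_k - c0)^2
# with respect to the surface coefficients (adjoint of the curvature
# evaluation through the first/second fundamental forms).
helfrich_energy_gradient <- function(surface, material,
                                     q = upsampled_order(surface)) {
  g <- surface_geometry(surface, q = q, second = TRUE)
  b <- g$basis
  EB <- material$EB; c0 <- material$c0
  w <- b$wpar
  kap <- g$kappa
  dev <- 2 * kap - c0
  P1 <- 2 * w * EB * dev * g$W       # multiplies d(kappa)
  P2 <- (w * EB / 2) * dev^2         # multiplies dW
  qS <- -P1 / (2 * g$W^2)
  qW <- P2 - 2 * kap * P1 / g$W
  u1 <- g$xt; u2 <- g$xp; n <- g$normal
  L <- g$II$L; M <- g$II$M; N2 <- g$II$N
  h <- qS * (g$G * g$xtt - 2 * g$F * g$xtp + g$E * g$xpp)
  hn <- rowSums(h * n)
  r <- (h - hn * n) / g$W + qW * n
  cross3 <- function(a, b2) {
    cbind(a[, 2] * b2[, 3] - a[, 3] * b2[, 2],
          a[, 3] * b2[, 1] - a[, 1] * b2[, 3],
          a[, 1] * b2[, 2] - a[, 2] * b2[, 1])
  }
  alpha <- 2 * qS * N2 * u1 - 2 * qS * M * u2 + cross3(u2, r)
  beta <- -2 * qS * M * u1 + 2 * qS * L * u2 + cross3(r, u1)
  crossprod(b$Dt, alpha) + crossprod(b$Dp, beta) +
    crossprod(b$Dtt, qS * g$G * n) +
    crossprod(b$Dtp, -2 * qS * g$F * n) +
    crossprod(b$Dpp, qS * g$E * n)
}

#' Total membrane traction jump
#'
#' Sum of the Skalak tension and Helfrich bending tractions on the base
#' lattice.
#'
#' @inheritParams tension_traction
#' @return an object of class `traction_jump`: list with `delta_f`,
#'   `tension_part`, `bending_part` (matrices, N/m^2).
#' @export
traction_jump <- function(surface, reference, material) {
  tp <- tension_traction(surface, reference, material)
  bp <- bending_traction(surface, material)
  structure(list(delta_f = tp + bp, tension_part = tp, bending_part = bp),
            class = "traction_jump")
}

# Total elastic energy (tension per reference area + bending per current
# area); used in energy-consistency checks and relaxation monitoring.
membrane_energy <- function(surface, reference, material) {
  q <- upsampled_order(surface)
  sf <- strain_fields(surface, reference, q)
  wpar <- sf$geom$basis$wpar
  W0 <- sqrt(sf$det0)
  ET <- sum(wpar * W0 * skalak_energy_density(sf, material))
  gq <- surface_geometry(surface, q = q, second = TRUE)
  EBend <- (material$EB / 2) * sum(wpar * gq$W * (2 * gq$kappa - material$c0)^2)
  c(tension = ET, bending = EBend, total = ET + EBend)
}
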