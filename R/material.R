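#' Guard-cell wall material (transversely isotropic Veronda-Westmann)
#'
#' The wall matrix is an uncoupled, strain-stiffening hyperelastic solid with
#' isochoric energy
#' \deqn{W_m = C_1 (e^{C_2(\tilde I_1 - 3)} - 1) - \tfrac{C_1 C_2}{2}(\tilde I_2 - 3)}
#' written in the isochoric invariants of the distortional left Cauchy-Green
#' tensor.  A single family of fibers (the circumferential cellulose microfibril
#' direction) adds a tension-only quadratic energy with stiffness `C5`, and a
#' volumetric penalty \eqn{U(J) = \tfrac{K}{2}(\ln J)^2} enforces
#' near-incompressibility.  For small strains the matrix Young's modulus is
#' \eqn{E = 3 C_1 C_2}.
#'
#' Units: stresses and moduli in MPa throughout (`C2` is dimensionless).
#'
#' @param C1 matrix stress scale, MPa (> 0).
#' @param C2 dimensionless nonlinearity (> 0).
#' @param C5 fiber stiffness, MPa (>= 0); fibers carry load only in tension.
#' @param K_bulk bulk modulus, MPa.  Default 1e4 (10 GPa), which keeps the
#'   material nearly incompressible; must be at least `100 * 3 * C1 * C2`.
#' @return An object of class `wall_material`.
#' @export
wall_material <- function(C1, C2, C5 = 0, K_bulk = 1e4) {
  stopifnot(is.numeric(C1), is.numeric(C2), is.numeric(C5), is.numeric(K_bulk))
  if (C1 <= 0) stop("C1 must be > 0")
  if (C2 <= 0) stop("C2 must be > 0")
  if (C5 < 0) stop("C5 must be >= 0")
  if (K_bulk < 100 * 3 * C1 * C2) {
    stop("K_bulk must be >= 100 * (3*C1*C2) for near-incompressibility; got ",
         K_bulk, " vs required ", 100 * 3 * C1 * C2)
  }
  structure(list(C1 = C1, C2 = C2, C5 = C5, K_bulk = K_bulk),
            class = "wall_material")
}

#' @export
print.wall_material <- function(x, ...) {
  cat("Veronda-Westmann wall material (transversely isotropic)\n")
  cat(sprintf("  C1 = %g MPa, C2 = %g, C5 = %g MPa, K = %g MPa\n",
              x$C1, x$C2, x$C5, x$K_bulk))
  cat(sprintf("  small-strain matrix modulus E = 3*C1*C2 = %g MPa\n",
              small_strain_modulus(x)))
  invisible(x)
}

#' Kinematic state at a material point
#'
#' Wraps a deformation gradient `F` and reference fiber direction `a0` and
#' precomputes the quantities the constitutive law needs: `J = det(F)`, the
#' isochoric invariants `I1_bar`, `I2_bar` of the distortional left
#' Cauchy-Green tensor, and the distortional fiber stretch `lambda_bar`.
#'
#' @param F 3x3 deformation gradient (dimensionless); `det(F) > 0`.
#' @param a0 reference fiber direction, normalized internally.
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(F, a0 = c(1, 0, 0)) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)), length(a0) == 3)
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("invalid deformation: det(F) = ", J, " must be > 0")
  }
  a0 <- a0 / sqrt(sum(a0^2))
  B  <- F %*% t(F)
  Bbar <- J^(-2 / 3) * B
  I1 <- sum(diag(Bbar))
  I2 <- (I1^2 - sum(diag(Bbar %*% Bbar))) / 2
  w  <- drop(F %*% a0)
  lam_bar <- J^(-1 / 3) * sqrt(sum(w^2))
  structure(list(F = F, a0 = a0, J = J, Bbar = Bbar,
                 I1_bar = I1, I2_bar = I2, lambda_bar = lam_bar,
                 fiber_deformed = w / sqrt(sum(w^2))),
            class = "deformation_state")
}

#' Strain-energy density
#'
#' @param state a [deformation_state()].
#' @param mat a [wall_material()].
#' @return Energy per unit reference volume, MPa (zero at the identity).
#' @export
strain_energy <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"), inherits(mat, "wall_material"))
  W_mat <- mat$C1 * (exp(mat$C2 * (state$I1_bar - 3)) - 1) -
    (mat$C1 * mat$C2 / 2) * (state$I2_bar - 3)
  lb <- state$lambda_bar
  W_fib <- if (lb > 1) 0.5 * mat$C5 * (lb - 1)^2 else 0
  W_vol <- 0.5 * mat$K_bulk * log(state$J)^2
  W_mat + W_fib + W_vol
}

#' Cauchy stress
#'
#' Deviatoric matrix part from the isochoric invariants, a purely deviatoric
#' tension-only fiber term along the deformed fiber direction, and a
#' volumetric pressure `K * ln(J) / J`.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress <- function(state, mat) {
  stopifnot(inherits(state, "deformation_state"), inherits(mat, "wall_material"))
  J  <- state$J
  Bb <- state$Bbar
  W1 <- mat$C1 * mat$C2 * exp(mat$C2 * (state$I1_bar - 3))
  W2 <- -mat$C1 * mat$C2 / 2
  S  <- (W1 + state$I1_bar * W2) * Bb - W2 * (Bb %*% Bb)
  sig <- (2 / J) * .dev3(S)
  lb <- state$lambda_bar
  if (mat$C5 > 0 && lb > 1) {
    ahat <- state$fiber_deformed
    sig <- sig + (lb / J) * (mat$C5 * (lb - 1)) * .dev3(outer(ahat, ahat))
  }
  sig <- sig + (mat$K_bulk * log(J) / J) * diag(3)
  (sig + t(sig)) / 2
}

#' Small-strain Young's modulus of the wall matrix
#'
#' @param mat a [wall_material()].
#' @return `3 * C1 * C2` in MPa, the small-strain Young's modulus of the
#'   isotropic matrix (fibers excluded).
#' @export
small_strain_modulus <- function(mat) {
  stopifnot(inherits(mat, "wall_material"))
  3 * mat$C1 * mat$C2
}

#' Uniaxial tangent modulus by a lateral-contraction solve
#'
#' Applies an axial stretch `lambda` along `axis` with equal lateral stretches
#' solved by Newton iteration so the transverse Cauchy stress vanishes, then
#' returns axial stress / axial strain.  For `lambda` close to 1 and `C5 = 0`
#' this converges to the small-strain modulus `3*C1*C2`.
#'
#' @param mat a [wall_material()].
#' @param lambda axial stretch (default 1.001).
#' @param axis axial direction, 1..3; the fiber (if any) is placed along axis 1
#'   so `axis = 2` or `3` probes the matrix response.
#' @return List with `E` (MPa), `lateral_stretch`, `stress` (axial Cauchy, MPa).
#' @export
uniaxial_modulus <- function(mat, lambda = 1.001, axis = 2) {
  stopifnot(inherits(mat, "wall_material"))
  axial_stress <- function(lat) {
    s <- rep(lat, 3); s[axis] <- lambda
    st <- deformation_state(diag(s), a0 = c(1, 0, 0))
    cauchy_stress(st, mat)
  }
  tr_ax <- setdiff(1:3, axis)[1]
  lat <- 1 / sqrt(lambda)               # incompressible initial guess
  for (it in 1:50) {
    r <- axial_stress(lat)[tr_ax, tr_ax]
    h <- 1e-7
    dr <- (axial_stress(lat + h)[tr_ax, tr_ax] - axial_stress(lat - h)[tr_ax, tr_ax]) / (2 * h)
    step <- -r / dr
    lat <- lat + step
    if (abs(step) < 1e-13) break
  }
  sig <- axial_stress(lat)
  list(E = sig[axis, axis] / (lambda - 1),
       lateral_stretch = lat,
       stress = sig[axis, axis])
}

# deviatoric part of a 3x3 tensor
.dev3 <- function(A) A - (sum(diag(A)) / 3) * diag(3)
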