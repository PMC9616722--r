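#' Load program for the pressure ramp
#'
#' Adaptive quasi-static incrementation: steps that converge in fewer than
#' half the Newton budget grow by 1.25x (capped at `dP_max`); failed steps
#' are halved down to `dP_min`, below which the solve aborts with the states
#' accepted so far.
#'
#' @param P_max final turgor pressure, MPa (default 5).
#' @param dP_init initial pressure increment, MPa.
#' @param dP_min smallest allowed increment, MPa.
#' @param dP_max largest allowed increment, MPa.
#' @param newton_tol relative residual tolerance (vs external force norm).
#' @param newton_max_iter Newton iteration budget per step.
#' @return Object of class `load_program`.
#' @export
load_program <- function(P_max = 5, dP_init = 0.025, dP_min = 1e-4, dP_max = 0.5,
                         newton_tol = 1e-6, newton_max_iter = 30) {
  if (P_max > 0 && !(dP_min <= dP_init && dP_init <= dP_max && dP_max <= P_max)) {
    stop("require 0 < dP_min <= dP_init <= dP_max <= P_max")
  }
  if (dP_min <= 0) stop("dP_min must be > 0")
  if (!(newton_tol > 0 && newton_tol <= 1e-3)) stop("newton_tol must be in (0, 1e-3]")
  structure(list(P_max = P_max, dP_init = dP_init, dP_min = dP_min,
                 dP_max = dP_max, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter)),
            class = "load_program")
}

.mat_par <- function(mat) c(mat$C1, mat$C2, mat$C5, mat$K_bulk)

.facet_mats <- function(mesh) {
  quads <- do.call(rbind, lapply(mesh$pressure_facets, `[[`, "quads"))
  tris  <- do.call(rbind, lapply(mesh$pressure_facets, `[[`, "tris"))
  list(quads = quads, tris = tris)
}

#' Assemble the global residual at a trial state
#'
#' Internal nodal forces from the wall stress by Gauss quadrature minus the
#' follower pressure loads on the lumen surfaces.  Entries at constrained
#' DOF are reported separately as reactions and excluded from convergence
#' norms.
#'
#' @param mesh a `volume_mesh`.
#' @param mat a [wall_material()].
#' @param U nodal displacement matrix (n_nodes x 3, um).
#' @param P turgor pressure, MPa.
#' @return List with `residual` (full 3n vector, reactions zeroed),
#'   `reactions` (constrained entries), `f_int`, `f_ext`, `energy` (internal
#'   strain energy), `potential` (internal minus pressure-volume work).
#' @export
assemble_residual <- function(mesh, mat, U, P = 0) {
  fa <- .facet_mats(mesh)
  asm <- fe_assemble(mesh$node_coords, mesh$hex_connectivity, mesh$fiber_dirs,
                     .mat_par(mat), U, fa$quads, fa$tris, P, FALSE)
  r <- asm$f_int - asm$f_ext
  free <- as.vector(t(free_dof_mask(mesh)))
  reac <- r; reac[free] <- 0
  r[!free] <- 0
  def <- mesh$node_coords + U
  Venc <- sum(vapply(mesh$pressure_facets, function(sf)
    surface_volume(def, sf$quads, sf$tris), numeric(1)))
  list(residual = r, reactions = reac, f_int = asm$f_int, f_ext = asm$f_ext,
       energy = asm$energy, potential = asm$energy - P * Venc)
}

# one Newton solve at fixed pressure; U is the warm start
.newton <- function(mesh, mat, U, P, tol, maxit, quads, tris, free) {
  nd <- length(free)
  idx_free <- which(free)
  remap <- integer(nd); remap[idx_free] <- seq_along(idx_free)
  mp <- .mat_par(mat)
  for (it in seq_len(maxit)) {
    asm <- fe_assemble(mesh$node_coords, mesh$hex_connectivity, mesh$fiber_dirs,
                       mp, U, quads, tris, P, TRUE)
    r <- (asm$f_int - asm$f_ext)[idx_free]
    ref <- sqrt(sum(asm$f_ext[idx_free]^2))
    rn <- sqrt(sum(r^2))
    if (rn <= tol * max(ref, 1e-9)) {
      return(list(U = U, converged = TRUE, iters = it - 1L, resid = rn))
    }
    keep <- free[asm$Ki] & free[asm$Kj]
    K <- Matrix::sparseMatrix(i = remap[asm$Ki[keep]], j = remap[asm$Kj[keep]],
                              x = asm$Kx[keep], dims = c(length(idx_free), length(idx_free)))
    du <- tryCatch(as.numeric(Matrix::solve(K, -r)), error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      return(list(U = U, converged = FALSE, iters = it, resid = rn))
    }
    # damped step acceptance: full Newton steps may transiently raise the
    # residual (follower-load nonlinearity); only back off on element
    # inversion or gross divergence
    alpha <- 1
    accepted <- FALSE
    sub <- cbind((idx_free - 1L) %/% 3L + 1L, (idx_free - 1L) %% 3L + 1L)
    for (ls in 1:6) {
      Utry <- U
      Utry[sub] <- Utry[sub] + alpha * du
      atry <- tryCatch(
        fe_assemble(mesh$node_coords, mesh$hex_connectivity, mesh$fiber_dirs,
                    mp, Utry, quads, tris, P, FALSE),
        error = function(e) NULL)
      if (!is.null(atry)) {
        rt <- sqrt(sum(((atry$f_int - atry$f_ext)[idx_free])^2))
        if (is.finite(rt) && rt < 1e4 * max(rn, ref)) {
          U <- Utry
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      return(list(U = U, converged = FALSE, iters = it, resid = rn))
    }
  }
  list(U = U, converged = FALSE, iters = maxit, resid = NA_real_)
}

#' Solve the quasi-static pressure ramp
#'
#' Total-Lagrangian Newton iteration with follower pressure on the lumen
#' surfaces and adaptive load incrementation from 0 to `load$P_max`.
#'
#' @param mesh a `volume_mesh` (stoma or benchmark shell).
#' @param mat a [wall_material()].
#' @param load a [load_program()].
#' @param verbose print per-step convergence records.
#' @return List of `solution_state` objects (class `pressure_ramp`), one per
#'   accepted step, including P = 0 and P = P_max.  On failure at `dP_min`, a
#'   condition of class `stomech_partial_result` carrying the accepted states
#'   is signalled.
#' @export
solve_pressure_ramp <- function(mesh, mat, load = load_program(), verbose = FALSE) {
  stopifnot(inherits(mesh, "volume_mesh"), inherits(mat, "wall_material"),
            inherits(load, "load_program"))
  fa <- .facet_mats(mesh)
  free <- as.vector(t(free_dof_mask(mesh)))
  U <- matrix(0, nrow(mesh$node_coords), 3)
  states <- list(solution_state(0, U))
  if (load$P_max <= 0) return(structure(states, class = "pressure_ramp"))
  P <- 0; dP <- load$dP_init
  while (P < load$P_max - 1e-12) {
    dP <- min(dP, load$P_max - P)
    res <- .newton(mesh, mat, U, P + dP, load$newton_tol, load$newton_max_iter,
                   fa$quads, fa$tris, free)
    if (res$converged) {
      P <- P + dP
      U <- res$U
      states[[length(states) + 1L]] <- solution_state(P, U)
      if (verbose) {
        message(sprintf("  P = %.4f MPa: %d iterations, residual %.3e",
                        P, res$iters, res$resid))
      }
      if (res$iters < load$newton_max_iter / 2) {
        dP <- min(dP * 1.25, load$dP_max)
      }
    } else {
      dP <- dP / 2
      if (verbose) message(sprintf("  step to %.4f failed; dP -> %.5f", P + 2 * dP, dP))
      if (dP < load$dP_min) {
        cond <- structure(
          class = c("stomech_partial_result", "error", "condition"),
          list(message = sprintf(
            "pressure ramp failed to converge below dP_min at P = %.4f MPa", P),
            call = sys.call(-1), states = structure(states, class = "pressure_ramp")))
        stop(cond)
      }
    }
  }
  structure(states, class = "pressure_ramp")
}

#' Solution state at one accepted pressure
#' @param pressure turgor pressure, MPa.
#' @param displacements n_nodes x 3 displacement matrix, um.
#' @return Object of class `solution_state`.
#' @export
solution_state <- function(pressure, displacements) {
  structure(list(pressure = pressure, displacements = displacements),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf("solution_state: P = %g MPa, max |u| = %.4g um\n",
              x$pressure, max(abs(x$displacements))))
  invisible(x)
}

#' @export
print.pressure_ramp <- function(x, ...) {
  cat(sprintf("pressure_ramp: %d accepted states, P in [%g, %g] MPa\n",
              length(x), x[[1]]$pressure, x[[length(x)]]$pressure))
  invisible(x)
}

#' Per-element stress, strain and dilatation fields at a state
#'
#' @param mesh a `volume_mesh`.
#' @param mat a [wall_material()].
#' @param state a `solution_state`.
#' @return List with `sigma` and `E_GL` (n_el x 6, order xx yy zz xy yz xz),
#'   `J_bar` (element mean dilatation), `J_min`/`J_max` (Gauss-point range),
#'   `eff_stress` (von Mises, MPa) and `eff_strain` (effective Lagrange).
#' @export
element_fields <- function(mesh, mat, state) {
  f <- fe_fields(mesh$node_coords, mesh$hex_connectivity, mesh$fiber_dirs,
                 .mat_par(mat), state$displacements)
  f$eff_stress <- apply(f$sigma, 1, function(v) effective_stress(.sym_from6(v)))
  f$eff_strain <- apply(f$E_GL, 1, function(v) effective_lagrange_strain(.sym_from6(v)))
  f
}

.sym_from6 <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}
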