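#' Effective (deviatoric) Lagrange strain scalar
#'
#' \eqn{e = \sqrt{\tfrac{3}{2} E':E'}} with \eqn{E' = E - \tfrac{tr E}{3} I};
#' zero for purely volumetric strain.
#'
#' @param E_GL symmetric 3x3 Green-Lagrange strain tensor.
#' @return Dimensionless scalar.
#' @export
effective_lagrange_strain <- function(E_GL) {
  E_GL <- as.matrix(E_GL)
  .check_sym(E_GL, "E_GL")
  D <- E_GL - (sum(diag(E_GL)) / 3) * diag(3)
  sqrt(1.5 * sum(D * D))
}

#' Effective (von Mises) stress
#'
#' \eqn{\sigma_{vm} = \sqrt{\tfrac{3}{2}\, dev(\sigma):dev(\sigma)}}.
#'
#' @param sigma symmetric 3x3 Cauchy stress tensor, MPa.
#' @return Scalar, MPa.
#' @export
effective_stress <- function(sigma) {
  sigma <- as.matrix(sigma)
  .check_sym(sigma, "sigma")
  D <- sigma - (sum(diag(sigma)) / 3) * diag(3)
  sqrt(1.5 * sum(D * D))
}

.check_sym <- function(A, nm) {
  if (!all(dim(A) == c(3, 3))) stop(nm, " must be 3x3")
  sc <- max(abs(A), 1e-300)
  if (max(abs(A - t(A))) > 1e-8 * sc) stop(nm, " must be symmetric")
  invisible(TRUE)
}

# ordered deformed pore outline (closed polygon, leaf-plane projection)
.pore_outline <- function(state, mesh) {
  def <- mesh$node_coords + state$displacements
  s1 <- mesh$seam_nodes[[1]]
  s2 <- mesh$seam_nodes[[2]]
  ids <- c(s1, rev(s2)[-1])
  ids <- ids[-length(ids)]               # shared end node closes the loop
  def[ids, 1:2, drop = FALSE]
}

.polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

.polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  seg <- cbind(xy, xy[c(2:n, 1), ])
  ccw <- function(a, b, c) (c[2] - a[2]) * (b[1] - a[1]) - (b[2] - a[2]) * (c[1] - a[1])
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j == i || j == i %% n + 1 || i == j %% n + 1) next
    a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
    if (ccw(a, c, d) * ccw(b, c, d) < 0 && ccw(c, a, b) * ccw(d, a, b) < 0) {
      return(TRUE)
    }
  }
  FALSE
}

#' Pore aperture and area at a solution state
#'
#' The pore outline is the deformed ventral seam of each guard cell (the wall
#' edge facing the pore), joined into a closed polygon and projected onto the
#' leaf plane.  Aperture is the maximum transverse (short-axis) width of the
#' outline; pore area is its planar polygon area.
#'
#' @param state a `solution_state`.
#' @param mesh the stoma `volume_mesh` the state was solved on.
#' @return List with `aperture` (um) and `pore_area` (um^2).
#' @export
measure_pore <- function(state, mesh) {
  stopifnot(inherits(state, "solution_state"), mesh$kind == "stoma")
  xy <- .pore_outline(state, mesh)
  if (.polygon_self_intersects(xy)) {
    stop("pore outline self-intersects at P = ", state$pressure,
         " MPa: nonphysical state")
  }
  list(aperture = max(xy[, 2]) - min(xy[, 2]),
       pore_area = .polygon_area(xy))
}

#' Stomatal complex aspect ratio at a solution state
#'
#' @inheritParams measure_pore
#' @return List with `aspect_ratio`, `complex_length` (um, extent along the
#'   pore long axis) and `complex_width` (um, transverse extent), measured on
#'   the deformed outer wall surface.
#' @export
measure_aspect_ratio <- function(state, mesh) {
  stopifnot(inherits(state, "solution_state"), mesh$kind == "stoma")
  def <- mesh$node_coords[mesh$outer_nodes, , drop = FALSE] +
    state$displacements[mesh$outer_nodes, , drop = FALSE]
  len <- max(def[, 1]) - min(def[, 1])
  wid <- max(def[, 2]) - min(def[, 2])
  list(aspect_ratio = len / wid, complex_length = len, complex_width = wid)
}

#' Pressure-response table from a solved ramp
#'
#' One row per accepted state: pressure, aperture, pore area, aspect ratio
#' and deformed complex dimensions.  Optionally writes a CSV and a VTU series
#' with displacement vectors and effective stress/strain element fields.
#'
#' @param states a `pressure_ramp` (list of `solution_state`).
#' @param mesh the stoma `volume_mesh`.
#' @param csv optional path for the response CSV.
#' @param vtu_dir optional directory for per-state VTU files (requires `mat`).
#' @param mat the [wall_material()], needed only for VTU stress output.
#' @return `data.frame` of class `pressure_response`.
#' @export
build_response <- function(states, mesh, csv = NULL, vtu_dir = NULL, mat = NULL) {
  rows <- lapply(states, function(st) {
    p <- tryCatch(measure_pore(st, mesh), error = function(e)
      stop("at P = ", st$pressure, " MPa: ", conditionMessage(e), call. = FALSE))
    a <- measure_aspect_ratio(st, mesh)
    data.frame(pressure = st$pressure, aperture = p$aperture,
               pore_area = p$pore_area, aspect_ratio = a$aspect_ratio,
               complex_length = a$complex_length, complex_width = a$complex_width)
  })
  out <- do.call(rbind, rows)
  if (is.unsorted(out$pressure, strictly = TRUE)) {
    stop("states must be ordered by strictly increasing pressure")
  }
  class(out) <- c("pressure_response", "data.frame")
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(out), csv, row.names = FALSE)
  }
  if (!is.null(vtu_dir)) {
    stopifnot(!is.null(mat))
    dir.create(vtu_dir, showWarnings = FALSE, recursive = TRUE)
    for (si in seq_along(states)) {
      st <- states[[si]]
      f <- element_fields(mesh, mat, st)
      write_vtu(file.path(vtu_dir, sprintf("state_%03d.vtu", si - 1L)),
                mesh$node_coords, mesh$hex_connectivity,
                point_data = list(displacement = st$displacements),
                cell_data = list(eff_stress_MPa = f$eff_stress,
                                 eff_lagrange_strain = f$eff_strain,
                                 region = as.integer(factor(mesh$element_region))))
    }
  }
  out
}
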