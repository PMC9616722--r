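#' Stomatal complex geometry
#'
#' The undeformed guard-cell pair is described by four measured plan-view
#' dimensions plus two wall thicknesses.  In plan, the pore outline is the
#' ellipse with semi-axes `pore_length/2` x `pore_width/2` and the complex
#' outline is the ellipse with semi-axes `stoma_length/2` x
#' `(pore_width/2 + gc_width)`.  Each guard cell is a hollow tube swept
#' between the two ellipses; its midline is the half-ellipse lying pointwise
#' midway between them.
#'
#' @param stoma_length complex length, um.
#' @param pore_length pore length, um (< `stoma_length`).
#' @param pore_width pore width, um.
#' @param gc_width guard-cell width, um; also the out-of-plane tube height.
#' @param wall_thickness wall thickness, um (default 0.1).
#' @param polar_wall_thickness polar wall thickness, um (default 0.3).
#' @return Object of class `stoma_geometry`.
#' @export
stoma_geometry <- function(stoma_length, pore_length, pore_width, gc_width,
                           wall_thickness = 0.1, polar_wall_thickness = 0.3) {
  v <- c(stoma_length = stoma_length, pore_length = pore_length,
         pore_width = pore_width, gc_width = gc_width,
         wall_thickness = wall_thickness,
         polar_wall_thickness = polar_wall_thickness)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all stoma_geometry lengths must be finite and strictly positive")
  }
  if (pore_length >= stoma_length) {
    stop("pore_length must be < stoma_length")
  }
  if (wall_thickness >= gc_width / 2) {
    stop("wall_thickness must be < gc_width / 2")
  }
  g <- structure(as.list(v), class = "stoma_geometry")
  # minimum in-plane cross-section semi-axis along the sweep; the wall must fit
  umin <- min(.gc_inplane_semi(g, seq(0, pi, length.out = 721)))
  if (wall_thickness >= umin) {
    stop("wall_thickness (", wall_thickness, ") exceeds the minimum in-plane ",
         "cross-section semi-axis (", signif(umin, 4),
         "): pore too wide relative to gc_width")
  }
  g
}

#' @export
print.stoma_geometry <- function(x, ...) {
  cat("Stomatal complex geometry (um):\n")
  cat(sprintf("  stoma length %g, pore %g x %g, guard-cell width %g\n",
              x$stoma_length, x$pore_length, x$pore_width, x$gc_width))
  cat(sprintf("  wall thickness %g, polar wall thickness %g\n",
              x$wall_thickness, x$polar_wall_thickness))
  invisible(x)
}

#' Mesh resolution for the guard-cell pair
#'
#' @param n_midline segments along each guard-cell midline (>= 8).
#' @param n_circum segments around the tube cross-section (>= 8).
#' @param n_thickness element layers through the wall (>= 1).
#' @return Object of class `mesh_resolution`.
#' @export
mesh_resolution <- function(n_midline = 24, n_circum = 16, n_thickness = 1) {
  if (n_midline < 8 || n_circum < 8 || n_thickness < 1) {
    stop("require n_midline >= 8, n_circum >= 8, n_thickness >= 1")
  }
  structure(list(n_midline = as.integer(n_midline),
                 n_circum = as.integer(n_circum),
                 n_thickness = as.integer(n_thickness)),
            class = "mesh_resolution")
}

# ellipse semi-axes: pore (a_p, b_p), complex (a_c, b_c), midline = average
.gc_axes <- function(geom) {
  a_p <- geom$pore_length / 2
  b_p <- geom$pore_width / 2
  a_c <- geom$stoma_length / 2
  b_c <- geom$pore_width / 2 + geom$gc_width
  list(a_p = a_p, b_p = b_p, a_c = a_c, b_c = b_c,
       a_m = (a_p + a_c) / 2, b_m = (b_p + b_c) / 2,
       da = a_c - a_p, db = b_c - b_p)
}

# in-plane cross-section semi-axis u(theta) = |c(theta) - p(theta)| / 2
.gc_inplane_semi <- function(geom, theta) {
  ax <- .gc_axes(geom)
  sqrt((ax$da * cos(theta))^2 + (ax$db * sin(theta))^2) / 2
}

#' Guard-cell midline curve
#'
#' Half-ellipse lying pointwise midway between the pore outline and the
#' complex outline, in the leaf plane (z = 0).  The two sides are mirror
#' images across the pore long axis (the x axis).
#'
#' @param geom a [stoma_geometry()].
#' @param side `"left"` (y > 0) or `"right"` (y < 0).
#' @param n number of points sampled along the arc.
#' @return `n` x 3 matrix of points (um); columns x, y, z.
#' @export
build_midline <- function(geom, side = c("left", "right"), n = 201) {
  stopifnot(inherits(geom, "stoma_geometry"))
  side <- match.arg(side)
  s <- if (side == "left") 1 else -1
  ax <- .gc_axes(geom)
  theta <- seq(0, pi, length.out = n)
  cbind(x = ax$a_m * cos(theta),
        y = s * ax$b_m * sin(theta),
        z = rep(0, n))
}

# one structured node position of a guard-cell tube
# theta sweep angle, phi circumferential angle (0 = ventral seam), tau depth
# s = +1 / -1 selects the cell side; for s = -1 phi runs reversed so element
# orientation stays right-handed
.gc_point <- function(geom, theta, phi, tau, s) {
  ax <- .gc_axes(geom)
  u  <- .gc_inplane_semi(geom, theta)
  v  <- geom$gc_width / 2
  er <- cbind(-ax$da * cos(theta), -s * ax$db * sin(theta), 0)
  er <- er / sqrt(rowSums(er^2))
  m  <- cbind(ax$a_m * cos(theta), s * ax$b_m * sin(theta), 0)
  ph <- if (s > 0) phi else -phi
  m + (u - tau) * cos(ph) * er +
    cbind(0, 0, (v - tau) * sin(ph))
}

#' Generate the hexahedral volume mesh of the guard-cell pair
#'
#' Sweeps a hollow elliptical-section tube along each guard-cell midline
#' (outer surface spanning pore to complex outline, inner surface offset by
#' `wall_thickness`), welds the two cells at their shared polar cross-
#' sections, adds solid polar wall slabs of thickness `polar_wall_thickness`
#' whose nodes are all fixed in space, tags the two closed lumen pressure
#' surfaces, and assigns circumferential (hoop) fiber directions.
#'
#' @param geom a [stoma_geometry()].
#' @param res a [mesh_resolution()].
#' @return Object of class `volume_mesh` with fields `node_coords`,
#'   `hex_connectivity`, `fiber_dirs`, `pressure_facets` (two closed surfaces,
#'   each with `quads` and `tris`), `fixed_nodes`, `element_region`.
#' @export
generate_mesh <- function(geom, res) {
  stopifnot(inherits(geom, "stoma_geometry"), inherits(res, "mesh_resolution"))
  nm <- res$n_midline; nc <- res$n_circum; nt <- res$n_thickness
  v  <- geom$gc_width / 2
  tw <- geom$wall_thickness
  theta <- seq(0, pi, length.out = nm + 1)
  phi   <- 2 * pi * (0:(nc - 1)) / nc
  tau   <- tw * (0:nt) / nt

  key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9), round(p[, 3], 9))
  nodes <- matrix(numeric(0), 0, 3)
  nodemap <- new.env(hash = TRUE, parent = emptyenv())
  add_nodes <- function(p) {
    ks <- key(p)
    idx <- integer(nrow(p))
    for (r in seq_len(nrow(p))) {
      got <- nodemap[[ks[r]]]
      if (is.null(got)) {
        nodes <<- rbind(nodes, p[r, , drop = FALSE])
        got <- nrow(nodes)
        nodemap[[ks[r]]] <- got
      }
      idx[r] <- got
    }
    idx
  }

  hexes <- NULL; region <- character(0)
  meta <- NULL
  surf <- list(list(quads = NULL, tris = NULL), list(quads = NULL, tris = NULL))
  tube_index <- vector("list", 2)  # per cell: array [nm, nc, nt+1] of node ids

  for (cell in 1:2) {
    s <- if (cell == 1) 1 else -1
    nid <- array(0L, dim = c(nm + 1, nc, nt + 1))
    for (i in 0:nm) for (k in 0:nt) {
      p <- .gc_point(geom, rep(theta[i + 1], nc), phi, rep(tau[k + 1], nc), s)
      nid[i + 1, , k + 1] <- add_nodes(p)
    }
    tube_index[[cell]] <- nid
    jp <- function(j) (j %% nc) + 1
    for (i in 1:nm) for (j in 1:nc) for (k in 1:nt) {
      hexes <- rbind(hexes, c(nid[i, j, k],       nid[i + 1, j, k],
                              nid[i + 1, jp(j), k], nid[i, jp(j), k],
                              nid[i, j, k + 1],   nid[i + 1, j, k + 1],
                              nid[i + 1, jp(j), k + 1], nid[i, jp(j), k + 1]))
      phic <- (phi[j] + if (j < nc) phi[j + 1] else 2 * pi) / 2
      region <- c(region, if (cos(phic) >= 0) "ventral" else "dorsal")
      meta <- rbind(meta, c(cell, i, j, k,
                            (theta[i] + theta[i + 1]) / 2, phic,
                            (tau[k] + tau[k + 1]) / 2))
    }
    # lumen surface quads (innermost layer, k = nt + 1), outward from lumen
    for (i in 1:nm) for (j in 1:nc) {
      surf[[cell]]$quads <- rbind(surf[[cell]]$quads,
        c(nid[i, j, nt + 1], nid[i + 1, j, nt + 1],
          nid[i + 1, jp(j), nt + 1], nid[i, jp(j), nt + 1]))
    }
  }

  # polar slabs: extrude the shared end cross-sections axially outward;
  # every polar node (incl. the shared interface ring) is fixed in space
  ax <- .gc_axes(geom)
  polar_nodes <- integer(0)
  cap_centers <- integer(0)
  for (pole in 1:2) {                       # 1: theta = 0 (+x), 2: theta = pi (-x)
    iend <- if (pole == 1) 1 else nm + 1
    sgn  <- if (pole == 1) 1 else -1
    ring <- tube_index[[1]][iend, , ]       # nc x (nt+1), shared with cell 2
    # the end cross-section lies in the y = 0 plane; the polar wall is a slab
    # straddling it, half into each cell side
    extp <- matrix(0L, nc, nt + 1)
    extm <- matrix(0L, nc, nt + 1)
    for (k in 1:(nt + 1)) {
      p <- nodes[ring[, k], , drop = FALSE]
      extp[, k] <- add_nodes(sweep(p, 2, c(0, geom$polar_wall_thickness / 2, 0), "+"))
      extm[, k] <- add_nodes(sweep(p, 2, c(0, -geom$polar_wall_thickness / 2, 0), "+"))
    }
    jp <- function(j) (j %% nc) + 1
    for (lay in list(list(extm, ring), list(ring, extp))) {
      lo <- lay[[1]]; hi <- lay[[2]]
      for (j in 1:nc) for (k in 1:nt) {
        hexes <- rbind(hexes, c(lo[j, k], hi[j, k], hi[jp(j), k], lo[jp(j), k],
                                lo[j, k + 1], hi[j, k + 1],
                                hi[jp(j), k + 1], lo[jp(j), k + 1]))
        region <- c(region, "polar")
        meta <- rbind(meta, c(0, pole, j, k, if (pole == 1) 0 else pi, NA, NA))
      }
    }
    polar_nodes <- c(polar_nodes, as.integer(ring), as.integer(extp),
                     as.integer(extm))
    # cap: triangle fan over the inner end cross-section, closes both lumens
    ctr <- add_nodes(matrix(c(sgn * ax$a_m, 0, 0), 1, 3))
    cap_centers <- c(cap_centers, ctr)
    polar_nodes <- c(polar_nodes, ctr)
    inner <- ring[, nt + 1]
    tris <- cbind(ctr, inner, inner[c(2:nc, 1)])
    # the cap bounds both lumens with opposite outward normals; windings are
    # chosen consistent with each cell's lumen quads, then .orient_mesh flips
    # whole surfaces so normals point out of the lumen
    surf[[1]]$tris <- rbind(surf[[1]]$tris, tris)
    surf[[2]]$tris <- rbind(surf[[2]]$tris, tris[, c(1, 3, 2)])
  }

  seam_nodes <- lapply(tube_index, function(nid) as.integer(nid[, 1, 1]))
  outer_nodes <- sort(unique(c(as.integer(tube_index[[1]][, , 1]),
                               as.integer(tube_index[[2]][, , 1]))))
  mesh <- structure(list(
    node_coords = nodes,
    hex_connectivity = hexes,
    fiber_dirs = NULL,
    pressure_facets = surf,
    fixed_nodes = sort(unique(polar_nodes)),
    fixed_dofs = NULL,
    element_region = region,
    element_meta = data.frame(cell = meta[, 1], i = meta[, 2], j = meta[, 3],
                              k = meta[, 4], theta = meta[, 5], phi = meta[, 6],
                              tau = meta[, 7]),
    seam_nodes = seam_nodes, outer_nodes = outer_nodes,
    geom = geom, res = res, kind = "stoma"), class = "volume_mesh")
  mesh <- .orient_mesh(mesh)
  mesh <- assign_fiber_orientations(mesh)
  .check_mesh_quality(mesh)
  mesh
}

# flip any left-handed hexahedra (xi<->eta swap) and orient each pressure
# surface so its divergence-theorem volume is positive (normals point out of
# the lumen, the direction the pressure traction acts)
.orient_mesh <- function(mesh) {
  dets <- hex_jacobians(mesh$node_coords, mesh$hex_connectivity)
  bad <- dets <= 0
  if (any(bad)) {
    perm <- c(1, 4, 3, 2, 5, 8, 7, 6)
    mesh$hex_connectivity[bad, ] <- mesh$hex_connectivity[bad, perm, drop = FALSE]
  }
  for (sfi in seq_along(mesh$pressure_facets)) {
    sf <- mesh$pressure_facets[[sfi]]
    V <- surface_volume(mesh$node_coords, sf$quads, sf$tris)
    if (V < 0) {
      if (!is.null(sf$quads)) sf$quads <- sf$quads[, 4:1, drop = FALSE]
      if (!is.null(sf$tris))  sf$tris  <- sf$tris[, c(1, 3, 2), drop = FALSE]
      mesh$pressure_facets[[sfi]] <- sf
    }
  }
  mesh
}

.check_mesh_quality <- function(mesh) {
  dets <- hex_jacobians(mesh$node_coords, mesh$hex_connectivity)
  if (any(dets <= 0)) {
    bad <- which(dets <= 0)
    stop("degenerate mesh: ", length(bad),
         " hexahedra with non-positive Jacobian (first: element ", bad[1],
         ", det = ", signif(dets[bad[1]], 4), ")")
  }
  invisible(TRUE)
}

#' Assign circumferential fiber directions
#'
#' Sets each tube element's fiber to the cross-section hoop direction (the
#' circumferential cellulose microfibril orientation): the unit tangent to the
#' tube circumference at the element centroid, orthogonalized against the
#' local midline tangent.  Polar solid elements inherit the hoop direction of
#' the nearest tube element (lowest element index on ties).
#'
#' @param mesh a `volume_mesh` with element metadata.
#' @return The mesh with `fiber_dirs` filled (unit row vectors).
#' @export
assign_fiber_orientations <- function(mesh) {
  stopifnot(inherits(mesh, "volume_mesh"))
  ne <- nrow(mesh$hex_connectivity)
  fib <- matrix(0, ne, 3)
  md <- mesh$element_meta
  if (mesh$kind == "stoma") {
    ax <- .gc_axes(mesh$geom)
    vh <- mesh$geom$gc_width / 2
    for (e in seq_len(ne)) {
      if (md$cell[e] == 0) next
      s  <- if (md$cell[e] == 1) 1 else -1
      th <- md$theta[e]; ph0 <- md$phi[e]; tu <- md$tau[e]
      u  <- .gc_inplane_semi(mesh$geom, th)
      er <- c(-ax$da * cos(th), -s * ax$db * sin(th), 0)
      er <- er / sqrt(sum(er^2))
      ph <- if (s > 0) ph0 else -ph0
      h  <- -(u - tu) * sin(ph) * er + c(0, 0, (vh - tu) * cos(ph))
      tg <- c(-ax$a_m * sin(th), s * ax$b_m * cos(th), 0)
      tg <- tg / sqrt(sum(tg^2))
      h  <- h - sum(h * tg) * tg
      nh <- sqrt(sum(h^2))
      if (nh < 1e-12) stop("degenerate hoop tangent at element ", e)
      fib[e, ] <- h / nh
    }
    tube <- which(md$cell != 0)
    if (length(tube) < ne) {
      cent <- element_centroids(mesh)
      for (e in which(md$cell == 0)) {
        d2 <- rowSums(sweep(cent[tube, , drop = FALSE], 2, cent[e, ], "-")^2)
        fib[e, ] <- fib[tube[which.min(d2)], ]
      }
    }
  } else if (mesh$kind == "cylinder") {
    cent <- element_centroids(mesh)
    for (e in seq_len(ne)) {
      h <- c(0, -cent[e, 3], cent[e, 2])   # hoop about the x axis
      nh <- sqrt(sum(h^2))
      if (nh < 1e-12) stop("degenerate hoop tangent at element ", e)
      fib[e, ] <- h / nh
    }
  } else if (mesh$kind == "sphere") {
    cent <- element_centroids(mesh)
    for (e in seq_len(ne)) {
      h <- c(-cent[e, 2], cent[e, 1], 0)   # any tangent; isotropy uses C5 = 0
      nh <- sqrt(sum(h^2))
      if (nh < 1e-9) h <- c(1, 0, 0)
      fib[e, ] <- h / sqrt(sum(h^2))
    }
  } else {
    stop("unknown mesh kind: ", mesh$kind)
  }
  mesh$fiber_dirs <- fib
  mesh
}

#' Element centroids
#' @param mesh a `volume_mesh`.
#' @return n_element x 3 matrix of mean corner coordinates (um).
#' @export
element_centroids <- function(mesh) {
  t(apply(mesh$hex_connectivity, 1,
          function(h) colMeans(mesh$node_coords[h, , drop = FALSE])))
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("volume_mesh (%s): %d nodes, %d hexahedra\n",
              x$kind, nrow(x$node_coords), nrow(x$hex_connectivity)))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s=%d", names(table(x$element_region)),
                            table(x$element_region)), collapse = ", ")))
  cat(sprintf("  fixed nodes: %d; pressure surfaces: %d\n",
              length(x$fixed_nodes), length(x$pressure_facets)))
  invisible(x)
}

#' Outer-wall surface area of a stoma mesh
#'
#' Sum of bilinear quad areas over the outermost node layer of both tubes.
#' @param mesh a stoma `volume_mesh`.
#' @return Area in um^2.
#' @export
outer_surface_area <- function(mesh) {
  stopifnot(mesh$kind == "stoma")
  md <- mesh$element_meta
  nt <- mesh$res$n_thickness
  quads <- NULL
  sel <- which(md$cell != 0 & md$k == 1)
  for (e in sel) {
    h <- mesh$hex_connectivity[e, ]
    quads <- rbind(quads, h[1:4])          # k = 1 face is the outer surface
  }
  sum(apply(quads, 1, function(q) {
    p <- mesh$node_coords[q, ]
    a1 <- 0.5 * sqrt(sum(.cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
    a2 <- 0.5 * sqrt(sum(.cross3(p[3, ] - p[1, ], p[4, ] - p[1, ])^2))
    a1 + a2
  }))
}

#' Enclosed volume of a pressure surface
#'
#' Divergence-theorem volume of one closed lumen surface; positive when the
#' facet orientation points out of the lumen.
#' @param mesh a `volume_mesh`.
#' @param surface surface index (1 or 2).
#' @return Volume in um^3.
#' @export
lumen_volume <- function(mesh, surface = 1) {
  sf <- mesh$pressure_facets[[surface]]
  surface_volume(mesh$node_coords, sf$quads, sf$tris)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# free-DOF logical mask (n_nodes x 3); TRUE = unconstrained
free_dof_mask <- function(mesh) {
  msk <- matrix(TRUE, nrow(mesh$node_coords), 3)
  if (length(mesh$fixed_nodes)) msk[mesh$fixed_nodes, ] <- FALSE
  if (!is.null(mesh$fixed_dofs)) msk[mesh$fixed_dofs] <- FALSE
  msk
}
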