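#' Benchmark thin-shell meshes with analytic stress solutions
#'
#' Closed hexahedral shells for validating the pressure solver against the
#' Laplace formulas: a sphere (`sigma = p R / (2 t)`) meshed as a cubed
#' sphere (no polar degeneracy), or a capped circular cylinder
#' (`sigma_hoop = p R / t`) with its end slices fixed in space.
#'
#' @param kind `"sphere"` or `"cylinder"`.
#' @param R mid-surface radius, um.
#' @param t wall thickness, um (must be < R/10).
#' @param n resolution: nodes per cube-face edge (sphere, must be even) or
#'   circumferential segments (cylinder).
#' @param n_thickness layers through the wall.
#' @param length cylinder length, um (default `6 * R`).
#' @return A `volume_mesh`; for the sphere, rigid-body modes are pinned by
#'   per-component constraints on the six axis nodes (`fixed_dofs`).
#' @export
benchmark_shell_mesh <- function(kind = c("sphere", "cylinder"), R = 10, t = 0.1,
                                 n = 8, n_thickness = 1, length = 6 * R) {
  kind <- match.arg(kind)
  if (t >= R / 10) stop("require t < R/10 for the thin-shell benchmark")
  if (kind == "sphere") {
    .sphere_mesh(R, t, n, n_thickness)
  } else {
    .cylinder_mesh(R, t, n, n_thickness, length)
  }
}

.sphere_mesh <- function(R, t, n, nt) {
  if (n %% 2 != 0) stop("sphere resolution n must be even (axis nodes)")
  # cube-face grids projected to the unit sphere, welded on shared edges
  dirs <- matrix(numeric(0), 0, 3)
  dmap <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(p) paste(round(p[1], 10), round(p[2], 10), round(p[3], 10))
  add_dir <- function(p) {
    p <- p / sqrt(sum(p^2))
    k <- key(p)
    got <- dmap[[k]]
    if (is.null(got)) {
      dirs <<- rbind(dirs, p)
      got <- nrow(dirs)
      dmap[[k]] <- got
    }
    got
  }
  faces <- list(function(a, b) c(1, a, b), function(a, b) c(-1, -a, b),
                function(a, b) c(a, 1, -b), function(a, b) c(a, -1, b),
                function(a, b) c(a, b, 1), function(a, b) c(-a, b, 1 * -1))
  fidx <- vector("list", 6)
  g <- seq(-1, 1, length.out = n + 1)
  for (f in 1:6) {
    m <- matrix(0L, n + 1, n + 1)
    for (ia in 1:(n + 1)) for (ib in 1:(n + 1)) {
      m[ia, ib] <- add_dir(faces[[f]](g[ia], g[ib]))
    }
    fidx[[f]] <- m
  }
  radii <- R - t / 2 + t * (0:nt) / nt
  nd <- nrow(dirs)
  nodes <- do.call(rbind, lapply(radii, function(r) dirs * r))
  nid <- function(d, l) d + (l - 1L) * nd
  hexes <- NULL
  quads <- NULL
  for (f in 1:6) {
    m <- fidx[[f]]
    for (ia in 1:n) for (ib in 1:n) for (l in 1:nt) {
      c00 <- m[ia, ib]; c10 <- m[ia + 1, ib]
      c11 <- m[ia + 1, ib + 1]; c01 <- m[ia, ib + 1]
      hexes <- rbind(hexes, c(nid(c00, l), nid(c10, l), nid(c11, l), nid(c01, l),
                              nid(c00, l + 1), nid(c10, l + 1),
                              nid(c11, l + 1), nid(c01, l + 1)))
      if (l == 1) quads <- rbind(quads, c(c00, c10, c11, c01))  # inner surface
    }
  }
  fixed_dofs <- matrix(FALSE, nrow(nodes), 3)
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    on_axis <- abs(nodes[, others[1]]) < 1e-8 & abs(nodes[, others[2]]) < 1e-8
    fixed_dofs[on_axis, others] <- TRUE
  }
  mesh <- structure(list(
    node_coords = nodes, hex_connectivity = hexes, fiber_dirs = NULL,
    pressure_facets = list(list(quads = quads, tris = NULL)),
    fixed_nodes = integer(0), fixed_dofs = fixed_dofs,
    element_region = rep("shell", nrow(hexes)),
    element_meta = data.frame(cell = rep(NA_real_, nrow(hexes))),
    geom = list(R = R, t = t), res = list(n = n, n_thickness = nt),
    kind = "sphere"), class = "volume_mesh")
  mesh <- .orient_mesh(mesh)
  mesh <- assign_fiber_orientations(mesh)
  .check_mesh_quality(mesh)
  mesh
}

.cylinder_mesh <- function(R, t, n, nt, len) {
  na <- max(8L, as.integer(round(n * len / (2 * pi * R))))
  phi <- 2 * pi * (0:(n - 1)) / n
  xs <- seq(-len / 2, len / 2, length.out = na + 1)
  radii <- R - t / 2 + t * (0:nt) / nt      # k = 1 is the lumen surface
  nodes <- NULL
  nid <- array(0L, dim = c(na + 1, n, nt + 1))
  cnt <- 0L
  for (i in 1:(na + 1)) for (k in 1:(nt + 1)) {
    pts <- cbind(xs[i], radii[k] * cos(phi), radii[k] * sin(phi))
    nid[i, , k] <- cnt + 1:n
    nodes <- rbind(nodes, pts)
    cnt <- cnt + n
  }
  jp <- function(j) (j %% n) + 1
  hexes <- NULL; quads <- NULL
  for (i in 1:na) for (j in 1:n) for (k in 1:nt) {
    hexes <- rbind(hexes, c(nid[i, j, k], nid[i + 1, j, k],
                            nid[i + 1, jp(j), k], nid[i, jp(j), k],
                            nid[i, j, k + 1], nid[i + 1, j, k + 1],
                            nid[i + 1, jp(j), k + 1], nid[i, jp(j), k + 1]))
    if (k == 1) {
      quads <- rbind(quads, c(nid[i, j, 1], nid[i + 1, j, 1],
                              nid[i + 1, jp(j), 1], nid[i, jp(j), 1]))
    }
  }
  ctr1 <- nrow(nodes) + 1L; ctr2 <- nrow(nodes) + 2L
  nodes <- rbind(nodes, c(-len / 2, 0, 0), c(len / 2, 0, 0))
  inner1 <- nid[1, , 1]; inner2 <- nid[na + 1, , 1]
  tris <- rbind(cbind(ctr1, inner1, inner1[c(2:n, 1)]),
                cbind(ctr2, inner2[c(2:n, 1)], inner2))
  fixed <- sort(unique(c(as.integer(nid[1, , ]), as.integer(nid[na + 1, , ]),
                         ctr1, ctr2)))
  mesh <- structure(list(
    node_coords = nodes, hex_connectivity = hexes, fiber_dirs = NULL,
    pressure_facets = list(list(quads = quads, tris = tris)),
    fixed_nodes = fixed, fixed_dofs = NULL,
    element_region = rep("shell", nrow(hexes)),
    element_meta = data.frame(cell = rep(NA_real_, nrow(hexes)),
                              i = rep(rep(1:na, each = n * nt), 1)),
    geom = list(R = R, t = t, length = len), res = list(n = n, n_thickness = nt),
    kind = "cylinder"), class = "volume_mesh")
  mesh <- .orient_mesh(mesh)
  mesh <- assign_fiber_orientations(mesh)
  .check_mesh_quality(mesh)
  mesh
}

#' Configuration for the synthetic AFM force-map generator
#'
#' Defaults emulate the acquisition settings of the real instrument: 45 N/m
#' cantilever, 250 nN force setpoint, and a 16x16 desk-scale grid (the
#' instrument's 128x128 is available by config).
#'
#' @param shape grid shape, c(rows, cols).
#' @param scan_size scan edge length, um.
#' @param k_c cantilever stiffness, N/m (= nN/nm).
#' @param sensitivity deflection sensitivity, nm/V.
#' @param tilt baseline tilt slope, nN per nm of piezo travel.
#' @param noise Gaussian deflection noise s.d. as a fraction of the setpoint
#'   force.
#' @param setpoint approach force setpoint, nN.
#' @param z_range piezo travel, nm.
#' @param dz piezo sampling step, nm (default 0.5, a few thousand
#'   samples per curve as on the real instrument).
#' @param z0 contact position along the piezo axis, nm.
#' @param alpha pyramidal indenter face half-angle, degrees.
#' @param nu sample Poisson ratio.
#' @param seed integer RNG seed, recorded in output metadata.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(shape = c(16, 16), scan_size = 100, k_c = 45,
                         sensitivity = 50, tilt = 0, noise = 0.02,
                         setpoint = 250, z_range = 4000, dz = 0.5, z0 = 500,
                         alpha = 20, nu = 0.5, seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 1), scan_size > 0, k_c > 0,
            sensitivity > 0, noise >= 0, setpoint > 0, z_range > z0, dz > 0,
            alpha > 0, alpha < 90, nu >= 0, nu < 1)
  structure(list(shape = as.integer(shape), scan_size = scan_size, k_c = k_c,
                 sensitivity = sensitivity, tilt = tilt, noise = noise,
                 setpoint = setpoint, z_range = z_range, dz = dz, z0 = z0,
                 alpha = alpha, nu = nu, seed = as.integer(seed)),
            class = "synth_config")
}

#' Stoma-shaped ground-truth modulus field
#'
#' An elliptical annulus (the guard-cell pair in plan view) at `E_guard` on
#' an `E_pavement` background; pixels inside the pore ellipse are background.
#'
#' @param shape grid shape, c(rows, cols).
#' @param E_guard guard-cell ring modulus, MPa.
#' @param E_pavement background modulus, MPa.
#' @param outer_semi outer (complex outline) ellipse semi-axes as fractions
#'   of the grid extent, c(along-rows, along-cols).
#' @param pore_semi pore ellipse semi-axes, same units.
#' @return List with `E` (matrix, MPa) and `labels` (matrix, "guard" /
#'   "pavement").
#' @export
make_stoma_modulus_field <- function(shape, E_guard, E_pavement,
                                     outer_semi = c(0.42, 0.28),
                                     pore_semi = c(0.2, 0.08)) {
  stopifnot(E_guard > 0, E_pavement > 0, all(outer_semi > pore_semi))
  nr <- shape[1]; nc <- shape[2]
  rr <- (row(matrix(0, nr, nc)) - (nr + 1) / 2) / nr
  cc <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) / nc
  inside <- function(semi) (rr / semi[1])^2 + (cc / semi[2])^2 <= 1
  ring <- inside(outer_semi) & !inside(pore_semi)
  if (!any(ring)) stop("guard-cell annulus not representable on this grid")
  E <- matrix(E_pavement, nr, nc)
  E[ring] <- E_guard
  labels <- matrix("pavement", nr, nc)
  labels[ring] <- "guard"
  list(E = E, labels = labels)
}

# pyramidal-indenter force constant, nN/nm^2 for E in MPa
# (1 MPa = 1e-3 nN/nm^2; documented shared constant of the forward model)
.hertz_A <- function(E, alpha, nu) {
  (tan(alpha * pi / 180) / sqrt(2)) * (E * 1e-3) / (1 - nu^2)
}

#' Synthesize one raw force-distance curve
#'
#' Forward model: pyramidal Hertz contact `F = A * delta^2`, cantilever
#' bending coupling `z = z0 + delta + F/k_c`, deflection read out in volts
#' with optional baseline tilt and seeded Gaussian noise, approach terminated
#' at the force setpoint.
#'
#' @param E sample modulus, MPa (ignored if `rigid`).
#' @param cfg a [synth_config()].
#' @param rigid simulate hard (glass) contact: zero indentation.
#' @param z0 contact position override, nm.
#' @param seed RNG seed override.
#' @return A [force_curve()] whose `truth` attribute records E, z0 and the
#'   noise-free (indentation, force) pairs.
#' @export
synth_force_curve <- function(E, cfg, rigid = FALSE, z0 = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!rigid && E <= 0) stop("E must be positive")
  z0 <- if (is.null(z0)) cfg$z0 else z0
  seed <- if (is.null(seed)) cfg$seed else seed
  z <- seq(0, cfg$z_range, by = cfg$dz)
  over <- pmax(z - z0, 0)
  if (rigid) {
    delta <- rep(0, length(z))
    F <- cfg$k_c * over
  } else {
    A <- .hertz_A(E, cfg$alpha, cfg$nu)
    q <- A / cfg$k_c
    delta <- (-1 + sqrt(1 + 4 * q * over)) / (2 * q)
    F <- A * delta^2
  }
  if (max(F) < cfg$setpoint) {
    stop("setpoint ", cfg$setpoint, " nN unreachable within the piezo range")
  }
  last <- which(F >= cfg$setpoint)[1]
  keep <- seq_len(last)
  z <- z[keep]; F <- F[keep]; delta <- delta[keep]
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  noise_V <- withr_seed(stats::rnorm(length(z), 0,
                                     cfg$noise * cfg$setpoint / (cfg$k_c * cfg$sensitivity)))
  V <- F / (cfg$k_c * cfg$sensitivity) + cfg$tilt * z / (cfg$k_c * cfg$sensitivity) +
    noise_V
  fc <- force_curve(z, V, k_c = cfg$k_c, sensitivity = cfg$sensitivity)
  attr(fc, "truth") <- list(E = E, z0 = z0, delta = delta, force = F,
                            rigid = rigid, seed = seed)
  fc
}

#' Synthesize a full force map with ground truth
#'
#' One curve per pixel with a per-pixel seed derived from `(seed, i, j)`, so
#' regeneration from the same config is bit-identical.
#'
#' @param field output of [make_stoma_modulus_field()] (or any list with an
#'   `E` matrix and optional `labels`).
#' @param cfg a [synth_config()]; `cfg$shape` must match `dim(field$E)`.
#' @return A `force_map`: list of curves (row-major), grid shape, scan size,
#'   calibration metadata, and a `ground_truth` bundle (E, z0, labels, seed).
#' @export
synth_force_map <- function(field, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  E <- field$E
  if (!all(dim(E) == cfg$shape)) stop("field shape does not match cfg$shape")
  curves <- vector("list", length(E))
  for (i in seq_len(nrow(E))) for (j in seq_len(ncol(E))) {
    px_seed <- cfg$seed + (i - 1L) * ncol(E) + (j - 1L)
    idx <- (i - 1L) * ncol(E) + j
    curves[[idx]] <- tryCatch(
      synth_force_curve(E[i, j], cfg, seed = px_seed),
      error = function(e) stop("pixel (", i, ",", j, "): ",
                               conditionMessage(e), call. = FALSE))
  }
  structure(list(curves = curves, shape = cfg$shape, scan_size = cfg$scan_size,
                 k_c = cfg$k_c, sensitivity = cfg$sensitivity,
                 ground_truth = list(E = E, z0 = cfg$z0,
                                     labels = field$labels, seed = cfg$seed)),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("force_map: %d x %d curves over %g x %g um\n",
              x$shape[1], x$shape[2], x$scan_size, x$scan_size))
  invisible(x)
}

#' Write a force map as TSV curve tables plus JSON metadata
#'
#' One `curve_<i>_<j>.tsv` (columns piezo_nm, deflection_V) per pixel and a
#' `map.json` sidecar with grid geometry, calibration and ground truth.
#'
#' @param map a `force_map`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_force_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(map$shape[1])) for (j in seq_len(map$shape[2])) {
    cv <- map$curves[[(i - 1L) * map$shape[2] + j]]
    utils::write.table(
      data.frame(piezo_nm = sprintf("%.17g", cv$piezo_height),
                 deflection_V = sprintf("%.17g", cv$deflection)),
      file.path(dir, sprintf("curve_%03d_%03d.tsv", i, j)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- list(shape = map$shape, scan_size = map$scan_size, k_c = map$k_c,
               sensitivity = map$sensitivity)
  if (!is.null(map$ground_truth)) {
    gt <- map$ground_truth
    meta$ground_truth <- list(E = as.vector(gt$E), z0 = gt$z0,
                              labels = as.vector(gt$labels), seed = gt$seed)
  }
  jsonlite::write_json(meta, file.path(dir, "map.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a force map written by [write_force_map()]
#' @param dir directory containing curve TSVs and `map.json`.
#' @return A `force_map`.
#' @export
read_force_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "map.json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  curves <- vector("list", prod(shape))
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    d <- utils::read.table(file.path(dir, sprintf("curve_%03d_%03d.tsv", i, j)),
                           header = TRUE, sep = "\t")
    curves[[(i - 1L) * shape[2] + j]] <-
      force_curve(d$piezo_nm, d$deflection_V, k_c = meta$k_c,
                  sensitivity = meta$sensitivity)
  }
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- list(E = matrix(meta$ground_truth$E, shape[1], shape[2]),
               z0 = meta$ground_truth$z0,
               labels = matrix(meta$ground_truth$labels, shape[1], shape[2]),
               seed = meta$ground_truth$seed)
  }
  structure(list(curves = curves, shape = shape, scan_size = meta$scan_size,
                 k_c = meta$k_c, sensitivity = meta$sensitivity,
                 ground_truth = gt), class = "force_map")
}
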