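test_that("stoma_geometry enforces its invariants", {
  expect_s3_class(desk_geom(), "stoma_geometry")
  expect_error(stoma_geometry(24, 25, 2.4, 6), "pore_length")
  expect_error(stoma_geometry(24, 12, 2.4, 6, wall_thickness = 3.5), "wall_thickness")
  expect_error(stoma_geometry(24, 12, -1, 6), "positive")
})

test_that("midline is circular when pore and complex outlines are circles", {
  # pore 6 x 6 and complex 20 x 20 (gc_width = 7): both circular, so the
  # averaged midline is a circle
  g <- stoma_geometry(20, 6, 6, 7)
  ml <- build_midline(g, "left", n = 400)
  r <- sqrt(ml[, 1]^2 + ml[, 2]^2)
  expect_lt(diff(range(r)), 1e-9)
})

test_that("left and right midlines are mirror images across the long axis", {
  g <- stoma_geometry(30, 15, 5, 7)
  l <- build_midline(g, "left")
  r <- build_midline(g, "right")
  expect_equal(l[, 1], r[, 1], tolerance = 1e-12)
  expect_equal(l[, 2], -r[, 2], tolerance = 1e-12)
})

test_that("midline endpoints match a brute-force ellipse interpolation", {
  g <- stoma_geometry(30, 15, 5, 7)
  # oracle: sample pore and complex outline ellipses at 1e4 parameter values,
  # average pointwise, take the extreme x
  th <- seq(0, pi, length.out = 1e4)
  pore <- cbind(7.5 * cos(th), 2.5 * sin(th))
  comp <- cbind(15 * cos(th), 9.5 * sin(th))
  mid_oracle <- (pore + comp) / 2
  ml <- build_midline(g, "left", n = 1e4)
  expect_equal(max(ml[, 1]), max(mid_oracle[, 1]), tolerance = 1e-9)
  expect_equal(max(ml[, 1]), (15 / 2 + 30 / 2) / 2, tolerance = 1e-12)
  expect_equal(max(abs(ml[, 1:2] - mid_oracle)), 0, tolerance = 1e-9)
})

test_that("mesh element counts follow the resolution arithmetic", {
  g <- desk_geom()
  m <- generate_mesh(g, mesh_resolution(16, 12, 1))
  tube <- m$element_region != "polar"
  expect_equal(sum(tube), 2 * 16 * 12 * 1)
  m2 <- generate_mesh(g, mesh_resolution(32, 24, 2))
  expect_equal(sum(m2$element_region != "polar"), 8 * sum(tube))
})

test_that("outer wall mesh area matches a quadrature oracle of the swept surface", {
  g <- desk_geom()
  res <- mesh_resolution(24, 16, 1)
  m <- generate_mesh(g, res)
  # oracle: 10x-resolution numerical quadrature of the parametric outer
  # surface of one cell, via the same triangulated area measure
  nt <- 240; np <- 160
  th <- seq(0, pi, length.out = nt + 1)
  ph <- 2 * pi * (0:(np - 1)) / np
  pts <- function(i) stomech:::.gc_point(g, rep(th[i], np), ph, rep(0, np), 1)
  area <- 0
  prev <- pts(1)
  for (i in 2:(nt + 1)) {
    cur <- pts(i)
    for (j in 1:np) {
      jp <- j %% np + 1
      a <- prev[j, ]; b <- cur[j, ]; cc <- cur[jp, ]; d <- prev[jp, ]
      area <- area +
        0.5 * sqrt(sum(stomech:::.cross3(b - a, cc - a)^2)) +
        0.5 * sqrt(sum(stomech:::.cross3(cc - a, d - a)^2))
    }
    prev <- cur
  }
  expect_equal(outer_surface_area(m), 2 * area, tolerance = 0.02)
})

test_that("mesh is symmetric, well oriented, and closed", {
  m <- desk_mesh()
  nc <- m$node_coords
  key <- function(p) sort(paste(round(p[, 1], 6), round(p[, 2], 6), round(p[, 3], 6)))
  expect_identical(key(nc), key(cbind(nc[, 1], -nc[, 2], nc[, 3])))
  expect_identical(key(nc), key(cbind(-nc[, 1], nc[, 2], nc[, 3])))
  expect_gt(min(stomech:::hex_jacobians(nc, m$hex_connectivity)), 0)
  v1 <- lumen_volume(m, 1); v2 <- lumen_volume(m, 2)
  expect_gt(v1, 0)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("fixed nodes are nonempty and confined to the polar wall regions", {
  m <- desk_mesh()
  expect_gt(length(m$fixed_nodes), 0)
  polar_els <- which(m$element_region == "polar")
  polar_nodes <- unique(as.integer(m$hex_connectivity[polar_els, ]))
  # fixed set = polar element nodes plus the two lumen cap centres
  extra <- setdiff(m$fixed_nodes, polar_nodes)
  expect_lte(length(extra), 2)
  ax <- stomech:::.gc_axes(m$geom)
  expect_true(all(abs(abs(nc <- m$node_coords[extra, 1]) - ax$a_m) < 1e-9))
  # and all fixed nodes live near the two poles (|y| small)
  expect_lt(max(abs(m$node_coords[m$fixed_nodes, 2])),
            m$geom$polar_wall_thickness / 2 + 1e-9)
})

test_that("fiber directions are unit hoop vectors perpendicular to the midline", {
  m <- desk_mesh()
  expect_lt(max(abs(sqrt(rowSums(m$fiber_dirs^2)) - 1)), 1e-9)
  md <- m$element_meta
  tube <- which(md$cell != 0)
  ax <- stomech:::.gc_axes(m$geom)
  set.seed(7)
  for (e in sample(tube, 40)) {
    s <- if (md$cell[e] == 1) 1 else -1
    th <- md$theta[e]
    # midline tangent by central finite difference of the curve
    h <- 1e-6
    mpt <- function(t) c(ax$a_m * cos(t), s * ax$b_m * sin(t), 0)
    tg <- (mpt(th + h) - mpt(th - h)) / (2 * h)
    tg <- tg / sqrt(sum(tg^2))
    expect_lt(abs(sum(m$fiber_dirs[e, ] * tg)), 1e-9)
  }
})

test_that("fibers on a straight cylinder are perpendicular to its axis", {
  m <- benchmark_shell_mesh("cylinder", R = 5, t = 0.1, n = 12, length = 20)
  expect_lt(max(abs(m$fiber_dirs[, 1])), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(m$fiber_dirs^2)) - 1)), 1e-9)
})

test_that("outer area and lumen volume converge under refinement", {
  # quadratic convergence: the change per doubling shrinks monotonically and
  # falls below 1% at the finer levels
  g <- desk_geom()
  meshes <- lapply(list(c(16, 12), c(32, 24), c(64, 48)), function(r)
    generate_mesh(g, mesh_resolution(r[1], r[2], 1)))
  a <- vapply(meshes, outer_surface_area, numeric(1))
  v <- vapply(meshes, lumen_volume, numeric(1), surface = 1)
  da <- abs(diff(a)) / a[-1]
  dv <- abs(diff(v)) / v[-1]
  expect_lt(da[2], da[1])
  expect_lt(dv[2], dv[1])
  expect_lt(da[2], 0.01)
  expect_lt(dv[2], 0.01)
})

test_that("degenerate geometry is rejected at mesh time or construction", {
  # wall thicker than the thinnest cross-section semi-axis
  expect_error(stoma_geometry(30, 28, 5, 7, wall_thickness = 1.2), "pore too wide")
})
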