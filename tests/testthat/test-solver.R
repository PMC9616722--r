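test_that("load_program validates its invariants", {
  expect_s3_class(load_program(), "load_program")
  expect_error(load_program(P_max = 5, dP_init = 1, dP_max = 0.5), "dP")
  expect_error(load_program(newton_tol = 0.1), "newton_tol")
})

test_that("zero load gives a single zero-displacement state", {
  m <- tiny_shell()
  mat <- wall_material(1, 2, 0, 1e3)
  ramp <- solve_pressure_ramp(m, mat, load_program(P_max = 0, dP_init = 0.1))
  expect_length(ramp, 1)
  expect_equal(max(abs(ramp[[1]]$displacements)), 0)
})

test_that("the reference state is in equilibrium and translations are zero modes", {
  m <- tiny_shell()
  mat <- wall_material(1, 2, 0.5, 1e3)
  U0 <- matrix(0, nrow(m$node_coords), 3)
  r0 <- assemble_residual(m, mat, U0, 0)
  expect_lt(max(abs(r0$f_int)), 1e-12)
  Ut <- matrix(rep(c(0.3, -0.2, 0.15), each = nrow(m$node_coords)), ncol = 3)
  rt <- assemble_residual(m, mat, Ut, 0)
  expect_lt(max(abs(rt$f_int)), 1e-10)
})

test_that("assembled residual equals the finite-difference potential gradient", {
  m <- tiny_shell()
  mat <- wall_material(1, 2, 0.5, 1e3)
  n <- nrow(m$node_coords)
  set.seed(31)
  U <- matrix(rnorm(3 * n, 0, 0.01), n, 3)
  P <- 0.02
  r <- assemble_residual(m, mat, U, P)
  pot <- function(UU) assemble_residual(m, mat, UU, P)$potential
  h <- 1e-5
  free <- which(as.vector(t(stomech:::free_dof_mask(m))))
  sampled <- sample(free, 40)
  scale <- max(abs(r$residual))
  for (d in sampled) {
    Up <- U; Um <- U
    i <- (d - 1) %/% 3 + 1; j <- (d - 1) %% 3 + 1
    Up[i, j] <- Up[i, j] + h
    Um[i, j] <- Um[i, j] - h
    fd <- (pot(Up) - pot(Um)) / (2 * h)
    expect_lt(abs(fd - r$residual[d]) / scale, 1e-6)
  }
})

test_that("element force is covariant under rigid rotation of the element", {
  # regression guard for isoparametric-gradient frame errors: a skewed curved
  # element rotated rigidly must produce rigidly rotated nodal forces
  th <- 2 * pi / 16
  Rm <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  phi0 <- c(0, th)
  Xe <- NULL
  for (k in c(4.95, 5.05)) for (j in 1:2) for (i in 0:1) {
    Xe <- rbind(Xe, c(2 * i, k * cos(phi0[j]), k * sin(phi0[j])))
  }
  Xe <- Xe[c(1, 3, 4, 2, 5, 7, 8, 6), ]
  set.seed(2)
  Ue <- matrix(rnorm(24, 0, 1e-3), 8, 3)
  fone <- function(X, U, a0) {
    stomech:::fe_assemble(X, matrix(1:8, 1), matrix(a0, 1), c(50, 2, 10, 1e5),
                          U, NULL, NULL, 0, FALSE)$f_int
  }
  f1 <- matrix(fone(Xe, Ue, c(0, 0, 1)), ncol = 3, byrow = TRUE)
  f2 <- matrix(fone(Xe %*% t(Rm), Ue %*% t(Rm), drop(Rm %*% c(0, 0, 1))),
               ncol = 3, byrow = TRUE)
  expect_lt(max(abs(f2 - f1 %*% t(Rm))) / max(abs(f1)), 1e-9)
})

test_that("follower pressure on a closed surface has zero resultant", {
  for (fix in list(sphere_benchmark(), cylinder_benchmark())) {
    m <- fix$mesh
    st <- fix$state
    r <- assemble_residual(m, fix$mat, st$displacements, 0.01)
    fx <- matrix(r$f_ext, ncol = 3, byrow = TRUE)
    area <- sum(abs(fx)) / 0.01   # ~ loaded area scale
    expect_lt(max(abs(colSums(fx))), 1e-8 * 0.01 * area)
  }
})

test_that("pressurized thin sphere reproduces the Laplace stress p R / (2 t)", {
  fix <- sphere_benchmark()
  vm <- fix$fields$eff_stress
  expect_equal(mean(vm), 0.01 * 10 / (2 * 0.1), tolerance = 0.05)
  expect_lt(max(abs(fix$fields$J_bar - 1)), 1e-4)
})

test_that("pressurized capped cylinder reproduces the hoop stress p R / t", {
  fix <- cylinder_benchmark()
  m <- fix$mesh
  cent <- element_centroids(m)
  mid <- which(abs(cent[, 1]) < 5)       # away from the clamped ends
  hoop <- vapply(mid, function(e) {
    h <- m$fiber_dirs[e, ]
    drop(h %*% sym_from6(fix$fields$sigma[e, ]) %*% h)
  }, numeric(1))
  expect_equal(mean(hoop), 0.01 * 5 / 0.1, tolerance = 0.05)
})

test_that("sphere inflation is isotropic: extents equal in all axes", {
  fix <- sphere_benchmark()
  def <- fix$mesh$node_coords + fix$state$displacements
  ext <- apply(def, 2, function(v) max(v) - min(v))
  expect_lt(diff(range(ext)) / mean(ext), 1e-6)
})

test_that("quasi-static path is insensitive to the initial step size", {
  m <- desk_mesh()
  mat <- default_genotype_set()$materials$control
  a1 <- {
    r <- solve_pressure_ramp(m, mat, load_program(P_max = 1.5, dP_init = 0.05,
                                                  dP_max = 0.3))
    measure_pore(r[[length(r)]], m)$aperture
  }
  a2 <- {
    r <- solve_pressure_ramp(m, mat, load_program(P_max = 1.5, dP_init = 0.025,
                                                  dP_max = 0.3))
    measure_pore(r[[length(r)]], m)$aperture
  }
  expect_lt(abs(a1 - a2) / a1, 0.005)
})

test_that("aperture is mesh-converged at desk resolution", {
  mat <- default_genotype_set()$materials$control
  lp <- load_program(P_max = 1.5, dP_init = 0.05, dP_max = 0.3)
  a1 <- {
    m <- desk_mesh()
    r <- solve_pressure_ramp(m, mat, lp)
    measure_pore(r[[length(r)]], m)$aperture
  }
  a2 <- {
    m <- generate_mesh(desk_geom(), mesh_resolution(48, 32, 1))
    r <- solve_pressure_ramp(m, mat, lp)
    measure_pore(r[[length(r)]], m)$aperture
  }
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("non-convergence below dP_min signals a partial result with states", {
  # absurdly tight Newton budget forces failure immediately
  m <- tiny_shell()
  mat <- wall_material(1, 2, 0, 1e3)
  cond <- tryCatch(
    solve_pressure_ramp(m, mat, load_program(P_max = 1, dP_init = 0.5,
                                             dP_min = 0.4, dP_max = 0.5,
                                             newton_max_iter = 1)),
    stomech_partial_result = function(c) c)
  expect_s3_class(cond, "stomech_partial_result")
  expect_s3_class(cond$states, "pressure_ramp")
  expect_equal(cond$states[[1]]$pressure, 0)
})
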