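test_that("wall_material validates its parameter ranges", {
  expect_s3_class(wall_material(1, 2, 0, 1e4), "wall_material")
  expect_error(wall_material(-1, 2, 0, 1e4), "C1")
  expect_error(wall_material(1, 0, 0, 1e4), "C2")
  expect_error(wall_material(1, 2, -1, 1e4), "C5")
  expect_error(wall_material(1, 2, 0, 100), "K_bulk")
  expect_error(deformation_state(diag(c(1, 1, -1))), "det")
})

test_that("strain energy vanishes at the reference state and under rotation", {
  mat <- wall_material(0.5, 2, 3, 1e3)
  expect_equal(strain_energy(deformation_state(diag(3)), mat), 0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(abs(strain_energy(deformation_state(R, c(0, 1, 0)), mat)), 1e-12)
})

test_that("strain energy matches term-by-term evaluation from the invariants", {
  # isochoric uniaxial F = diag(l, 1/sqrt(l), 1/sqrt(l)); invariants in closed
  # form: I1 = l^2 + 2/l, I2 = 2l + 1/l^2, J = 1
  l <- 1.1
  F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
  mat <- wall_material(0.5, 2, 0, 1e4)
  I1 <- l^2 + 2 / l
  I2 <- 2 * l + 1 / l^2
  W_expect <- 0.5 * (exp(2 * (I1 - 3)) - 1) - (0.5 * 2 / 2) * (I2 - 3)
  st <- deformation_state(F, a0 = c(0, 1, 0))
  expect_equal(st$J, 1, tolerance = 1e-12)
  expect_equal(st$I1_bar, I1, tolerance = 1e-12)
  expect_equal(st$I2_bar, I2, tolerance = 1e-12)
  expect_equal(strain_energy(st, mat), W_expect, tolerance = 1e-12)
})

test_that("Cauchy stress is zero at the reference and matches the energy gradient", {
  mat <- wall_material(0.5, 2, 3, 1e3)
  expect_lt(max(abs(cauchy_stress(deformation_state(diag(3), c(1, 0, 0)), mat))),
            1e-12)
  set.seed(11)
  for (rep in 1:4) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.04), 3)
    if (det(F) <= 0) next
    a0 <- rnorm(3); a0 <- a0 / sqrt(sum(a0^2))
    sig <- cauchy_stress(deformation_state(F, a0), mat)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    h <- 1e-7
    P_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P_fd[i, j] <- (strain_energy(deformation_state(Fp, a0), mat) -
                     strain_energy(deformation_state(Fm, a0), mat)) / (2 * h)
    }
    sig_fd <- P_fd %*% t(F) / det(F)
    expect_lt(max(abs(sig - sig_fd)) / max(abs(sig)), 1e-6)
  }
})

test_that("small-strain modulus is 3*C1*C2 and linear in C1", {
  expect_equal(small_strain_modulus(wall_material(0.5, 2, 0, 1e4)), 3)
  expect_equal(small_strain_modulus(wall_material(1, 1, 0, 1e4)), 3)
  expect_equal(small_strain_modulus(wall_material(1, 2, 0, 1e4)),
               2 * small_strain_modulus(wall_material(0.5, 2, 0, 1e4)))
})

test_that("uniaxial lateral-contraction solve reproduces E = 3 C1 C2", {
  mat <- wall_material(0.5, 2, 0, 1e4)
  # central difference across the reference removes the quadratic correction
  up <- uniaxial_modulus(mat, lambda = 1.0005)
  dn <- uniaxial_modulus(mat, lambda = 0.9995)
  E <- (up$stress - dn$stress) / 0.001
  expect_equal(E, 3, tolerance = 0.01)
})

test_that("uniform volume scaling changes only the volumetric energy term", {
  mat  <- wall_material(0.8, 5, 10, 1e4)
  mat0 <- wall_material(0.8, 5, 10, 1e4)
  set.seed(21)
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
    if (det(F) <= 0) next
    a0 <- c(1, 0, 0)
    c_scl <- 1.02
    W1 <- strain_energy(deformation_state(F, a0), mat)
    W2 <- strain_energy(deformation_state(c_scl * F, a0), mat)
    J1 <- det(F); J2 <- det(c_scl * F)
    dvol <- 0.5 * 1e4 * (log(J2)^2 - log(J1)^2)
    expect_equal(W2 - W1, dvol, tolerance = 1e-9 * max(1, abs(W1)))
  }
})

test_that("tangent stiffness is nondecreasing in isochoric uniaxial stretch", {
  mat <- wall_material(0.8, 5, 0, 1e4)
  sig_axial <- function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    cauchy_stress(deformation_state(F, c(0, 1, 0)), mat)[1, 1]
  }
  ls <- seq(1, 1.4, by = 0.02)
  tang <- diff(sapply(ls, sig_axial)) / diff(ls)
  expect_true(all(diff(tang) > -1e-9))
})

test_that("fibers are inactive in compression", {
  with_f <- wall_material(0.5, 2, 50, 1e4)
  no_f   <- wall_material(0.5, 2, 0, 1e4)
  F <- diag(c(0.97, 1.02, 1.015))   # fiber direction shortened
  a0 <- c(1, 0, 0)
  expect_equal(cauchy_stress(deformation_state(F, a0), with_f),
               cauchy_stress(deformation_state(F, a0), no_f), tolerance = 1e-14)
  # and active in tension
  Ft <- diag(c(1.03, 0.99, 0.985))
  expect_gt(max(abs(cauchy_stress(deformation_state(Ft, a0), with_f) -
                    cauchy_stress(deformation_state(Ft, a0), no_f))), 1e-6)
})

test_that("effective Poisson ratio approaches 1/2 as K grows", {
  lam <- 1.001
  for (K in c(1e4, 1e6)) {
    mat <- wall_material(0.5, 2, 0, K)
    lat <- uniaxial_modulus(mat, lambda = lam)$lateral_stretch
    nu <- -(lat - 1) / (lam - 1)
    expect_lt(abs(nu - 0.5), if (K >= 1e6) 1e-3 else 2e-2)
  }
})
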