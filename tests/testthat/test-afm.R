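# shared pipeline fixtures: curves come from the seeded synthetic generator
afm_cfg <- function(noise = 0, ...) {
  synth_config(shape = c(4, 4), noise = noise, seed = 101, ...)
}

test_that("force_curve validates its inputs", {
  expect_error(force_curve(1:10, 1:10, 45, 50), "50 samples")
  expect_error(force_curve(1:60, 1:59, 45, 50), "equal length")
  expect_error(force_curve(1:60, 1:60, -1, 50), "positive")
})

test_that("glass-curve calibration recovers the deflection sensitivity", {
  cfg <- afm_cfg()
  glass <- synth_force_curve(Inf, cfg, rigid = TRUE)
  # generating slope in contact is 1/sensitivity = 0.02 V/nm
  expect_equal(calibrate_sensitivity(glass), 50, tolerance = 1e-6)
  cfgn <- afm_cfg(noise = 0.01)
  glass_n <- synth_force_curve(Inf, cfgn, rigid = TRUE)
  expect_equal(calibrate_sensitivity(glass_n), 50, tolerance = 0.02)
  flat <- force_curve(seq(0, 1000, by = 2), rep(0, 501), k_c = 45,
                      sensitivity = 50)
  expect_error(calibrate_sensitivity(flat), "no detectable contact")
})

test_that("preprocessing converts units and removes baseline tilt", {
  # unit arithmetic: 1 V at 50 nm/V on a 45 N/m lever is 2250 nN
  z <- seq(0, 1000, by = 2)
  v <- ifelse(z < 800, 0, 1)
  corr <- preprocess_curve(force_curve(z, v, k_c = 45, sensitivity = 50))
  expect_equal(max(corr$force), 2250, tolerance = 1e-9)
  # already-flat curve is unchanged
  cfg <- afm_cfg()
  cv <- synth_force_curve(2, cfg)
  c1 <- preprocess_curve(cv)
  c2 <- preprocess_curve(force_curve(c1$z, c1$force / (45 * 50), 45, 50))
  expect_lt(max(abs(c2$force - c1$force)), 1e-9)
  # tilt of 0.005 nN/nm is removed to < 0.05 nN in the pre-contact region
  cvt <- synth_force_curve(2, afm_cfg(tilt = 0.005))
  ct <- preprocess_curve(cvt)
  pre <- ct$z < 450
  expect_lt(mean(abs(ct$force[pre])), 0.05)
})

test_that("indentation subtracts cantilever bending from piezo travel", {
  # rigid surface: all piezo travel goes into bending, none into the sample
  z <- seq(0, 1000, by = 2)
  z0 <- 500
  Fr <- pmax(z - z0, 0) * 45
  corr <- structure(list(z = z, force = Fr, baseline_sd = 0, k_c = 45, qc = TRUE),
                    class = "corrected_curve")
  di <- compute_indentation(corr, z0)
  expect_lt(max(di$delta), 1e-9)
  # null force: free travel
  corr0 <- structure(list(z = z, force = rep(0, length(z)), baseline_sd = 0,
                          k_c = 45, qc = TRUE), class = "corrected_curve")
  di0 <- compute_indentation(corr0, z0)
  expect_equal(di0$delta, z[z >= z0] - z0)
  expect_error(compute_indentation(corr, 2000), "outside")
})

test_that("pipeline recovers the generator's indentation-force pairs", {
  cfg <- afm_cfg()
  cv <- synth_force_curve(2, cfg)
  truth <- attr(cv, "truth")
  corr <- preprocess_curve(cv)
  zc <- detect_contact(corr)
  di <- compute_indentation(corr, zc)
  # align by force level: compare recovered delta at the truth samples
  sel <- truth$force > 5
  rec <- stats::approx(di$force, di$delta, truth$force[sel])$y
  expect_lt(max(abs(rec - truth$delta[sel]), na.rm = TRUE), 0.5)
  recF <- stats::approx(di$delta, di$force, truth$delta[sel])$y
  expect_lt(max(abs(recF / truth$force[sel] - 1), na.rm = TRUE), 0.005)
})

test_that("Hertz fit recovers the generating modulus and point force", {
  cfg <- afm_cfg()
  for (E in c(0.5, 2, 10)) {
    cv <- synth_force_curve(E, cfg)
    corr <- preprocess_curve(cv)
    di <- compute_indentation(corr, detect_contact(corr))
    fit <- fit_hertz(di)
    expect_true(fit$qc_pass)
    expect_equal(fit$E_a, E, tolerance = 0.01)
  }
  # direct arithmetic: F(100 nm) at E = 2 MPa, nu = 0.5, alpha = 20 deg
  A <- (tan(20 * pi / 180) / sqrt(2)) * (2e-3 / (1 - 0.25))
  expect_equal(A * 100^2, 6.86, tolerance = 0.001)
  truth <- attr(synth_force_curve(2, cfg), "truth")
  F100 <- stats::approx(truth$delta, truth$force, 100)$y
  expect_equal(F100, 6.86, tolerance = 0.001)
  # doubling E doubles the fitted modulus
  fitE <- function(E) {
    cv <- synth_force_curve(E, cfg)
    corr <- preprocess_curve(cv)
    fit_hertz(compute_indentation(corr, detect_contact(corr)))$E_a
  }
  expect_equal(fitE(4) / fitE(2), 2, tolerance = 0.01)
})

test_that("Hertz fit flags degenerate inputs instead of failing", {
  few <- data.frame(delta = c(1, 2, 3), force = c(1, 2, 3))
  fit <- fit_hertz(few)
  expect_false(fit$qc_pass)
  expect_equal(fit$n_points, 0L)
})

test_that("force-map processing recovers uniform and structured fields", {
  cfg <- synth_config(shape = c(8, 8), noise = 0, seed = 5)
  uni <- synth_force_map(list(E = matrix(1, 8, 8)), cfg)
  res <- process_force_map(uni)
  expect_equal(res$n_failed, 0)
  expect_lt(max(abs(res$E_a - 1)), 0.01)
  # all-flat curves: fully masked, never fatal
  flatc <- force_curve(seq(0, 1000, by = 2), rep(0, 501), 45, 50)
  flat_map <- structure(list(curves = rep(list(flatc), 16), shape = c(4L, 4L),
                             scan_size = 100, k_c = 45, sensitivity = 50,
                             ground_truth = NULL), class = "force_map")
  resf <- process_force_map(flat_map)
  expect_equal(sum(resf$qc), 0)
  expect_true(all(is.na(resf$E_a)))
})

test_that("stoma-annulus stiffness contrast is recovered", {
  cfg <- synth_config(shape = c(16, 16), noise = 0.02, seed = 42)
  fld <- make_stoma_modulus_field(c(16, 16), E_guard = 4, E_pavement = 1)
  map <- synth_force_map(fld, cfg)
  res <- process_force_map(map)
  st <- region_stats(res$E_a, map$ground_truth$labels, res$qc)
  ring <- stats::median(res$E_a[fld$labels == "guard" & res$qc], na.rm = TRUE)
  bg <- stats::median(res$E_a[fld$labels == "pavement" & res$qc], na.rm = TRUE)
  expect_equal(ring / bg, 4, tolerance = 0.15)
  expect_true(all(!st$empty))
})

test_that("region statistics match hand computation and flag empty regions", {
  Ea <- matrix(c(1, 1, 3, 3, 2, 2), 2, 3)
  labs <- matrix(c("a", "a", "a", "a", "b", "b"), 2, 3)
  st <- region_stats(Ea, labs)
  expect_equal(st$mean, c(2, 2))
  expect_equal(st$sem[st$region == "a"], sqrt(4 / 3) / 2, tolerance = 1e-12)
  expect_equal(st$sem[st$region == "b"], 0)
  expect_equal(st$n, c(4L, 2L))
  # single constant region
  st1 <- region_stats(matrix(2, 3, 3), matrix("g", 3, 3))
  expect_equal(st1$mean, 2); expect_equal(st1$sem, 0)
  # fully masked region is marked empty, not zero
  qc <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  st2 <- region_stats(Ea, labs, qc)
  expect_true(st2$empty[st2$region == "b"])
  expect_true(is.na(st2$mean[st2$region == "b"]))
})

test_that("tightening QC stringency never unmasks a pixel", {
  cfg <- synth_config(shape = c(6, 6), noise = 0.03, seed = 17)
  map <- synth_force_map(list(E = matrix(2, 6, 6)), cfg)
  loose <- process_force_map(map, qc_rms_max = Inf, qc_min_points = 10)
  mid   <- process_force_map(map, qc_rms_max = 0.5, qc_min_points = 20)
  tight <- process_force_map(map, qc_rms_max = 0.1, qc_min_points = 40)
  expect_true(all(mid$qc <= loose$qc))
  expect_true(all(tight$qc <= mid$qc))
})

test_that("fitted moduli scale linearly with the true moduli", {
  cfg <- synth_config(shape = c(3, 3), noise = 0, seed = 9)
  E0 <- matrix(c(0.5, 1, 2, 5, 10, 1, 2, 5, 10), 3, 3)
  f1 <- process_force_map(synth_force_map(list(E = E0), cfg))
  f3 <- process_force_map(synth_force_map(list(E = 3 * E0), cfg))
  expect_lt(max(abs(f3$E_a / f1$E_a - 3)), 0.03)
})
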