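#' A raw AFM force-distance curve (approach segment)
#'
#' @param piezo_height piezo position, nm, increasing toward the surface.
#' @param deflection raw cantilever deflection, volts.
#' @param k_c cantilever stiffness, N/m (numerically equal to nN/nm).
#' @param sensitivity deflection sensitivity, nm/V.
#' @return Object of class `force_curve`.
#' @export
force_curve <- function(piezo_height, deflection, k_c, sensitivity) {
  if (length(piezo_height) != length(deflection)) {
    stop("piezo_height and deflection must have equal length")
  }
  if (length(piezo_height) < 50) stop("need at least 50 samples per curve")
  if (k_c <= 0 || sensitivity <= 0) stop("k_c and sensitivity must be positive")
  structure(list(piezo_height = as.numeric(piezo_height),
                 deflection = as.numeric(deflection),
                 k_c = k_c, sensitivity = sensitivity),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve: %d samples, z in [%g, %g] nm, k_c = %g N/m\n",
              length(x$piezo_height), min(x$piezo_height),
              max(x$piezo_height), x$k_c))
  invisible(x)
}

#' Calibrate deflection sensitivity on a glass (rigid-contact) curve
#'
#' On rigid glass the surface does not indent, so past contact the cantilever
#' deflection tracks the piezo 1:1 and the volts-vs-nm slope is the inverse
#' sensitivity.
#'
#' @param glass_curve a [force_curve()] acquired on clean glass.
#' @return Sensitivity, nm/V.
#' @export
calibrate_sensitivity <- function(glass_curve) {
  stopifnot(inherits(glass_curve, "force_curve"))
  v <- glass_curve$deflection
  z <- glass_curve$piezo_height
  nb <- max(10L, floor(length(v) * 0.3))
  base_sd <- stats::sd(v[seq_len(nb)])
  base_mu <- mean(v[seq_len(nb)])
  rise <- max(v) - base_mu
  if (!(rise > max(10 * base_sd, 1e-9))) {
    stop("no detectable contact region on the calibration curve")
  }
  # hard contact is linear end-to-end; use everything above 5% of the rise
  # (skips only the kink-straddling sample)
  sel <- which(v >= base_mu + 0.05 * rise)
  if (length(sel) < 4) stop("contact region too short for calibration")
  slope <- stats::coef(stats::lm(v[sel] ~ z[sel]))[2]
  if (!is.finite(slope) || slope <= 0) stop("invalid contact slope")
  unname(1 / slope)
}

#' Convert and baseline-correct a raw curve
#'
#' Force conversion `F = V * sensitivity * k_c` (nN), then subtraction of a
#' straight line fitted to the pre-contact baseline (first 50% of the
#' approach by default), which removes both offset and tilt.  The window is
#' validated by fitting the line on its head half and testing the mean
#' deviation of its tail from the extrapolation; a contact ramp inside the
#' window shifts that mean systematically and triggers shrinking (with a
#' warning).  If no stable window is found the curve is flagged
#' `qc = FALSE`.
#'
#' @param curve a [force_curve()].
#' @param baseline_frac initial baseline window as a fraction of the curve.
#' @param baseline_end optional explicit end of the baseline window (piezo
#'   position, nm); used to re-fit the baseline over all pre-contact data
#'   once the contact point is known precisely.
#' @return Object of class `corrected_curve`: `z` (nm), `force` (nN),
#'   `baseline_sd` (nN), `k_c`, `qc`.
#' @export
preprocess_curve <- function(curve, baseline_frac = 0.5, baseline_end = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$piezo_height
  Fraw <- curve$deflection * curve$sensitivity * curve$k_c
  n <- length(z)
  if (!is.null(baseline_end)) {
    win <- which(z <= baseline_end)
    if (length(win) < 10) stop("baseline window too short")
    fit <- stats::lm(Fraw[win] ~ z[win])
    cf <- stats::coef(fit)
    return(structure(list(z = z, force = unname(Fraw - (cf[1] + cf[2] * z)),
                          baseline_sd = stats::sd(stats::resid(fit)),
                          k_c = curve$k_c, qc = TRUE),
                     class = "corrected_curve"))
  }
  win_end <- max(20L, floor(n * baseline_frac))
  warned <- FALSE
  floor_sd <- 1e-9 * max(abs(Fraw), 1e-9)
  for (attempt in 1:40) {
    # fit the line on the head half only (clean whenever the contact sits in
    # the outer half) and test how far the tail strays from its extrapolation;
    # contact inside the window grows quadratically and fails the test
    head <- seq_len(floor(win_end * 0.5))
    hfit <- stats::lm(Fraw[head] ~ z[head])
    hc <- stats::coef(hfit)
    head_sd <- stats::sd(stats::resid(hfit))
    tail <- seq(max(1, floor(win_end * 0.8)), win_end)
    # mean deviation: a clean tail averages to ~sd/sqrt(n), while a contact
    # ramp shifts the mean systematically, so even sub-noise contamination
    # that would tilt the fitted baseline is caught
    tail_mean <- abs(mean(Fraw[tail] - (hc[1] + hc[2] * z[tail])))
    if (tail_mean <= 6 * head_sd / sqrt(length(tail)) + floor_sd) {
      win <- seq_len(win_end)
      fit <- stats::lm(Fraw[win] ~ z[win])
      cf <- stats::coef(fit)
      Fc <- Fraw - (cf[1] + cf[2] * z)
      return(structure(list(z = z, force = unname(Fc),
                            baseline_sd = stats::sd(stats::resid(fit)),
                            k_c = curve$k_c, qc = TRUE),
                       class = "corrected_curve"))
    }
    if (!warned) {
      warning("baseline window overlaps contact; shrinking window")
      warned <- TRUE
    }
    win_end <- floor(win_end * 0.85)
    if (win_end < 20) break
  }
  q <- seq_len(max(10L, floor(n * 0.1)))
  structure(list(z = z, force = unname(Fraw - stats::median(Fraw[q])),
                 baseline_sd = stats::sd(Fraw[q]),
                 k_c = curve$k_c, qc = FALSE),
            class = "corrected_curve")
}

#' Detect the contact point on a corrected curve
#'
#' Force-threshold crossing at `nsd` times the baseline noise (with a small
#' absolute floor for noise-free data), sustained over the following samples.
#'
#' @param corrected a `corrected_curve`.
#' @param nsd threshold in baseline noise standard deviations (default 5).
#' @return Contact piezo position, nm.
#' @export
detect_contact <- function(corrected, nsd = 5) {
  F <- corrected$force
  thr <- max(nsd * corrected$baseline_sd, 1e-7 * max(F, 0), 1e-10)
  above <- F > thr
  run <- which(above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE))
  if (!length(run)) stop("no contact point detected")
  i <- run[1]
  if (i > 1 && F[i] != F[i - 1]) {
    # linear interpolation back to the threshold crossing
    corrected$z[i - 1] + (thr - F[i - 1]) / (F[i] - F[i - 1]) *
      (corrected$z[i] - corrected$z[i - 1])
  } else {
    corrected$z[i]
  }
}

#' Indentation from piezo position and cantilever bending
#'
#' Past contact, the piezo travel divides into sample indentation and
#' cantilever deflection: `delta = (z - z_contact) - F / k_c`.
#'
#' @param corrected a `corrected_curve`.
#' @param contact_point contact piezo position, nm.
#' @return `data.frame` with `delta` (nm, clamped at 0) and `force` (nN) for
#'   samples past contact.
#' @export
compute_indentation <- function(corrected, contact_point) {
  z <- corrected$z
  if (contact_point < min(z) || contact_point > max(z)) {
    stop("contact point outside the curve")
  }
  sel <- z >= contact_point
  delta <- (z[sel] - contact_point) - corrected$force[sel] / corrected$k_c
  if (any(delta > (max(z) - min(z)))) stop("indentation exceeds piezo travel")
  data.frame(delta = pmax(delta, 0), force = corrected$force[sel])
}

#' Fit the pyramidal-indenter Hertz model
#'
#' Least squares of \eqn{F = \frac{\tan\alpha}{\sqrt 2}\,
#' \frac{E_a}{1-\nu^2}\, \delta^2} over the configured indentation-depth
#' window (default 10-100 nm), with optional joint refinement of the contact
#' point as a depth offset.
#'
#' @param indentation `data.frame` with `delta` (nm) and `force` (nN).
#' @param tip_half_angle pyramid face half-angle alpha, degrees (default 20).
#' @param poisson sample Poisson ratio (default 0.5).
#' @param depth_range fit window on indentation depth, nm.
#' @param refine_contact jointly refine the contact point (default TRUE).
#' @return Object of class `hertz_fit`: `E_a` (MPa), `contact_shift` (nm),
#'   `fit_rms` (nN), `depth_range_used`, `qc_pass`, `n_points`.
#' @export
fit_hertz <- function(indentation, tip_half_angle = 20, poisson = 0.5,
                      depth_range = c(10, 100), refine_contact = TRUE) {
  fail <- function(msg) structure(list(E_a = NA_real_, contact_shift = 0,
                                       fit_rms = NA_real_,
                                       depth_range_used = depth_range,
                                       qc_pass = FALSE, n_points = 0L,
                                       reason = msg), class = "hertz_fit")
  d0 <- indentation$delta
  F0 <- indentation$force
  # quadratic coefficient and RSS at a given contact-point shift
  quad_fit <- function(shift) {
    d <- d0 - shift
    in_win <- d >= depth_range[1] & d <= depth_range[2]
    if (sum(in_win) < 10) return(list(ok = FALSE))
    dd <- d[in_win]; ff <- F0[in_win]
    C <- sum(dd^2 * ff) / sum(dd^4)
    list(ok = TRUE, C = C, rss = sum((ff - C * dd^2)^2), n = sum(in_win))
  }
  shift <- 0
  if (refine_contact) {
    # for quadratic contact sqrt(F) is linear in depth, so a straight-line
    # fit through the deep (high-force, low relative noise) part of the
    # curve extrapolates to the true contact offset in closed form; this
    # absorbs the bias of threshold-based detection on soft samples
    deep <- which(F0 > 0.25 * max(F0))
    if (length(deep) >= 5) {
      cf <- stats::coef(stats::lm(sqrt(F0[deep]) ~ d0[deep]))
      if (is.finite(cf[2]) && cf[2] > 0) {
        s0 <- unname(-cf[1] / cf[2])
        if (is.finite(s0) && abs(s0) < max(d0)) shift <- s0
      }
    }
    # polish only a few nm around the closed-form estimate: the windowed RSS
    # is noise-dominated for soft samples and cannot be trusted further out
    obj <- function(s) {
      q <- quad_fit(s)
      if (!q$ok) Inf else q$rss
    }
    opt <- suppressWarnings(stats::optimize(obj, interval = shift + c(-3, 3)))
    if (is.finite(opt$objective)) shift <- opt$minimum
  }
  q <- quad_fit(shift)
  if (!q$ok) {
    # the depth window holds no data at the refined offset (detection far
    # from the true contact); fit unshifted but keep reporting the offset so
    # callers can re-derive the indentation around it
    q <- quad_fit(0)
    if (!q$ok) return(fail("too few points in the fit window"))
  }
  # invert F = (tan(alpha)/sqrt(2)) * (E/(1-nu^2)) * delta^2, E in MPa
  # (1 MPa = 1e-3 nN/nm^2)
  E_a <- q$C * (1 - poisson^2) * sqrt(2) / tan(tip_half_angle * pi / 180) * 1e3
  if (!is.finite(E_a) || E_a <= 0) return(fail("non-positive fitted modulus"))
  structure(list(E_a = unname(E_a), contact_shift = shift,
                 fit_rms = sqrt(q$rss / q$n), depth_range_used = depth_range,
                 qc_pass = TRUE, n_points = q$n, reason = NULL),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (x$qc_pass) {
    cat(sprintf("hertz_fit: E_a = %.4g MPa (%d points, rms %.3g nN)\n",
                x$E_a, x$n_points, x$fit_rms))
  } else {
    cat("hertz_fit: QC FAIL -", x$reason, "\n")
  }
  invisible(x)
}

#' Process a force map into an apparent-modulus map
#'
#' Runs preprocess, contact detection, indentation and the Hertz fit on
#' every pixel.  Pixels whose pipeline fails at any stage are masked, never
#' fatal.
#'
#' @param map a `force_map`.
#' @param tip_half_angle,poisson,depth_range,nsd pipeline settings, see
#'   [fit_hertz()] and [detect_contact()].
#' @param refine_contact jointly refine contact points (default TRUE).
#' @param qc_rms_max QC stringency: mask pixels whose fit RMS (nN) exceeds
#'   this bound (default Inf).  Tightening it can only mask more pixels.
#' @param qc_min_points QC stringency: minimum in-window points per fit.
#' @return List with `E_a` (matrix, MPa, NA where masked), `qc` (logical
#'   matrix), `n_failed`.
#' @export
process_force_map <- function(map, tip_half_angle = 20, poisson = 0.5,
                              depth_range = c(10, 100), nsd = 5,
                              refine_contact = TRUE, qc_rms_max = Inf,
                              qc_min_points = 10) {
  stopifnot(inherits(map, "force_map"))
  nr <- map$shape[1]; nc <- map$shape[2]
  Ea <- matrix(NA_real_, nr, nc)
  qc <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cv <- map$curves[[(i - 1L) * nc + j]]
    fit <- tryCatch({
      corr <- suppressWarnings(preprocess_curve(cv))
      if (!corr$qc) stop("baseline correction failed")
      zc <- detect_contact(corr, nsd = nsd)
      # threshold detection runs late on soft samples (the crossing sits at
      # nsd sigma of force); fold the fit's refined contact offset back into
      # the indentation so the depth window sees real data
      fit <- NULL
      best <- NULL
      for (pass in 1:3) {
        di <- compute_indentation(corr, zc)
        fit <- fit_hertz(di, tip_half_angle, poisson, depth_range,
                         refine_contact)
        if (fit$qc_pass) best <- fit
        if (!refine_contact || !fit$qc_pass) break
        if (pass > 1 && abs(fit$contact_shift) < 2) break
        zc <- zc + fit$contact_shift
        # with the contact pinned by the deep data, re-fit the baseline on
        # the full pre-contact stretch (the searched window is conservative)
        corr2 <- tryCatch(preprocess_curve(cv, baseline_end = zc - 20),
                          error = function(e) NULL)
        if (!is.null(corr2)) corr <- corr2
      }
      if (!is.null(best)) best else fit
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$qc_pass && fit$n_points >= qc_min_points &&
        fit$fit_rms <= qc_rms_max) {
      Ea[i, j] <- fit$E_a
      qc[i, j] <- TRUE
    }
  }
  list(E_a = Ea, qc = qc, n_failed = sum(!qc))
}

#' Per-region summary of an apparent-modulus map
#'
#' @param E_a modulus matrix (MPa), NA where masked.
#' @param labels region label matrix, same shape.
#' @param qc optional logical matrix; only qc-passing pixels contribute.
#' @return `data.frame` with `region`, `mean`, `sem`, `n`, `empty` (TRUE for
#'   regions with no usable pixels; their mean/sem are NA, not zero).
#' @export
region_stats <- function(E_a, labels, qc = NULL) {
  stopifnot(all(dim(E_a) == dim(labels)))
  if (is.null(qc)) qc <- !is.na(E_a)
  regs <- sort(unique(as.vector(labels)))
  out <- lapply(regs, function(rg) {
    v <- E_a[labels == rg & qc & !is.na(E_a)]
    if (!length(v)) {
      data.frame(region = rg, mean = NA_real_, sem = NA_real_, n = 0L,
                 empty = TRUE)
    } else {
      data.frame(region = rg, mean = mean(v),
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                 n = length(v), empty = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Render an apparent-modulus map as a heatmap
#'
#' @param E_a modulus matrix (MPa), NA where masked (masked pixels are drawn
#'   blank).
#' @param main plot title.
#' @param ... further arguments to [graphics::image()].
#' @return `E_a`, invisibly.
#' @export
plot_modulus_map <- function(E_a, main = "apparent modulus E_a (MPa)", ...) {
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(t(E_a[nrow(E_a):1, , drop = FALSE]), col = pal,
                  axes = FALSE, main = main, useRaster = TRUE, ...)
  invisible(E_a)
}
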