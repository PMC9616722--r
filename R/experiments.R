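#' A named set of genotype parameterizations
#'
#' Bundles per-genotype wall materials and stomatal geometries for matched
#' pressure-ramp comparisons.  With a single geometry supplied, all
#' genotypes share it (complex length does not differ between the lines).
#'
#' @param materials named list of [wall_material()] objects.
#' @param geometries a single [stoma_geometry()] shared by all genotypes, or
#'   a named list matching `materials`.
#' @return Object of class `genotype_set`.
#' @export
genotype_set <- function(materials, geometries) {
  stopifnot(is.list(materials), length(materials) >= 1)
  if (is.null(names(materials)) || anyDuplicated(names(materials))) {
    stop("materials must be uniquely named")
  }
  for (m in materials) stopifnot(inherits(m, "wall_material"))
  if (inherits(geometries, "stoma_geometry")) {
    geometries <- stats::setNames(rep(list(geometries), length(materials)),
                                  names(materials))
  }
  stopifnot(setequal(names(geometries), names(materials)))
  for (g in geometries) stopifnot(inherits(g, "stoma_geometry"))
  structure(list(materials = materials, geometries = geometries[names(materials)]),
            class = "genotype_set")
}

#' Default reconstruction of the three genotype parameter sets
#'
#' The control wall matrix has small-strain modulus `E = 3*C1*C2 = 48` MPa;
#' the stiffer `arad1` and softer `ARAD1_OE` walls are scaled by
#' `sqrt(1.8)` either side of control, giving an arad1:ARAD1_OE matrix
#' modulus ratio of exactly 1.8.  Fiber stiffness `C5` and bulk modulus are
#' shared.  These are reconstruction defaults meant to reproduce the study
#' conditions qualitatively; fitted per-genotype values can be supplied via
#' [genotype_set()] or a YAML/JSON config.
#'
#' @param geom shared [stoma_geometry()] (default: realistic Arabidopsis
#'   dimensions, 24 x 12 x 2.4 um pore, 6 um guard cells).
#' @param C2 shared nonlinearity parameter.
#' @param E_control control small-strain matrix modulus, MPa.
#' @param stiffness_ratio arad1 : ARAD1_OE matrix modulus fold ratio.
#' @param C5 shared fiber stiffness, MPa.
#' @param K_bulk bulk modulus, MPa.
#' @return A `genotype_set` with members `control`, `arad1`, `ARAD1_OE`.
#' @export
default_genotype_set <- function(geom = stoma_geometry(24, 12, 2.4, 6),
                                 C2 = 5, E_control = 48, stiffness_ratio = 1.8,
                                 C5 = 3000, K_bulk = 1e4) {
  C1c <- E_control / (3 * C2)
  s <- sqrt(stiffness_ratio)
  genotype_set(
    materials = list(
      control  = wall_material(C1c, C2, C5, K_bulk),
      arad1    = wall_material(C1c * s, C2, C5, K_bulk),
      ARAD1_OE = wall_material(C1c / s, C2, C5, K_bulk)),
    geometries = geom)
}

#' Solve matched pressure ramps for every genotype
#'
#' @param gset a [genotype_set()].
#' @param load a [load_program()].
#' @param res a [mesh_resolution()].
#' @param out_dir optional directory for per-genotype response CSVs and VTU
#'   series.
#' @param verbose print solver progress.
#' @return List of class `genotype_sweep`: `responses` (named list of
#'   [build_response()] tables), `summary` (one row per genotype: aperture
#'   and aspect ratio at P_max and at the first accepted step), `failed`
#'   (named list of partial-result messages for non-converged genotypes).
#' @export
run_genotype_sweep <- function(gset, load = load_program(),
                               res = mesh_resolution(), out_dir = NULL,
                               verbose = FALSE) {
  stopifnot(inherits(gset, "genotype_set"))
  responses <- list()
  failed <- list()
  for (nm in names(gset$materials)) {
    mesh <- generate_mesh(gset$geometries[[nm]], res)
    states <- tryCatch(
      solve_pressure_ramp(mesh, gset$materials[[nm]], load, verbose = verbose),
      stomech_partial_result = function(c) {
        failed[[nm]] <<- conditionMessage(c)
        c$states
      })
    responses[[nm]] <- build_response(
      states, mesh,
      csv = if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        file.path(out_dir, paste0("response_", nm, ".csv"))
      },
      vtu_dir = if (!is.null(out_dir)) file.path(out_dir, paste0("vtu_", nm)),
      mat = gset$materials[[nm]])
  }
  if (!is.null(out_dir)) {
    overlay <- do.call(rbind, lapply(names(responses), function(nm) {
      cbind(genotype = nm, as.data.frame(responses[[nm]]))
    }))
    utils::write.csv(overlay, file.path(out_dir, "response_overlay.csv"),
                     row.names = FALSE)
  }
  summ <- do.call(rbind, lapply(names(responses), function(nm) {
    r <- responses[[nm]]
    data.frame(genotype = nm,
               E_matrix = small_strain_modulus(gset$materials[[nm]]),
               P_final = r$pressure[nrow(r)],
               aperture_final = r$aperture[nrow(r)],
               aspect_final = r$aspect_ratio[nrow(r)],
               P_low = r$pressure[min(2, nrow(r))],
               aperture_low = r$aperture[min(2, nrow(r))])
  }))
  structure(list(responses = responses, summary = summ, failed = failed),
            class = "genotype_sweep")
}

#' @export
print.genotype_sweep <- function(x, ...) {
  cat("genotype_sweep:\n")
  print(x$summary, row.names = FALSE)
  if (length(x$failed)) {
    cat("partial (non-converged):", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Model-predicted wall-matrix stiffness fold ratio
#'
#' Ratio of the small-strain matrix moduli of the stiff (`arad1`) and soft
#' (`ARAD1_OE`) parameterizations, the model counterpart of the fold change
#' in AFM apparent modulus between those lines.
#'
#' @param gset a [genotype_set()] containing `arad1` and `ARAD1_OE`.
#' @return Dimensionless fold ratio.
#' @export
predicted_stiffness_ratio <- function(gset) {
  stopifnot(inherits(gset, "genotype_set"))
  for (nm in c("arad1", "ARAD1_OE")) {
    if (is.null(gset$materials[[nm]])) stop("genotype set lacks '", nm, "'")
  }
  small_strain_modulus(gset$materials$arad1) /
    small_strain_modulus(gset$materials$ARAD1_OE)
}

#' Read geometry/material/genotype configuration from YAML or JSON
#'
#' Layout: top-level `geometry` (six stoma_geometry keys) and `materials`
#' (named sets of C1, C2, C5, K_bulk); both support per-genotype overrides.
#'
#' @param path .yaml/.yml or .json file.
#' @return A `genotype_set`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  geom_from <- function(g) {
    do.call(stoma_geometry, g[intersect(names(g),
      c("stoma_length", "pore_length", "pore_width", "gc_width",
        "wall_thickness", "polar_wall_thickness"))])
  }
  base_geom <- geom_from(cfg$geometry)
  mats <- lapply(cfg$materials, function(m) {
    do.call(wall_material, m[intersect(names(m), c("C1", "C2", "C5", "K_bulk"))])
  })
  geoms <- base_geom
  if (!is.null(cfg$geometries)) {
    geoms <- lapply(cfg$geometries, geom_from)
  }
  genotype_set(mats, geoms)
}

#' Write a genotype set to a YAML config
#' @param gset a `genotype_set`.
#' @param path output .yaml path.
#' @return `path`, invisibly.
#' @export
write_config <- function(gset, path) {
  g1 <- gset$geometries[[1]]
  cfg <- list(geometry = unclass(g1),
              materials = lapply(gset$materials, unclass))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
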