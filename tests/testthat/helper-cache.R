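# Shared fixtures: the expensive solves are computed once per test run and
# reused across test files.
.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.solve_cache[[key]])) assign(key, fn(), envir = .solve_cache)
  get(key, envir = .solve_cache)
}

desk_geom <- function() stoma_geometry(24, 12, 2.4, 6)

desk_mesh <- function() cached("desk_mesh", function() {
  generate_mesh(desk_geom(), mesh_resolution(24, 16, 1))
})

# full 0-5 MPa ramp of the default control parameterization at desk resolution
control_ramp <- function() cached("control_ramp", function() {
  gs <- default_genotype_set()
  mesh <- desk_mesh()
  mat <- gs$materials$control
  ramp <- solve_pressure_ramp(mesh, mat, load_program(P_max = 5))
  list(mesh = mesh, mat = mat, ramp = ramp,
       response = build_response(ramp, mesh))
})

# matched three-genotype sweep at desk resolution (default reconstruction)
genotype_sweep_cached <- function() cached("sweep", function() {
  run_genotype_sweep(default_genotype_set(), load_program(P_max = 5),
                     mesh_resolution(24, 16, 1))
})

# single-parameter variants of control for the sensitivity comparison
variant_aperture <- function(C1_mult = 1, C5_mult = 1) {
  key <- sprintf("variant_%g_%g", C1_mult, C5_mult)
  cached(key, function() {
    gs <- default_genotype_set()
    m0 <- gs$materials$control
    mat <- wall_material(m0$C1 * C1_mult, m0$C2, m0$C5 * C5_mult, m0$K_bulk)
    mesh <- desk_mesh()
    ramp <- solve_pressure_ramp(mesh, mat, load_program(P_max = 5))
    resp <- build_response(ramp, mesh)
    resp$aperture[nrow(resp)]
  })
}

# pressurized thin-sphere benchmark at near-linear parameters
sphere_benchmark <- function() cached("sphere", function() {
  mesh <- benchmark_shell_mesh("sphere", R = 10, t = 0.1, n = 8)
  mat <- wall_material(50, 2, 0, 1e5)
  ramp <- solve_pressure_ramp(mesh, mat,
    load_program(P_max = 0.01, dP_init = 0.01, dP_min = 1e-4, dP_max = 0.01))
  st <- ramp[[length(ramp)]]
  list(mesh = mesh, mat = mat, state = st,
       fields = element_fields(mesh, mat, st))
})

cylinder_benchmark <- function() cached("cylinder", function() {
  mesh <- benchmark_shell_mesh("cylinder", R = 5, t = 0.1, n = 16, length = 30)
  mat <- wall_material(50, 2, 0, 1e5)
  ramp <- solve_pressure_ramp(mesh, mat,
    load_program(P_max = 0.01, dP_init = 0.01, dP_min = 1e-4, dP_max = 0.01))
  st <- ramp[[length(ramp)]]
  list(mesh = mesh, mat = mat, state = st,
       fields = element_fields(mesh, mat, st))
})

# small thick-walled sphere for fast consistency checks
tiny_shell <- function() cached("tiny_shell", function() {
  benchmark_shell_mesh("sphere", R = 10, t = 0.5, n = 4, n_thickness = 1)
})

sym_from6 <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}
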