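#' Write an unstructured hexahedral grid to ASCII VTU
#'
#' Plain XML VTK UnstructuredGrid with Float64 coordinates printed at full
#' precision (17 significant digits), so a write/read round trip reproduces
#' the doubles bit-exactly.
#'
#' @param path output file path (.vtu).
#' @param nodes n x 3 coordinate matrix.
#' @param hexes n_el x 8 connectivity (1-based).
#' @param point_data named list of per-node vectors or n x k matrices.
#' @param cell_data named list of per-element vectors or n_el x k matrices.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(path, nodes, hexes, point_data = list(), cell_data = list()) {
  num <- function(x) paste(sprintf("%.17g", as.numeric(t(x))), collapse = " ")
  da <- function(name, x, int = FALSE) {
    nc <- if (is.matrix(x)) ncol(x) else 1L
    sprintf(
      '<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
      if (int) "Int32" else "Float64", name, nc,
      if (int) paste(as.integer(t(x)), collapse = " ") else num(x))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(nodes), nrow(hexes)),
    '<Points>',
    da("Points", nodes),
    '</Points>',
    '<Cells>',
    da("connectivity", hexes - 1L, int = TRUE),
    da("offsets", matrix(seq_len(nrow(hexes)) * 8L, ncol = 1), int = TRUE),
    da("types", matrix(rep(12L, nrow(hexes)), ncol = 1), int = TRUE),
    '</Cells>',
    '<PointData>',
    vapply(names(point_data), function(nm) da(nm, point_data[[nm]]), character(1)),
    '</PointData>',
    '<CellData>',
    vapply(names(cell_data), function(nm) da(nm, cell_data[[nm]]), character(1)),
    '</CellData>',
    '</Piece>',
    '</UnstructuredGrid>',
    '</VTKFile>'), con)
  invisible(path)
}

#' Read an ASCII VTU file written by [write_vtu()]
#'
#' @param path .vtu file path.
#' @return List with `nodes`, `hexes` (1-based), `point_data`, `cell_data`.
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  np <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  ne <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  get_da <- function(node) {
    nc <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    v <- scan(text = xml2::xml_text(node), quiet = TRUE)
    if (nc > 1) matrix(v, ncol = nc, byrow = TRUE) else v
  }
  pts <- get_da(xml2::xml_find_first(piece, ".//Points/DataArray"))
  conn <- get_da(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))
  hexes <- if (is.matrix(conn)) {
    matrix(as.integer(conn), nrow(conn)) + 1L
  } else {
    matrix(as.integer(conn), ncol = 8, byrow = TRUE) + 1L
  }
  read_block <- function(xp) {
    das <- xml2::xml_find_all(piece, xp)
    out <- lapply(das, get_da)
    names(out) <- xml2::xml_attr(das, "Name")
    out
  }
  list(nodes = pts, hexes = hexes,
       point_data = read_block(".//PointData/DataArray"),
       cell_data = read_block(".//CellData/DataArray"))
}

#' Write a full mesh (with tags) to VTU
#'
#' Region labels and fiber directions go out as cell data; fixed nodes as a
#' 0/1 point scalar.  [read_vtu()] plus [mesh_from_vtu()] round-trips the
#' mesh geometry, connectivity and tags.
#'
#' @param mesh a `volume_mesh`.
#' @param path output .vtu path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path) {
  fixed <- numeric(nrow(mesh$node_coords))
  fixed[mesh$fixed_nodes] <- 1
  regions <- c(dorsal = 1L, ventral = 2L, polar = 3L, shell = 4L)
  write_vtu(path, mesh$node_coords, mesh$hex_connectivity,
            point_data = list(fixed = fixed),
            cell_data = list(fiber = mesh$fiber_dirs,
                             region = regions[mesh$element_region]))
}

#' Rebuild mesh geometry/tags from a VTU written by [write_mesh_vtu()]
#'
#' @param path .vtu path.
#' @return List with `node_coords`, `hex_connectivity`, `fiber_dirs`,
#'   `element_region`, `fixed_nodes` (solver metadata such as pressure facets
#'   is not stored in VTU and is not recovered).
#' @export
mesh_from_vtu <- function(path) {
  v <- read_vtu(path)
  regions <- c("dorsal", "ventral", "polar", "shell")
  list(node_coords = v$nodes,
       hex_connectivity = v$hexes,
       fiber_dirs = v$cell_data$fiber,
       element_region = regions[as.integer(v$cell_data$region)],
       fixed_nodes = which(v$point_data$fixed > 0.5))
}
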