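#' Write a mesh and fields to a VTK unstructured-grid (.vtu) file
#'
#' ASCII XML VTU with hexahedron cells (VTK type 12). Coordinates and field
#' values are written with 17 significant digits so a read round-trips
#' bit-identically. The element region tag is always written as cell data
#' (`region`, 0 = tissue, 1 = probe).
#'
#' @param mesh a `"hex_mesh"`.
#' @param path output file path.
#' @param point_data named list of per-node fields: numeric vectors (length
#'   N) or N x k matrices.
#' @param cell_data named list of per-element fields (length M vectors or
#'   M x k matrices).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  N <- nrow(mesh$nodes); M <- nrow(mesh$elements)
  check_len <- function(fields, n, what) {
    for (nm in names(fields)) {
      len <- if (is.matrix(fields[[nm]])) nrow(fields[[nm]]) else
        length(fields[[nm]])
      if (len != n)
        stop(what, " field '", nm, "' has length ", len, ", expected ", n)
    }
  }
  check_len(point_data, N, "point")
  check_len(cell_data, M, "cell")
  cell_data$region <- as.numeric(mesh$region == "probe")

  num <- function(x) paste(formatC(x, format = "g", digits = 17),
                           collapse = " ")
  da <- function(name, x) {
    ncomp <- if (is.matrix(x)) ncol(x) else 1L
    vals <- if (is.matrix(x)) as.vector(t(x)) else x
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, ncomp, num(vals))
  }
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl('<?xml version="1.0"?>',
     '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
     '<UnstructuredGrid>',
     sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M))
  wl('<Points>', da("Points", mesh$nodes), '</Points>')
  wl('<Cells>',
     sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n</DataArray>',
             paste(as.vector(t(mesh$elements)) - 1L, collapse = " ")),
     sprintf('<DataArray type="Int64" Name="offsets" format="ascii">\n%s\n</DataArray>',
             paste(seq_len(M) * 8L, collapse = " ")),
     sprintf('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>',
             paste(rep(12L, M), collapse = " ")),
     '</Cells>')
  if (length(point_data)) {
    wl('<PointData>')
    for (nm in names(point_data)) wl(da(nm, point_data[[nm]]))
    wl('</PointData>')
  }
  wl('<CellData>')
  for (nm in names(cell_data)) wl(da(nm, cell_data[[nm]]))
  wl('</CellData>')
  wl('</Piece>', '</UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}

#' Read back an ASCII .vtu file written by [write_vtu()]
#'
#' Minimal reader for round-trip checks and downstream inspection; parses
#' points, hexahedron connectivity, and all point/cell data arrays.
#'
#' @param path .vtu file path.
#' @return list with `nodes` (N x 3), `elements` (M x 8, 1-based),
#'   `point_data`, `cell_data` (named lists; multi-component arrays as
#'   matrices).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  N <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  M <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  parse_da <- function(node) {
    ncomp <- as.integer(xml2::xml_attr(node, "NumberOfComponents"))
    if (is.na(ncomp)) ncomp <- 1L
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
    if (ncomp > 1L) matrix(vals, ncol = ncomp, byrow = TRUE) else vals
  }
  pts <- parse_da(xml2::xml_find_first(piece, ".//Points/DataArray"))
  conn <- parse_da(xml2::xml_find_first(
    piece, ".//Cells/DataArray[@Name='connectivity']"))
  elements <- matrix(as.integer(conn) + 1L, ncol = 8, byrow = TRUE)
  grab <- function(xpath) {
    nodes <- xml2::xml_find_all(piece, xpath)
    out <- lapply(nodes, parse_da)
    names(out) <- xml2::xml_attr(nodes, "Name")
    out
  }
  list(nodes = pts, elements = elements,
       point_data = grab(".//PointData/DataArray"),
       cell_data = grab(".//CellData/DataArray"))
}
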