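# VTK unstructured-grid serialisation: plain inline ASCII VTU frames plus a
# PVD time-series index, the layout ParaView expects. 2-D geometry is
# embedded in 3-D with z = 0, and the per-cell integer array is named exactly
# "Cell types" so frames are colourable by cell type out of the box.

VTK_VERTEX <- 1L
VTK_POLYGON <- 7L
VTK_QUAD <- 9L

fmt_num <- function(x) sprintf("%.12g", x)

#' Write a VTU (XML unstructured grid) file
#'
#' @param points n x 2 or n x 3 coordinate matrix (z = 0 added when absent).
#' @param cells List of integer vectors, 1-based point indices per cell
#'   (written 0-based, as the format requires).
#' @param cell_types VTK cell type code per cell (1 = vertex, 7 = polygon,
#'   9 = quad).
#' @param cell_data Named list of numeric/integer vectors, one value per
#'   cell; integer vectors are written as Int32, others as Float64.
#' @param path Output path; the directory must exist (checked before
#'   anything is written, so a failure leaves no partial file).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(points, cells, cell_types, cell_data = list(), path) {
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  n_pts <- nrow(points)
  n_cells <- length(cells)
  if (length(cell_types) != n_cells) {
    ts_stop("one VTK cell type code per cell required", "tissuesim_io_error")
  }
  for (arr in cell_data) {
    if (length(arr) != n_cells) {
      ts_stop("every cell-data array needs one value per cell", "tissuesim_io_error")
    }
  }
  if (!dir.exists(dirname(path))) {
    ts_stop(sprintf("output directory does not exist: %s", dirname(path)),
            "tissuesim_io_error")
  }
  conn <- unlist(cells, use.names = FALSE) - 1L
  offsets <- cumsum(lengths(cells))
  da <- function(type, name, values, ncomp = NULL) {
    attrs <- sprintf(' Name="%s"', name)
    if (is.null(name)) attrs <- ""
    if (!is.null(ncomp)) attrs <- paste0(attrs, sprintf(' NumberOfComponents="%d"', ncomp))
    sprintf('        <DataArray type="%s"%s format="ascii">\n          %s\n        </DataArray>',
            type, attrs, paste(values, collapse = " "))
  }
  cd_lines <- character(0)
  if (length(cell_data) > 0L) {
    cd_lines <- vapply(names(cell_data), function(nm) {
      v <- cell_data[[nm]]
      if (is.integer(v)) da("Int32", nm, v) else da("Float64", nm, fmt_num(v))
    }, character(1))
    cd_lines <- c("      <CellData>", cd_lines, "      </CellData>")
  }
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "  <UnstructuredGrid>",
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n_pts, n_cells),
    "      <Points>",
    da("Float64", NULL, fmt_num(t(points)), ncomp = 3),
    "      </Points>",
    "      <Cells>",
    da("Int32", "connectivity", conn),
    da("Int32", "offsets", offsets),
    da("UInt8", "types", as.integer(cell_types)),
    "      </Cells>",
    cd_lines,
    "    </Piece>",
    "  </UnstructuredGrid>",
    "</VTKFile>"
  )
  writeLines(xml, path)
  invisible(path)
}

#' Read a VTU file written by this package (or any inline-ASCII VTU)
#'
#' XML-parser based (xml2), an independent code path from [write_vtu()].
#'
#' @param path Path to a `.vtu` file.
#' @return List with `points` (n x 3), `cells` (list of 1-based index
#'   vectors), `cell_types`, and `cell_data` (named list).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  nums <- function(node) {
    txt <- xml2::xml_text(node)
    as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  }
  pts <- nums(xml2::xml_find_first(piece, ".//Points/DataArray"))
  points <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- nums(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="connectivity"]'))
  offs <- nums(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="offsets"]'))
  types <- nums(xml2::xml_find_first(piece, './/Cells/DataArray[@Name="types"]'))
  starts <- c(0, offs[-length(offs)])
  cells <- lapply(seq_along(offs), function(i) {
    as.integer(conn[(starts[i] + 1):offs[i]]) + 1L
  })
  cd_nodes <- xml2::xml_find_all(piece, ".//CellData/DataArray")
  cell_data <- stats::setNames(
    lapply(cd_nodes, nums),
    vapply(cd_nodes, function(nd) xml2::xml_attr(nd, "Name"), character(1))
  )
  list(points = points, cells = cells, cell_types = as.integer(types),
       cell_data = cell_data)
}

#' Write a PVD time-series index
#'
#' @param index Data.frame with columns `timestep` (strictly increasing) and
#'   `file` (frame paths relative to the PVD file).
#' @param path Output path for `results.pvd`.
#' @return `path`, invisibly.
#' @export
write_pvd <- function(index, path) {
  if (nrow(index) < 1L) {
    ts_stop("PVD index needs at least one frame", "tissuesim_io_error")
  }
  if (any(diff(index$timestep) <= 0)) {
    ts_stop("PVD timesteps must be strictly increasing", "tissuesim_io_error")
  }
  entries <- sprintf('    <DataSet timestep="%s" group="" part="0" file="%s"/>',
                     fmt_num(index$timestep), index$file)
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
    "  <Collection>",
    entries,
    "  </Collection>",
    "</VTKFile>"
  )
  writeLines(xml, path)
  invisible(path)
}

#' Read a PVD index
#'
#' @param path Path to a `.pvd` file.
#' @return Data.frame with `timestep` and `file`.
#' @export
read_pvd <- function(path) {
  doc <- xml2::read_xml(path)
  ds <- xml2::xml_find_all(doc, ".//DataSet")
  data.frame(
    timestep = as.numeric(vapply(ds, function(d) xml2::xml_attr(d, "timestep"),
                                 character(1))),
    file = vapply(ds, function(d) xml2::xml_attr(d, "file"), character(1)),
    stringsAsFactors = FALSE
  )
}

# ---- frame assembly per framework ------------------------------------------

# Geometry + cell data of one output frame for any framework. VM: one
# polygon per element; VT: clipped Voronoi polygon per cell; PM: one vertex
# per cell; CA/CP: one unit quad per occupied site carrying its owner's data.
frame_geometry <- function(state) {
  cells <- state$cells
  fw <- state$framework
  if (fw == "VM") {
    mesh <- state$structure
    rows <- element_cell_rows(mesh, cells)
    list(points = mesh$coords, cells = mesh$elements,
         cell_types = rep(VTK_POLYGON, length(mesh$elements)),
         cell_data = list(
           "Cell types" = as.integer(cells$type[rows]),
           "Cell ids" = as.integer(cells$id[rows]),
           "Cell ages" = state$t - cells$birth_time[rows]
         ))
  } else if (fw %in% c("PM", "VT")) {
    pop <- state$structure
    rows <- match(pop$cell_ids, cells$id)
    if (fw == "PM") {
      list(points = pop$coords,
           cells = as.list(seq_len(nrow(pop$coords))),
           cell_types = rep(VTK_VERTEX, nrow(pop$coords)),
           cell_data = list(
             "Cell types" = as.integer(cells$type[rows]),
             "Cell ids" = as.integer(pop$cell_ids),
             "Cell ages" = state$t - cells$birth_time[rows]
           ))
    } else {
      margin <- 1
      box <- bounding_box(min(pop$coords[, 1]) - margin,
                          max(pop$coords[, 1]) + margin,
                          min(pop$coords[, 2]) - margin,
                          max(pop$coords[, 2]) + margin)
      regions <- voronoi_regions(pop$coords, box)
      pts <- do.call(rbind, regions)
      sizes <- vapply(regions, nrow, integer(1))
      ends <- cumsum(sizes)
      cl <- lapply(seq_along(regions), function(i) {
        (ends[i] - sizes[i] + 1L):ends[i]
      })
      list(points = pts, cells = cl,
           cell_types = rep(VTK_POLYGON, length(cl)),
           cell_data = list(
             "Cell types" = as.integer(cells$type[rows]),
             "Cell ids" = as.integer(pop$cell_ids),
             "Cell ages" = state$t - cells$birth_time[rows]
           ))
    }
  } else {
    lat <- state$structure
    occ_idx <- which(lat$occupancy != 0L)
    ids <- lat$occupancy[occ_idx]
    row <- ((occ_idx - 1L) %% lat$height) + 1L
    col <- ((occ_idx - 1L) %/% lat$height) + 1L
    # unit quad centred on each site, CCW
    x0 <- col - 0.5; y0 <- row - 0.5
    pts <- cbind(
      x = as.vector(rbind(x0, x0 + 1, x0 + 1, x0)),
      y = as.vector(rbind(y0, y0, y0 + 1, y0 + 1))
    )
    cl <- lapply(seq_along(occ_idx), function(i) ((i - 1L) * 4L) + 1:4)
    rows <- match(ids, cells$id)
    list(points = pts, cells = cl,
         cell_types = rep(VTK_QUAD, length(cl)),
         cell_data = list(
           "Cell types" = as.integer(cells$type[rows]),
           "Cell ids" = as.integer(ids),
           "Cell ages" = state$t - cells$birth_time[rows]
         ))
  }
}

#' Write one simulation frame as VTU
#'
#' @param state A simulation state (see [run_simulation()]).
#' @param path Output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(state, path) {
  g <- frame_geometry(state)
  write_vtu(g$points, g$cells, g$cell_types, g$cell_data, path)
}
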