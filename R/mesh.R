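# Vertex meshes (shared-edge polygonal tilings) and occupancy lattices, with
# their fixture generators and structural validators.

NODE_MERGE_TOL <- 1e-10

#' Construct a vertex mesh
#'
#' A vertex mesh holds a node coordinate table and a list of polygonal
#' elements, each an ordered ring of node indices. Interior edges are shared
#' node pairs traversed in opposite directions by the two incident elements.
#' Clockwise input rings are repaired by reversal; self-intersecting rings are
#' reported as errors, not repaired.
#'
#' @param coords n x 2 numeric matrix of node positions.
#' @param elements List of integer vectors, each an ordered ring of row
#'   indices into `coords` (counter-clockwise after repair).
#' @param cell_ids Optional integer vector, one cell id per element; defaults
#'   to `seq_along(elements)`.
#' @param validate Run full structural validation (default TRUE).
#' @return A `vertex_mesh` object.
#' @export
vertex_mesh <- function(coords, elements, cell_ids = seq_along(elements),
                        validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  elements <- lapply(elements, as.integer)
  for (k in seq_along(elements)) {
    ring <- elements[[k]]
    if (length(ring) >= 3L && signed_area(coords[ring, , drop = FALSE]) < 0) {
      elements[[k]] <- rev(ring)
    }
  }
  mesh <- structure(list(coords = coords, elements = elements,
                         cell_ids = as.integer(cell_ids)),
                    class = "vertex_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.vertex_mesh <- function(x, ...) {
  cat(sprintf("<vertex_mesh: %d nodes, %d elements, total area %.4g>\n",
              nrow(x$coords), length(x$elements), sum(element_areas(x))))
  invisible(x)
}

#' Element areas and perimeters of a vertex mesh
#'
#' @param mesh A `vertex_mesh`.
#' @return Numeric vector, one value per element.
#' @export
element_areas <- function(mesh) {
  vapply(mesh$elements, function(r) signed_area(mesh$coords[r, , drop = FALSE]),
         numeric(1))
}

#' @rdname element_areas
#' @export
element_perimeters <- function(mesh) {
  vapply(mesh$elements, function(r) ring_perimeter(mesh$coords[r, , drop = FALSE]),
         numeric(1))
}

# Directed edge table: one row per (element, consecutive node pair).
directed_edges <- function(mesh) {
  n_per <- lengths(mesh$elements)
  elem <- rep(seq_along(mesh$elements), n_per)
  from <- unlist(mesh$elements, use.names = FALSE)
  to <- unlist(lapply(mesh$elements, function(r) c(r[-1], r[1])), use.names = FALSE)
  data.frame(elem = elem, from = from, to = to)
}

#' Undirected edge table of a vertex mesh
#'
#' One row per undirected edge with the incident element(s): `elem2` is NA for
#' boundary edges. Ordered by (node a, node b), the fixed order in which
#' topological checks are performed.
#'
#' @param mesh A `vertex_mesh`.
#' @return A data.frame with columns a, b (a < b), elem1, elem2, length.
#' @export
mesh_edges <- function(mesh) {
  de <- directed_edges(mesh)
  a <- pmin(de$from, de$to); b <- pmax(de$from, de$to)
  key <- paste(a, b)
  first <- !duplicated(key)
  ord <- split(seq_len(nrow(de)), match(key, unique(key)))
  ua <- a[first]; ub <- b[first]
  e1 <- integer(length(ord)); e2 <- rep(NA_integer_, length(ord))
  for (k in seq_along(ord)) {
    rows <- ord[[k]]
    e1[k] <- de$elem[rows[1]]
    if (length(rows) > 1L) e2[k] <- de$elem[rows[2]]
  }
  len <- sqrt(rowSums((mesh$coords[ub, , drop = FALSE] -
                         mesh$coords[ua, , drop = FALSE])^2))
  out <- data.frame(a = ua, b = ub, elem1 = e1, elem2 = e2, length = len)
  out[order(out$a, out$b), , drop = FALSE]
}

ring_is_simple <- function(ring) {
  n <- nrow(ring)
  segs <- cbind(ring, ring[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (share an endpoint)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(segs[i, 1:2], segs[i, 3:4], segs[j, 1:2], segs[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Validate a vertex mesh
#'
#' Checks element ring sizes, uniqueness of nodes within rings, positive
#' (counter-clockwise) areas, simplicity of rings, the shared-edge invariant
#' (every edge borders at most two elements, traversed in opposite
#' directions), and the node-merge tolerance (no two distinct nodes closer
#' than `tol`).
#'
#' @param mesh A `vertex_mesh`.
#' @param tol Node merge tolerance (default 1e-10, relative to edge length 1).
#' @param check_simple Also test every ring for self-intersection.
#' @return Invisibly TRUE; otherwise a `tissuesim_mesh_error` is signalled.
#' @export
validate_mesh <- function(mesh, tol = NODE_MERGE_TOL, check_simple = TRUE) {
  if (!all(is.finite(mesh$coords))) {
    ts_stop("mesh has non-finite node coordinates", "tissuesim_mesh_error")
  }
  if (length(mesh$cell_ids) != length(mesh$elements)) {
    ts_stop("one cell id per element required", "tissuesim_mesh_error")
  }
  nn <- nrow(mesh$coords)
  for (k in seq_along(mesh$elements)) {
    ring <- mesh$elements[[k]]
    if (length(ring) < 3L) {
      ts_stop(sprintf("element %d has fewer than 3 nodes", k), "tissuesim_mesh_error")
    }
    if (anyDuplicated(ring)) {
      ts_stop(sprintf("element %d repeats a node", k), "tissuesim_mesh_error")
    }
    if (any(ring < 1L | ring > nn)) {
      ts_stop(sprintf("element %d references a missing node", k), "tissuesim_mesh_error")
    }
    pts <- mesh$coords[ring, , drop = FALSE]
    if (signed_area(pts) <= 0) {
      ts_stop(sprintf("element %d has non-positive area", k), "tissuesim_mesh_error")
    }
    if (check_simple && !ring_is_simple(pts)) {
      ts_stop(sprintf("element %d self-intersects", k), "tissuesim_mesh_error")
    }
  }
  de <- directed_edges(mesh)
  dir_key <- paste(de$from, de$to)
  if (anyDuplicated(dir_key)) {
    ts_stop("a directed edge appears twice (orientation conflict)", "tissuesim_mesh_error")
  }
  und_key <- paste(pmin(de$from, de$to), pmax(de$from, de$to))
  if (any(table(und_key) > 2L)) {
    ts_stop("an edge is shared by more than two elements", "tissuesim_mesh_error")
  }
  # node merge tolerance: nearest distinct pair among used nodes
  used <- sort(unique(unlist(mesh$elements, use.names = FALSE)))
  if (length(used) > 1L) {
    d <- stats::dist(mesh$coords[used, , drop = FALSE])
    if (min(d) < tol) {
      ts_stop("two distinct nodes are closer than the merge tolerance",
              "tissuesim_mesh_error")
    }
  }
  invisible(TRUE)
}

#' Honeycomb vertex mesh generator
#'
#' Builds `nx` x `ny` regular hexagonal elements (pointy-top orientation,
#' odd rows offset) sharing nodes along common edges. The standard initial
#' condition for vertex-model scenarios.
#'
#' @param nx,ny Columns and rows of hexagons (>= 1).
#' @param edge Hexagon edge length (> 0, default 1).
#' @return A validated `vertex_mesh` of `nx * ny` elements.
#' @export
build_honeycomb_mesh <- function(nx, ny, edge = 1) {
  if (length(nx) != 1L || length(ny) != 1L || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny)) {
    ts_stop("nx and ny must be positive integers", "tissuesim_config_error")
  }
  if (!is.finite(edge) || edge <= 0) {
    ts_stop("edge length must be positive", "tissuesim_config_error")
  }
  w <- sqrt(3) * edge
  ang <- pi / 6 + (0:5) * pi / 3
  hex_x <- edge * cos(ang)
  hex_y <- edge * sin(ang)
  coords <- matrix(numeric(0), ncol = 2)
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  elements <- vector("list", nx * ny)
  k <- 0L
  for (row in seq_len(ny) - 1L) {
    for (col in seq_len(nx) - 1L) {
      cx <- w * (col + 0.5 * (row %% 2))
      cy <- 1.5 * edge * row
      ring <- integer(6)
      for (v in 1:6) {
        px <- cx + hex_x[v]; py <- cy + hex_y[v]
        # distinct honeycomb nodes are >= edge/2 apart; 6 decimals dedups
        # floating duplicates without ever merging distinct nodes
        key <- sprintf("%d_%d", as.integer(round(px / edge * 1e6)),
                       as.integer(round(py / edge * 1e6)))
        id <- key_env[[key]]
        if (is.null(id)) {
          coords <- rbind(coords, c(px, py))
          id <- nrow(coords)
          assign(key, id, envir = key_env)
        }
        ring[v] <- id
      }
      k <- k + 1L
      elements[[k]] <- ring
    }
  }
  vertex_mesh(coords, elements)
}

# ---- Lattices ---------------------------------------------------------------

#' Construct an occupancy lattice
#'
#' Integer grid mapping sites to cell ids; 0 is reserved for empty sites
#' (the medium). In CA mode a cell occupies at most one site; in CP mode a
#' cell is a set of sites.
#'
#' @param occupancy Integer matrix (`height` rows x `width` columns) of cell
#'   ids, 0 for empty/medium.
#' @param mode "CA" or "CP".
#' @param neighbourhood "von_neumann" (4 neighbours) or "moore" (8); defaults
#'   to von Neumann for CA and Moore for CP.
#' @return A `lattice` object.
#' @export
new_lattice <- function(occupancy, mode = c("CA", "CP"), neighbourhood = NULL) {
  mode <- match.arg(mode)
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "integer"
  if (nrow(occupancy) < 1L || ncol(occupancy) < 1L) {
    ts_stop("lattice dimensions must be >= 1", "tissuesim_config_error")
  }
  if (any(occupancy < 0L)) {
    ts_stop("occupancy values must be 0 (medium) or positive cell ids",
            "tissuesim_config_error")
  }
  if (is.null(neighbourhood)) {
    neighbourhood <- if (mode == "CA") "von_neumann" else "moore"
  }
  neighbourhood <- match.arg(neighbourhood, c("von_neumann", "moore"))
  structure(list(occupancy = occupancy, width = ncol(occupancy),
                 height = nrow(occupancy), mode = mode,
                 neighbourhood = neighbourhood),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice %s: %d x %d, %d occupied sites, %d cells>\n",
              x$mode, x$width, x$height, sum(x$occupancy != 0L),
              length(setdiff(unique(as.vector(x$occupancy)), 0L))))
  invisible(x)
}

neighbour_offsets <- function(neighbourhood) {
  if (neighbourhood == "von_neumann") {
    cbind(dx = c(1L, -1L, 0L, 0L), dy = c(0L, 0L, 1L, -1L))
  } else {
    cbind(dx = rep(c(-1L, 0L, 1L), 3)[-5], dy = rep(c(-1L, 0L, 1L), each = 3)[-5])
  }
}

# Row/col indices of neighbours of site (row, col); fixed boundaries: edge
# sites simply have fewer neighbours.
site_neighbours <- function(lat, row, col) {
  off <- neighbour_offsets(lat$neighbourhood)
  r <- row + off[, "dy"]; c <- col + off[, "dx"]
  ok <- r >= 1L & r <= lat$height & c >= 1L & c <= lat$width
  cbind(row = r[ok], col = c[ok])
}

#' Disc-shaped lattice initial condition
#'
#' Fills a disc at the grid centre. In CA mode, `n_cells` distinct sites of
#' the disc each receive one cell id. In CP mode the disc is partitioned into
#' `n_cells` 4-connected domains of near-equal size by balanced multi-source
#' breadth-first growth from random seeds.
#'
#' @param width,height Lattice dimensions (sites).
#' @param radius Disc radius (sites); the disc must fit inside the grid.
#' @param n_cells Number of cells to place.
#' @param mode "CA" or "CP".
#' @return A `lattice` of the requested mode.
#' @export
build_lattice_blob <- function(width, height, radius, n_cells,
                               mode = c("CA", "CP")) {
  mode <- match.arg(mode)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  if (radius > cx - 0.5 + 1e-9 || radius > cy - 0.5 + 1e-9) {
    ts_stop("disc does not fit inside the lattice", "tissuesim_config_error")
  }
  occ <- matrix(0L, nrow = height, ncol = width)
  g <- expand.grid(row = seq_len(height), col = seq_len(width))
  in_disc <- (g$col - cx)^2 + (g$row - cy)^2 <= radius^2
  disc <- g[in_disc, , drop = FALSE]
  if (nrow(disc) < n_cells) {
    ts_stop("disc holds fewer sites than requested cells", "tissuesim_config_error")
  }
  if (mode == "CA") {
    pick <- disc[sample.int(nrow(disc), n_cells), , drop = FALSE]
    occ[cbind(pick$row, pick$col)] <- seq_len(n_cells)
  } else {
    # balanced multi-source BFS over the 4-connected disc
    idx <- function(row, col) (col - 1L) * height + row
    disc_set <- logical(width * height)
    disc_set[idx(disc$row, disc$col)] <- TRUE
    seeds <- disc[sample.int(nrow(disc), n_cells), , drop = FALSE]
    frontiers <- vector("list", n_cells)
    for (s in seq_len(n_cells)) {
      occ[seeds$row[s], seeds$col[s]] <- s
      frontiers[[s]] <- matrix(c(seeds$row[s], seeds$col[s]), ncol = 2)
    }
    off <- neighbour_offsets("von_neumann")
    remaining <- nrow(disc) - n_cells
    while (remaining > 0L) {
      grew <- FALSE
      for (s in seq_len(n_cells)) {
        fr <- frontiers[[s]]
        if (is.null(fr) || nrow(fr) == 0L) next
        claimed <- FALSE
        new_fr <- matrix(integer(0), ncol = 2)
        for (fi in seq_len(nrow(fr))) {
          r0 <- fr[fi, 1]; c0 <- fr[fi, 2]
          nb_r <- r0 + off[, "dy"]; nb_c <- c0 + off[, "dx"]
          ok <- nb_r >= 1L & nb_r <= height & nb_c >= 1L & nb_c <= width
          nb_r <- nb_r[ok]; nb_c <- nb_c[ok]
          free <- disc_set[idx(nb_r, nb_c)] & occ[cbind(nb_r, nb_c)] == 0L
          if (!claimed && any(free)) {
            cand <- which(free)
            j <- cand[sample.int(length(cand), 1L)]
            occ[nb_r[j], nb_c[j]] <- s
            new_fr <- rbind(new_fr, fr[fi, , drop = FALSE], c(nb_r[j], nb_c[j]))
            remaining <- remaining - 1L
            claimed <- TRUE
            grew <- TRUE
          } else if (any(free)) {
            new_fr <- rbind(new_fr, fr[fi, , drop = FALSE])
          }
        }
        frontiers[[s]] <- new_fr
        if (remaining == 0L) break
      }
      if (!grew) break
    }
    # any disc sites unreachable by balanced growth: attach to a 4-neighbour's cell
    left <- which(disc_set & as.vector(occ) == 0L)
    while (length(left) > 0L) {
      progressed <- FALSE
      for (li in left) {
        r0 <- ((li - 1L) %% height) + 1L; c0 <- ((li - 1L) %/% height) + 1L
        nb_r <- r0 + off[, "dy"]; nb_c <- c0 + off[, "dx"]
        ok <- nb_r >= 1L & nb_r <= height & nb_c >= 1L & nb_c <= width
        ids <- occ[cbind(nb_r[ok], nb_c[ok])]
        ids <- ids[ids != 0L]
        if (length(ids) > 0L) {
          occ[r0, c0] <- ids[1]
          progressed <- TRUE
        }
      }
      left <- which(disc_set & as.vector(occ) == 0L)
      if (!progressed) break
    }
  }
  new_lattice(occ, mode = mode)
}

#' Site counts per cell id of a lattice
#'
#' @param lat A `lattice`.
#' @return Named integer vector (names = cell ids) of site counts.
#' @export
lattice_areas <- function(lat) {
  v <- as.vector(lat$occupancy)
  tab <- table(v[v != 0L])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
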