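# Vertex-model mechanics. Tissue energy
#   U = sum_i k_area/2 (A_i - A0_i)^2 + sum_i k_perimeter/2 P_i^2
#     + sum_edges gamma(type_left, type_right) * edge_length,
# with a typed line-tension matrix that makes differential adhesion a
# parameter choice; boundary edges use the "medium" tension index. Nodes move
# by overdamped forward Euler down the analytic energy gradient; T1 swaps and
# T2 removals keep the topology consistent as edges and cells shrink.

#' Vertex-model parameters
#'
#' @param k_area Area-elasticity coefficient (> 0).
#' @param k_perimeter Perimeter-contractility coefficient (>= 0).
#' @param gamma Symmetric line-tension matrix indexed by cell-type pair with
#'   the tissue boundary ("medium") first: row/column 1 is the medium, row
#'   `t + 2` is cell type `t`. A scalar is expanded to a constant matrix over
#'   `n_types`.
#' @param n_types Number of cell types `gamma` must cover when given as a
#'   scalar.
#' @param d_t1 Edge-length threshold below which a T1 swap fires (strict `<`).
#' @param t1_separation_ratio Post-swap edge length as a multiple of `d_t1`.
#' @param a_t2 Element-area threshold below which a triangle is removed (T2).
#' @param drag Nodal drag coefficient (> 0).
#' @param dt Time step (> 0).
#' @param noise Magnitude of the isotropic random nodal displacement applied
#'   each step (0 = off, the default; sorting scenarios use a small value to
#'   escape local minima).
#' @return A `vertex_params` object.
#' @export
vertex_params <- function(k_area = 50, k_perimeter = 1, gamma = 0.1,
                          n_types = 1, d_t1 = 0.05, t1_separation_ratio = 1.5,
                          a_t2 = 0.01, drag = 1, dt = 0.01, noise = 0) {
  if (is.matrix(gamma)) {
    if (nrow(gamma) != ncol(gamma) || !isTRUE(all.equal(gamma, t(gamma)))) {
      ts_stop("gamma must be a symmetric square matrix", "tissuesim_config_error")
    }
  } else {
    k <- n_types + 1L
    gamma <- matrix(gamma, k, k)
  }
  if (k_area <= 0 || drag <= 0 || dt <= 0 || k_perimeter < 0 ||
      d_t1 < 0 || a_t2 < 0 || t1_separation_ratio <= 0 || noise < 0) {
    ts_stop("invalid vertex-model parameter (see ?vertex_params)",
            "tissuesim_config_error")
  }
  structure(list(k_area = k_area, k_perimeter = k_perimeter, gamma = gamma,
                 d_t1 = d_t1, t1_separation_ratio = t1_separation_ratio,
                 a_t2 = a_t2, drag = drag, dt = dt, noise = noise),
            class = "vertex_params")
}

# type index into gamma/J matrices: NA (medium) -> 1, cell type t -> t + 2
type_index <- function(type) ifelse(is.na(type), 1L, as.integer(type) + 2L)

# per-element cell rows: mesh$cell_ids[k] -> row in cells
element_cell_rows <- function(mesh, cells) {
  rows <- match(mesh$cell_ids, cells$id)
  if (anyNA(rows)) {
    ts_stop("an element has no associated cell", "tissuesim_state_error")
  }
  rows
}

edge_tensions <- function(edges, mesh, cells, params) {
  rows <- element_cell_rows(mesh, cells)
  if (max(type_index(cells$type)) > nrow(params$gamma)) {
    ts_stop("gamma matrix smaller than the number of cell types in play",
            "tissuesim_config_error")
  }
  t1 <- cells$type[rows[edges$elem1]]
  t2 <- ifelse(is.na(edges$elem2), NA_integer_, cells$type[rows[edges$elem2]])
  params$gamma[cbind(type_index(t1), type_index(t2))]
}

#' Vertex-model tissue energy
#'
#' @param mesh A valid `vertex_mesh`.
#' @param cells Cell table with one row per element (matched on
#'   `mesh$cell_ids`), providing type and target area.
#' @param params A [vertex_params()].
#' @return Scalar energy.
#' @export
tissue_energy <- function(mesh, cells, params) {
  rows <- element_cell_rows(mesh, cells)
  a <- element_areas(mesh)
  p <- element_perimeters(mesh)
  e_area <- sum(params$k_area / 2 * (a - cells$target_area[rows])^2)
  e_per <- sum(params$k_perimeter / 2 * p^2)
  edges <- mesh_edges(mesh)
  e_ten <- sum(edge_tensions(edges, mesh, cells, params) * edges$length)
  e_area + e_per + e_ten
}

#' Analytic nodal forces of the vertex model
#'
#' Force on node j is minus the gradient of [tissue_energy()] with respect to
#' that node's position: area gradients via adjacent-vertex cross products,
#' perimeter and line-tension gradients via unit edge vectors.
#'
#' @inheritParams tissue_energy
#' @return An n_nodes x 2 matrix of force vectors.
#' @export
nodal_forces <- function(mesh, cells, params) {
  rows <- element_cell_rows(mesh, cells)
  f <- matrix(0, nrow(mesh$coords), 2)
  xy <- mesh$coords
  for (k in seq_along(mesh$elements)) {
    ring <- mesh$elements[[k]]
    n <- length(ring)
    prv <- ring[c(n, seq_len(n - 1))]
    nxt <- ring[c(seq_len(n)[-1], 1L)]
    a <- signed_area(xy[ring, , drop = FALSE])
    # area term: dA/dx_v = (y_next - y_prev)/2, dA/dy_v = (x_prev - x_next)/2
    ca <- params$k_area * (a - cells$target_area[rows[k]])
    f[ring, 1] <- f[ring, 1] - ca * (xy[nxt, 2] - xy[prv, 2]) / 2
    f[ring, 2] <- f[ring, 2] - ca * (xy[prv, 1] - xy[nxt, 1]) / 2
    if (params$k_perimeter > 0) {
      p <- ring_perimeter(xy[ring, , drop = FALSE])
      d1 <- xy[ring, , drop = FALSE] - xy[prv, , drop = FALSE]
      d2 <- xy[ring, , drop = FALSE] - xy[nxt, , drop = FALSE]
      u1 <- d1 / sqrt(rowSums(d1^2))
      u2 <- d2 / sqrt(rowSums(d2^2))
      f[ring, ] <- f[ring, ] - params$k_perimeter * p * (u1 + u2)
    }
  }
  edges <- mesh_edges(mesh)
  g <- edge_tensions(edges, mesh, cells, params)
  dv <- xy[edges$b, , drop = FALSE] - xy[edges$a, , drop = FALSE]
  u <- dv / edges$length
  # tension pulls both endpoints together; rowsum accumulates nodes that
  # appear in several edges (plain indexed assignment would drop repeats)
  fx <- rowsum(c(g * u[, 1], -g * u[, 1]), c(edges$a, edges$b))
  fy <- rowsum(c(g * u[, 2], -g * u[, 2]), c(edges$a, edges$b))
  ids <- as.integer(rownames(fx))
  f[ids, 1] <- f[ids, 1] + fx[, 1]
  f[ids, 2] <- f[ids, 2] + fy[, 1]
  f
}

# insert value `v` immediately before the first occurrence of `at` in ring
ring_insert_before <- function(ring, at, v) {
  pos <- match(at, ring)
  append(ring, v, after = pos - 1L)
}

#' T1 edge swap
#'
#' Standard vertex-model neighbour exchange on a short interior edge: the two
#' elements sharing the edge lose it, the two elements flanking its endpoints
#' gain it, and the two nodes are repositioned perpendicular to the old edge
#' through its midpoint at separation `t1_separation_ratio * d_t1`. Node and
#' element counts are unchanged. Swaps that would create an element with
#' fewer than 3 nodes, or whose edge is not flanked by four distinct
#' elements, are skipped with a reason.
#'
#' @param mesh A `vertex_mesh`.
#' @param edge Length-2 integer vector of node indices.
#' @param params A [vertex_params()].
#' @return List with `mesh`, logical `swapped`, and `reason` (character,
#'   "" when swapped).
#' @export
t1_swap <- function(mesh, edge, params) {
  a <- edge[1]; b <- edge[2]
  has_a <- vapply(mesh$elements, function(r) a %in% r, logical(1))
  has_b <- vapply(mesh$elements, function(r) b %in% r, logical(1))
  both <- which(has_a & has_b)
  only_a <- which(has_a & !has_b)
  only_b <- which(has_b & !has_a)
  if (length(both) != 2L || length(only_a) != 1L || length(only_b) != 1L) {
    return(list(mesh = mesh, swapped = FALSE,
                reason = "edge not flanked by four distinct elements"))
  }
  # orient: X traverses a -> b, Y traverses b -> a
  traverses <- function(el, from, to) {
    ring <- mesh$elements[[el]]
    i <- match(from, ring)
    ring[if (i == length(ring)) 1L else i + 1L] == to
  }
  X <- if (traverses(both[1], a, b)) both[1] else both[2]
  Y <- setdiff(both, X)
  if (!traverses(X, a, b) || !traverses(Y, b, a)) {
    return(list(mesh = mesh, swapped = FALSE, reason = "inconsistent edge orientation"))
  }
  if (length(mesh$elements[[X]]) <= 3L || length(mesh$elements[[Y]]) <= 3L) {
    return(list(mesh = mesh, swapped = FALSE,
                reason = "swap would reduce an element below 3 nodes"))
  }
  A <- only_a; B <- only_b
  # reposition: X keeps node a and sits left of a->b
  xa <- mesh$coords[a, ]; xb <- mesh$coords[b, ]
  m <- (xa + xb) / 2
  e <- xb - xa
  len <- sqrt(sum(e^2))
  if (len < 1e-14) {
    return(list(mesh = mesh, swapped = FALSE, reason = "degenerate zero-length edge"))
  }
  nrm <- c(-e[2], e[1]) / len
  sep <- params$t1_separation_ratio * params$d_t1 / 2
  mesh$coords[a, ] <- m + sep * nrm
  mesh$coords[b, ] <- m - sep * nrm
  # surgery: X drops b, Y drops a, A gains b before a, B gains a before b
  mesh$elements[[X]] <- setdiff(mesh$elements[[X]], b)
  mesh$elements[[Y]] <- setdiff(mesh$elements[[Y]], a)
  mesh$elements[[A]] <- ring_insert_before(mesh$elements[[A]], a, b)
  mesh$elements[[B]] <- ring_insert_before(mesh$elements[[B]], b, a)
  list(mesh = mesh, swapped = TRUE, reason = "")
}

#' T2 element removal
#'
#' Removes a small triangular element: its three nodes collapse to one node
#' at the element centroid, neighbouring elements are re-wired through the
#' new node, and the associated cell leaves the population. Net effect: one
#' element and two nodes fewer.
#'
#' @param mesh A `vertex_mesh`.
#' @param element Element index.
#' @param cells Cell table.
#' @param params A [vertex_params()]; the element must be a triangle with
#'   area below `a_t2`.
#' @return List with `mesh`, `cells`, logical `removed`, `removed_cell_id`,
#'   and `reason`.
#' @export
t2_remove <- function(mesh, element, cells, params) {
  ring <- mesh$elements[[element]]
  area <- signed_area(mesh$coords[ring, , drop = FALSE])
  if (length(ring) != 3L || area >= params$a_t2) {
    return(list(mesh = mesh, cells = cells, removed = FALSE,
                removed_cell_id = NA_integer_,
                reason = "not a sub-threshold triangle"))
  }
  cen <- ring_centroid(mesh$coords[ring, , drop = FALSE])
  keep_node <- ring[1]
  drop_nodes <- ring[2:3]
  # neighbours must stay polygons after losing one ring slot
  for (k in seq_along(mesh$elements)) {
    if (k == element) next
    r <- mesh$elements[[k]]
    shared <- sum(r %in% ring)
    if (shared > 0L && length(r) - max(shared - 1L, 0L) < 3L) {
      return(list(mesh = mesh, cells = cells, removed = FALSE,
                  removed_cell_id = NA_integer_,
                  reason = "a neighbour would drop below 3 nodes"))
    }
  }
  mesh$coords[keep_node, ] <- cen
  removed_cell <- mesh$cell_ids[element]
  mesh$elements[[element]] <- NULL
  mesh$cell_ids <- mesh$cell_ids[-element]
  collapse_ring <- function(r) {
    r <- r[c(TRUE, r[-1] != r[-length(r)])]      # consecutive duplicates
    if (length(r) > 1L && r[1] == r[length(r)]) r <- r[-length(r)]  # wrap-around
    r
  }
  mesh$elements <- lapply(mesh$elements, function(r) {
    r[r %in% drop_nodes] <- keep_node
    collapse_ring(r)
  })
  # drop the two unused nodes and compact indices
  keep <- setdiff(seq_len(nrow(mesh$coords)), drop_nodes)
  map <- integer(nrow(mesh$coords))
  map[keep] <- seq_along(keep)
  mesh$coords <- mesh$coords[keep, , drop = FALSE]
  mesh$elements <- lapply(mesh$elements, function(r) map[r])
  cells <- cells[cells$id != removed_cell, , drop = FALSE]
  rownames(cells) <- NULL
  list(mesh = mesh, cells = cells, removed = TRUE,
       removed_cell_id = removed_cell, reason = "")
}

# principal axis with the smaller second moment (unit vector)
short_axis <- function(ring) {
  s <- ring_second_moments(ring)
  eg <- eigen(s, symmetric = TRUE)
  eg$vectors[, 2]  # eigenvalues sorted decreasing; column 2 = smaller
}

#' Divide a vertex element in two
#'
#' Splits the element by the line through its centroid along `axis` (default:
#' the shortest principal axis of its area second-moment tensor). New nodes
#' are inserted at the two boundary intersections and shared with the
#' neighbouring elements; intersections falling on existing vertices reuse
#' them. The parent cell is replaced by two daughters via [make_daughters()].
#'
#' @param mesh A `vertex_mesh`.
#' @param element Element index of the dividing cell.
#' @param cells Cell table; the element's cell must be division-ready.
#' @param axis Unit direction of the split line, or "short-axis".
#' @param t Division time.
#' @param params A [cycle_params()] used to redraw daughter G1 durations.
#' @param ready Readiness guard, as in [make_daughters()].
#' @return List with `mesh`, `cells`, logical `divided`, `daughter_ids`, and
#'   `reason` ("" on success; degenerate splits are deferred).
#' @export
divide_element <- function(mesh, element, cells, axis = "short-axis", t = 0,
                           params = cycle_params(), ready = TRUE) {
  ring <- mesh$elements[[element]]
  pts <- mesh$coords[ring, , drop = FALSE]
  cen <- ring_centroid(pts)
  d <- if (identical(axis, "short-axis")) short_axis(pts) else axis / sqrt(sum(axis^2))
  n <- length(ring)
  vtol <- 1e-9
  cuts <- list()
  seen_vertex <- integer(0)
  for (k in seq_len(n)) {
    p <- pts[k, ]; q <- pts[if (k == n) 1L else k + 1L, ]
    denom <- cross2(q - p, d)
    if (abs(denom) < 1e-14) next
    s <- cross2(cen - p, d) / denom
    # note: intersection point p + s (q - p) lies on the split line
    if (s < -vtol || s > 1 + vtol) next
    if (abs(s) <= vtol) {
      if (k %in% seen_vertex) next
      seen_vertex <- c(seen_vertex, k)
      cuts[[length(cuts) + 1L]] <- list(pos = k - 1, vertex = k, point = p)
    } else if (abs(s - 1) <= vtol) {
      k2 <- if (k == n) 1L else k + 1L
      if (k2 %in% seen_vertex) next
      seen_vertex <- c(seen_vertex, k2)
      cuts[[length(cuts) + 1L]] <- list(pos = k2 - 1, vertex = k2, point = q)
    } else {
      cuts[[length(cuts) + 1L]] <- list(pos = k - 1 + s, vertex = NA_integer_,
                                        point = p + s * (q - p), edge = k)
    }
  }
  defer <- function(reason) list(mesh = mesh, cells = cells, divided = FALSE,
                                 daughter_ids = NULL, reason = reason)
  if (length(cuts) != 2L) return(defer("split line does not cross the boundary twice"))
  if (cuts[[1]]$pos > cuts[[2]]$pos) cuts <- cuts[c(2, 1)]
  u <- cuts[[1]]; w <- cuts[[2]]
  if (abs(u$pos - w$pos) < vtol) return(defer("coincident cut points"))

  # materialise cut nodes
  cut_node <- integer(2)
  for (i in 1:2) {
    cut <- list(u, w)[[i]]
    if (!is.na(cut$vertex)) {
      cut_node[i] <- ring[cut$vertex]
    } else {
      mesh$coords <- rbind(mesh$coords, cut$point)
      cut_node[i] <- nrow(mesh$coords)
      # share the new node with the neighbour across the cut edge
      va <- ring[cut$edge]
      vb <- ring[if (cut$edge == n) 1L else cut$edge + 1L]
      for (kk in seq_along(mesh$elements)) {
        if (kk == element) next
        r <- mesh$elements[[kk]]
        ia <- match(va, r); ib <- match(vb, r)
        if (!is.na(ia) && !is.na(ib)) {
          # neighbour traverses vb -> va; insert between them
          if (r[if (ib == length(r)) 1L else ib + 1L] == va) {
            mesh$elements[[kk]] <- ring_insert_before(r, va, cut_node[i])
          }
        }
      }
    }
  }
  inner <- function(lo, hi) ring[which(seq_len(n) - 1 > lo + vtol &
                                         seq_len(n) - 1 < hi - vtol)]
  ring1 <- c(cut_node[1], inner(u$pos, w$pos), cut_node[2])
  wrap <- c(which(seq_len(n) - 1 > w$pos + vtol), which(seq_len(n) - 1 < u$pos - vtol))
  ring2 <- c(cut_node[2], ring[wrap], cut_node[1])
  ring1 <- unique(ring1); ring2 <- unique(ring2)
  if (length(ring1) < 3L || length(ring2) < 3L) {
    return(defer("a daughter would have fewer than 3 nodes"))
  }
  md <- make_daughters(cells, match(mesh$cell_ids[element], cells$id), t,
                       params = params, ready = ready)
  mesh$elements[[element]] <- ring1
  mesh$cell_ids[element] <- md$daughter_ids[1]
  mesh$elements[[length(mesh$elements) + 1L]] <- ring2
  mesh$cell_ids <- c(mesh$cell_ids, md$daughter_ids[2])
  list(mesh = mesh, cells = md$cells, divided = TRUE,
       daughter_ids = md$daughter_ids, reason = "")
}

#' Heterotypic boundary fraction of a vertex mesh
#'
#' Length fraction of interior edges whose two flanking cells differ in type:
#' 0 for a fully sorted or monotypic tissue, approaching the random-mixing
#' value for a scrambled one. The quantitative readout of differential-
#' adhesion cell sorting.
#'
#' @param mesh A `vertex_mesh` with at least one interior edge.
#' @param cells Cell table supplying cell types.
#' @return Fraction in [0, 1].
#' @export
heterotypic_fraction <- function(mesh, cells) {
  edges <- mesh_edges(mesh)
  interior <- !is.na(edges$elem2)
  if (!any(interior)) {
    ts_stop("heterotypic fraction undefined: mesh has no interior edges",
            "tissuesim_undefined_metric")
  }
  edges <- edges[interior, , drop = FALSE]
  rows <- element_cell_rows(mesh, cells)
  het <- cells$type[rows[edges$elem1]] != cells$type[rows[edges$elem2]]
  sum(edges$length[het]) / sum(edges$length)
}

#' One vertex-model mechanics step
#'
#' Forward Euler update `x <- x + (dt/drag) * F` with optional isotropic
#' Gaussian nodal noise, followed by T1 checks (ascending edge order, at most
#' one swap per node per step) and T2 checks.
#'
#' @inheritParams tissue_energy
#' @return List with `mesh`, `cells`, `n_t1`, `removed_cell_ids`.
#' @export
vm_step <- function(mesh, cells, params) {
  f <- nodal_forces(mesh, cells, params)
  mesh$coords <- mesh$coords + (params$dt / params$drag) * f
  if (params$noise > 0) {
    mesh$coords <- mesh$coords +
      matrix(stats::rnorm(length(mesh$coords), sd = params$noise),
             ncol = 2)
  }
  n_t1 <- 0L
  if (params$d_t1 > 0) {
    edges <- mesh_edges(mesh)
    short <- edges[!is.na(edges$elem2) & edges$length < params$d_t1, , drop = FALSE]
    touched <- integer(0)
    for (i in seq_len(nrow(short))) {
      a <- short$a[i]; b <- short$b[i]
      if (a %in% touched || b %in% touched) next
      res <- t1_swap(mesh, c(a, b), params)
      if (res$swapped) {
        mesh <- res$mesh
        n_t1 <- n_t1 + 1L
        touched <- c(touched, a, b)
      }
    }
  }
  removed <- integer(0)
  if (params$a_t2 > 0) {
    repeat {
      areas <- element_areas(mesh)
      sizes <- lengths(mesh$elements)
      cand <- which(sizes == 3L & areas < params$a_t2)
      if (length(cand) == 0L) break
      res <- t2_remove(mesh, cand[1], cells, params)
      if (!res$removed) break
      mesh <- res$mesh
      cells <- res$cells
      removed <- c(removed, res$removed_cell_id)
    }
  }
  list(mesh = mesh, cells = cells, n_t1 = n_t1, removed_cell_ids = removed)
}
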