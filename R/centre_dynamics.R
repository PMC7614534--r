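# Cell-centre frameworks: each cell is a point; mechanics act through
# pairwise linear (Hookean) springs between neighbours, with neighbours
# defined either by a distance cutoff (overlapping spheres, PM) or by shared
# Delaunay edges (Voronoi tessellation, VT). Positions follow overdamped
# forward Euler: x <- x + (dt/eta) * F.

#' Construct a cell-centre population
#'
#' @param coords n x 2 matrix of cell-centre positions, one row per cell.
#' @param cell_ids Integer cell ids, one per row (default `1:n`).
#' @param mode Connectivity rule: "overlapping_spheres" or "voronoi".
#' @param cutoff Interaction radius for overlapping-spheres mode (> 0;
#'   default 1.5 rest lengths).
#' @return A `centre_population` object.
#' @export
centre_population <- function(coords, cell_ids = seq_len(nrow(coords)),
                              mode = c("overlapping_spheres", "voronoi"),
                              cutoff = 1.5) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) {
    ts_stop("non-finite centre coordinates", "tissuesim_config_error")
  }
  if (mode == "overlapping_spheres" && (!is.finite(cutoff) || cutoff <= 0)) {
    ts_stop("cutoff must be positive in overlapping_spheres mode",
            "tissuesim_config_error")
  }
  structure(list(coords = coords, cell_ids = as.integer(cell_ids),
                 mode = mode, cutoff = cutoff),
            class = "centre_population")
}

#' @export
print.centre_population <- function(x, ...) {
  cat(sprintf("<centre_population (%s): %d cells>\n", x$mode, nrow(x$coords)))
  invisible(x)
}

#' Neighbour pairs of a cell-centre population
#'
#' Overlapping-spheres mode: all pairs with separation strictly below the
#' cutoff. Voronoi mode: [delaunay_pairs()] of the positions.
#'
#' @param pop A `centre_population`.
#' @return Two-column integer matrix of row-index pairs (`[,1] < [,2]`).
#' @export
neighbour_pairs <- function(pop) {
  n <- nrow(pop$coords)
  if (pop$mode == "voronoi") {
    return(delaunay_pairs(pop$coords))
  }
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(pop$coords))
  hit <- which(upper.tri(d) & d < pop$cutoff, arr.ind = TRUE)
  out <- cbind(hit[, "row"], hit[, "col"])
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Cell-centre mechanics parameters
#'
#' @param stiffness Spring constant mu (force per unit length, > 0).
#' @param rest_length Mature cell separation (default 1 cell diameter).
#' @param growth_duration Time over which a newborn sibling pair's rest
#'   length ramps linearly from `newborn_separation` to `rest_length`.
#' @param newborn_separation Initial daughter spacing, in
#'   (0, `rest_length`).
#' @param drag Drag coefficient eta (> 0).
#' @param dt Time step (> 0).
#' @return A `centre_params` object.
#' @export
centre_params <- function(stiffness = 15, rest_length = 1,
                          growth_duration = 1, newborn_separation = 0.3,
                          drag = 1, dt = 0.005) {
  if (stiffness <= 0 || drag <= 0 || dt <= 0 ||
      !(newborn_separation > 0 && newborn_separation < rest_length) ||
      growth_duration < 0) {
    ts_stop("invalid centre-model parameter (see ?centre_params)",
            "tissuesim_config_error")
  }
  structure(list(stiffness = stiffness, rest_length = rest_length,
                 growth_duration = growth_duration,
                 newborn_separation = newborn_separation,
                 drag = drag, dt = dt),
            class = "centre_params")
}

# rest length of the pair (id1, id2) at time t, given the sibling registry
# (data.frame id1, id2, t0); expired entries act as ordinary neighbours
pair_rest_length <- function(id1, id2, t, params, siblings) {
  s <- params$rest_length
  if (is.null(siblings) || nrow(siblings) == 0L) return(rep(s, length(id1)))
  key <- paste(pmin(id1, id2), pmax(id1, id2))
  skey <- paste(pmin(siblings$id1, siblings$id2), pmax(siblings$id1, siblings$id2))
  hit <- match(key, skey)
  out <- rep(s, length(id1))
  found <- !is.na(hit)
  if (any(found)) {
    age <- t - siblings$t0[hit[found]]
    frac <- pmin(1, pmax(0, age / params$growth_duration))
    out[found] <- params$newborn_separation +
      frac * (s - params$newborn_separation)
  }
  out
}

#' Pairwise spring forces on cell centres
#'
#' Linear spring on each neighbour pair: magnitude
#' `mu * (separation - rest length)`, attractive when stretched, repulsive
#' when compressed, equal and opposite on the two cells. Sibling pairs
#' younger than `growth_duration` use the ramped rest length. Coincident
#' centres are pushed apart along a random unit vector.
#'
#' @param pop A `centre_population`.
#' @param pairs Neighbour pairs as from [neighbour_pairs()].
#' @param params A [centre_params()].
#' @param t Current time (for the sibling ramp).
#' @param siblings Sibling registry (data.frame id1, id2, t0) or NULL.
#' @return n x 2 matrix of force vectors.
#' @export
spring_forces <- function(pop, pairs, params, t = 0, siblings = NULL) {
  n <- nrow(pop$coords)
  f <- matrix(0, n, 2)
  if (nrow(pairs) == 0L) return(f)
  i <- pairs[, 1]; j <- pairs[, 2]
  dv <- pop$coords[j, , drop = FALSE] - pop$coords[i, , drop = FALSE]
  len <- sqrt(rowSums(dv^2))
  coincident <- len < 1e-12
  if (any(coincident)) {
    for (k in which(coincident)) {
      ang <- stats::runif(1, 0, 2 * pi)
      dv[k, ] <- c(cos(ang), sin(ang)) * 1e-12
      len[k] <- 1e-12
    }
  }
  u <- dv / len
  s <- pair_rest_length(pop$cell_ids[i], pop$cell_ids[j], t, params, siblings)
  mag <- params$stiffness * (len - s)
  fx <- rowsum(c(mag * u[, 1], -mag * u[, 1]), c(i, j))
  fy <- rowsum(c(mag * u[, 2], -mag * u[, 2]), c(i, j))
  ids <- as.integer(rownames(fx))
  f[ids, 1] <- fx[, 1]
  f[ids, 2] <- fy[, 1]
  f
}

#' Overdamped Euler position update
#'
#' @param pop A `centre_population`.
#' @param forces n x 2 force matrix, one row per cell.
#' @param params A [centre_params()] supplying `dt` and `drag`.
#' @return The population with updated coordinates.
#' @export
step_positions <- function(pop, forces, params) {
  if (!all(is.finite(forces))) {
    bad <- which(rowSums(!is.finite(forces)) > 0)[1]
    ts_stop(sprintf("non-finite force on node %d", bad), "tissuesim_integration_error")
  }
  pop$coords <- pop$coords + (params$dt / params$drag) * forces
  pop
}

#' Divide a cell-centre cell
#'
#' Replaces the parent node by two daughter nodes at
#' `+/- newborn_separation / 2` along a uniformly random direction about the
#' parent position, registers the sibling pair for rest-length ramping, and
#' updates the cell table via [make_daughters()].
#'
#' @param pop A `centre_population`.
#' @param cell_id Id of the dividing cell.
#' @param cells Cell table.
#' @param params A [centre_params()].
#' @param t Division time.
#' @param cycle A [cycle_params()].
#' @param siblings Sibling registry to extend (may be NULL).
#' @param ready Readiness guard.
#' @return List with `pop`, `cells`, `siblings`, `daughter_ids`.
#' @export
divide_centre_cell <- function(pop, cell_id, cells, params, t = 0,
                               cycle = cycle_params(), siblings = NULL,
                               ready = TRUE) {
  row <- match(cell_id, pop$cell_ids)
  crow <- match(cell_id, cells$id)
  md <- make_daughters(cells, crow, t, params = cycle, ready = ready)
  ang <- stats::runif(1, 0, 2 * pi)
  dir <- c(cos(ang), sin(ang))
  parent_pos <- pop$coords[row, ]
  half <- params$newborn_separation / 2
  pop$coords[row, ] <- parent_pos + half * dir
  pop$coords <- rbind(pop$coords, parent_pos - half * dir)
  pop$cell_ids[row] <- md$daughter_ids[1]
  pop$cell_ids <- c(pop$cell_ids, md$daughter_ids[2])
  sib <- data.frame(id1 = md$daughter_ids[1], id2 = md$daughter_ids[2], t0 = t)
  siblings <- if (is.null(siblings)) sib else rbind(siblings, sib)
  list(pop = pop, cells = md$cells, siblings = siblings,
       daughter_ids = md$daughter_ids)
}
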