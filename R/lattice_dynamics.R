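# On-lattice frameworks. Cellular Potts: Metropolis-accepted copy attempts on
#   H = sum_cells lambda_area (A_s - A0_s)^2
#     + sum_{neighbouring site pairs} J(type_i, type_j) [sigma_i != sigma_j],
# each unordered pair counted once, medium sites using the medium type index.
# Cellular automaton: exclusion dynamics, at most one cell per site.

#' Cellular Potts parameters
#'
#' @param lambda_area Area-constraint stiffness (>= 0).
#' @param adhesion Symmetric contact-energy matrix J indexed by cell-type
#'   pair with the medium first (row/column 1 = medium, row `t + 2` = cell
#'   type `t`). A scalar is expanded over `n_types`.
#' @param n_types Number of cell types `adhesion` must cover when scalar.
#' @param temperature Metropolis temperature (> 0).
#' @param sweeps_per_step Copy attempts per unit time as a multiple of the
#'   site count.
#' @return A `potts_params` object.
#' @export
potts_params <- function(lambda_area = 1, adhesion = 1, n_types = 1,
                         temperature = 1, sweeps_per_step = 1) {
  if (is.matrix(adhesion)) {
    if (nrow(adhesion) != ncol(adhesion) ||
        !isTRUE(all.equal(adhesion, t(adhesion)))) {
      ts_stop("adhesion must be a symmetric square matrix", "tissuesim_config_error")
    }
  } else {
    k <- n_types + 1L
    adhesion <- matrix(adhesion, k, k)
  }
  if (lambda_area < 0 || temperature <= 0 || sweeps_per_step <= 0) {
    ts_stop("invalid Potts parameter (see ?potts_params)", "tissuesim_config_error")
  }
  structure(list(lambda_area = lambda_area, adhesion = adhesion,
                 temperature = temperature, sweeps_per_step = sweeps_per_step),
            class = "potts_params")
}

#' Cellular automaton parameters
#'
#' @param motility Probability per step that a cell attempts a move to a
#'   vacant neighbour site, in [0, 1].
#' @param division_into_vacant Whether division-ready cells may place a
#'   daughter into a vacant neighbour site (deferred when none is free).
#' @return A `ca_params` object.
#' @export
ca_params <- function(motility = 1, division_into_vacant = TRUE) {
  if (motility < 0 || motility > 1) {
    ts_stop("motility must be in [0, 1]", "tissuesim_config_error")
  }
  structure(list(motility = motility,
                 division_into_vacant = isTRUE(division_into_vacant)),
            class = "ca_params")
}

# per-site type index matrix: medium -> 1, cell type t -> t + 2
occupancy_type_index <- function(lat, cells) {
  ids <- as.vector(lat$occupancy)
  unknown <- setdiff(unique(ids), c(0L, cells$id))
  if (length(unknown) > 0L) {
    ts_stop("occupancy references an unknown cell id", "tissuesim_state_error")
  }
  ti <- rep(1L, length(ids))
  hit <- ids != 0L
  ti[hit] <- type_index(cells$type[match(ids[hit], cells$id)])
  matrix(ti, nrow = lat$height)
}

#' Cellular Potts Hamiltonian
#'
#' @param lat A CP-mode `lattice`.
#' @param cells Cell table (target areas, types).
#' @param params A [potts_params()].
#' @return Scalar energy.
#' @export
potts_energy <- function(lat, cells, params) {
  ti <- occupancy_type_index(lat, cells)
  occ <- lat$occupancy
  a <- lattice_areas(lat)
  rows <- match(as.integer(names(a)), cells$id)
  if (anyNA(rows)) ts_stop("occupancy references an unknown cell id",
                           "tissuesim_state_error")
  e_area <- sum(params$lambda_area * (a - cells$target_area[rows])^2)
  # each unordered neighbouring pair once, via forward shifts
  shifts <- if (lat$neighbourhood == "von_neumann") {
    list(c(0L, 1L), c(1L, 0L))
  } else {
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  }
  e_int <- 0
  h <- lat$height; w <- lat$width
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    o1 <- occ[r1, c1, drop = FALSE]
    o2 <- occ[r1 + dr, c1 + dc, drop = FALSE]
    t1 <- ti[r1, c1, drop = FALSE]
    t2 <- ti[r1 + dr, c1 + dc, drop = FALSE]
    diff <- o1 != o2
    if (any(diff)) {
      e_int <- e_int + sum(params$adhesion[cbind(t1[diff], t2[diff])])
    }
  }
  e_area + e_int
}

# Local energy change of copying the id/type at site i onto site j.
# Exact: only site j changes, so only pairs involving j contribute, plus the
# two area terms.
potts_delta_h <- function(lat, cells, params, row_j, col_j, sigma_i, areas = NULL) {
  occ <- lat$occupancy
  sigma_j <- occ[row_j, col_j]
  if (is.null(areas)) areas <- lattice_areas(lat)
  type_of <- function(id) {
    if (id == 0L) 1L else type_index(cells$type[match(id, cells$id)])
  }
  ti_new <- type_of(sigma_i)
  ti_old <- type_of(sigma_j)
  nb <- site_neighbours(lat, row_j, col_j)
  d_int <- 0
  for (k in seq_len(nrow(nb))) {
    sk <- occ[nb[k, 1], nb[k, 2]]
    tk <- type_of(sk)
    if (sigma_i != sk) d_int <- d_int + params$adhesion[ti_new, tk]
    if (sigma_j != sk) d_int <- d_int - params$adhesion[ti_old, tk]
  }
  d_area <- 0
  lam <- params$lambda_area
  if (sigma_j != 0L) {
    a0 <- cells$target_area[match(sigma_j, cells$id)]
    aj <- areas[[as.character(sigma_j)]]
    d_area <- d_area + lam * ((aj - 1 - a0)^2 - (aj - a0)^2)
  }
  if (sigma_i != 0L) {
    a0 <- cells$target_area[match(sigma_i, cells$id)]
    ai <- areas[[as.character(sigma_i)]]
    if (is.null(ai) || is.na(ai)) ai <- 0
    d_area <- d_area + lam * ((ai + 1 - a0)^2 - (ai - a0)^2)
  }
  d_int + d_area
}

#' Metropolis acceptance rule
#'
#' Accept with probability `min(1, exp(-delta_h / temperature))`, drawing one
#' uniform variate per decision from the simulation RNG stream. Vectorised
#' over `delta_h`.
#'
#' @param delta_h Proposed energy change(s).
#' @param temperature Metropolis temperature (> 0).
#' @return Logical vector of acceptances.
#' @export
metropolis_accept <- function(delta_h, temperature) {
  stats::runif(length(delta_h)) < exp(pmin(0, -delta_h / temperature))
}

#' One Metropolis copy attempt
#'
#' Picks a uniform random site i and a uniform random neighbour j; when their
#' cell ids differ, proposes copying i's id onto j and accepts with the
#' Boltzmann probability on the local energy change (which equals the global
#' recomputation exactly).
#'
#' @param lat A CP-mode `lattice`.
#' @param cells Cell table.
#' @param params A [potts_params()].
#' @return List with `lattice`, logical `accepted`, logical `proposed`, and
#'   `delta_h` (NA when no heterogeneous pair was drawn).
#' @export
metropolis_attempt <- function(lat, cells, params) {
  h <- lat$height; w <- lat$width
  site <- sample.int(h * w, 1L)
  row_i <- ((site - 1L) %% h) + 1L
  col_i <- ((site - 1L) %/% h) + 1L
  nb <- site_neighbours(lat, row_i, col_i)
  j <- nb[sample.int(nrow(nb), 1L), ]
  sigma_i <- lat$occupancy[row_i, col_i]
  sigma_j <- lat$occupancy[j[1], j[2]]
  if (sigma_i == sigma_j) {
    return(list(lattice = lat, accepted = FALSE, proposed = FALSE,
                delta_h = NA_real_))
  }
  dh <- potts_delta_h(lat, cells, params, j[1], j[2], sigma_i)
  acc <- metropolis_accept(dh, params$temperature)
  if (acc) lat$occupancy[j[1], j[2]] <- sigma_i
  list(lattice = lat, accepted = acc, proposed = TRUE, delta_h = dh)
}

#' One cellular Potts time step
#'
#' `sweeps_per_step * site count` Metropolis copy attempts with incremental
#' area bookkeeping; cells reduced to zero sites are removed from the
#' population.
#'
#' @inheritParams metropolis_attempt
#' @return List with `lattice`, `cells`, `accepted` (count), and
#'   `removed_cell_ids`.
#' @export
potts_step <- function(lat, cells, params) {
  h <- lat$height; w <- lat$width
  occ <- lat$occupancy
  n_sites <- h * w
  n_attempts <- max(1L, as.integer(round(params$sweeps_per_step * n_sites)))
  areas <- rep(0, max(cells$id))
  tab <- lattice_areas(lat)
  areas[as.integer(names(tab))] <- tab
  a0 <- rep(NA_real_, max(cells$id))
  a0[cells$id] <- cells$target_area
  tix <- rep(NA_integer_, max(cells$id))
  tix[cells$id] <- type_index(cells$type)
  J <- params$adhesion
  if (max(tix, na.rm = TRUE) > nrow(J)) {
    ts_stop("adhesion matrix smaller than the number of cell types in play",
            "tissuesim_config_error")
  }
  lam <- params$lambda_area
  temp <- params$temperature
  off <- neighbour_offsets(lat$neighbourhood)
  n_off <- nrow(off)
  accepted <- 0L

  sites <- sample.int(n_sites, n_attempts, replace = TRUE)
  which_nb <- sample.int(n_off, n_attempts, replace = TRUE)
  u <- stats::runif(n_attempts)
  for (k in seq_len(n_attempts)) {
    site <- sites[k]
    ri <- ((site - 1L) %% h) + 1L
    ci <- ((site - 1L) %/% h) + 1L
    rj <- ri + off[which_nb[k], "dy"]
    cj <- ci + off[which_nb[k], "dx"]
    if (rj < 1L || rj > h || cj < 1L || cj > w) next
    si <- occ[ri, ci]
    sj <- occ[rj, cj]
    if (si == sj) next
    # local delta H over site j's neighbourhood
    ti_new <- if (si == 0L) 1L else tix[si]
    ti_old <- if (sj == 0L) 1L else tix[sj]
    d_int <- 0
    for (m in seq_len(n_off)) {
      rk <- rj + off[m, "dy"]; ck <- cj + off[m, "dx"]
      if (rk < 1L || rk > h || ck < 1L || ck > w) next
      sk <- occ[rk, ck]
      tk <- if (sk == 0L) 1L else tix[sk]
      if (si != sk) d_int <- d_int + J[ti_new, tk]
      if (sj != sk) d_int <- d_int - J[ti_old, tk]
    }
    d_area <- 0
    if (sj != 0L) d_area <- d_area + lam * ((areas[sj] - 1 - a0[sj])^2 -
                                              (areas[sj] - a0[sj])^2)
    if (si != 0L) d_area <- d_area + lam * ((areas[si] + 1 - a0[si])^2 -
                                              (areas[si] - a0[si])^2)
    dh <- d_int + d_area
    if (u[k] < exp(min(0, -dh / temp))) {
      occ[rj, cj] <- si
      if (sj != 0L) areas[sj] <- areas[sj] - 1
      if (si != 0L) areas[si] <- areas[si] + 1
      accepted <- accepted + 1L
    }
  }
  lat$occupancy <- occ
  gone <- cells$id[areas[cells$id] == 0]
  if (length(gone) > 0L) {
    cells <- cells[!cells$id %in% gone, , drop = FALSE]
    rownames(cells) <- NULL
  }
  list(lattice = lat, cells = cells, accepted = accepted,
       removed_cell_ids = gone)
}

#' Heterotypic interface count of a Potts lattice
#'
#' Number of neighbouring site pairs whose owners are two distinct cells of
#' different types (medium contacts excluded) -- the lattice analogue of the
#' vertex-model heterotypic boundary fraction.
#'
#' @param lat A `lattice`.
#' @param cells Cell table.
#' @return Integer count.
#' @export
potts_heterotypic_interfaces <- function(lat, cells) {
  ti <- occupancy_type_index(lat, cells)
  occ <- lat$occupancy
  shifts <- if (lat$neighbourhood == "von_neumann") {
    list(c(0L, 1L), c(1L, 0L))
  } else {
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  }
  h <- lat$height; w <- lat$width
  count <- 0L
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- max(1L, 1L - dr):min(h, h - dr)
    c1 <- max(1L, 1L - dc):min(w, w - dc)
    o1 <- occ[r1, c1, drop = FALSE]; o2 <- occ[r1 + dr, c1 + dc, drop = FALSE]
    t1 <- ti[r1, c1, drop = FALSE]; t2 <- ti[r1 + dr, c1 + dc, drop = FALSE]
    count <- count + sum(o1 != o2 & o1 != 0L & o2 != 0L & t1 != t2)
  }
  count
}

#' One cellular automaton time step
#'
#' Cells are visited in random order; each moves with probability `motility`
#' to a uniformly chosen vacant neighbour site (staying put when none is
#' free). Division-ready cells then place a daughter in a uniformly chosen
#' vacant neighbour, deferring when none is free. At most one cell per site
#' always.
#'
#' @param lat A CA-mode `lattice`.
#' @param cells Cell table.
#' @param params A [ca_params()].
#' @param ready Logical vector (per cell row) of division-ready flags;
#'   default none.
#' @param t Current time (daughter birth time).
#' @param cycle A [cycle_params()] for daughter G1 draws.
#' @return List with `lattice`, `cells`, and `n_divisions`.
#' @export
ca_step <- function(lat, cells, params, ready = NULL, t = 0,
                    cycle = cycle_params()) {
  if (lat$mode != "CA") ts_stop("ca_step requires a CA-mode lattice",
                                "tissuesim_state_error")
  occ <- lat$occupancy
  n <- nrow(cells)
  if (is.null(ready)) ready <- logical(n)
  order_idx <- if (n > 1L) sample.int(n) else seq_len(n)
  pos <- match(cells$id, as.vector(occ))
  h <- lat$height
  row_of <- function(p) ((p - 1L) %% h) + 1L
  col_of <- function(p) ((p - 1L) %/% h) + 1L
  # movement phase
  for (i in order_idx) {
    if (params$motility <= 0) break
    if (stats::runif(1) >= params$motility) next
    p <- pos[i]
    nb <- site_neighbours(lat, row_of(p), col_of(p))
    vac <- nb[occ[nb] == 0L, , drop = FALSE]
    if (nrow(vac) == 0L) next
    pick <- vac[sample.int(nrow(vac), 1L), ]
    occ[row_of(p), col_of(p)] <- 0L
    occ[pick[1], pick[2]] <- cells$id[i]
    pos[i] <- (pick[2] - 1L) * h + pick[1]
  }
  lat$occupancy <- occ
  # division phase, ascending cell id among ready cells
  n_div <- 0L
  if (any(ready) && params$division_into_vacant) {
    res <- ca_divide(lat, cells, ready, t = t, cycle = cycle)
    lat <- res$lattice
    cells <- res$cells
    n_div <- res$n_divisions
  }
  list(lattice = lat, cells = cells, n_divisions = n_div)
}

# Place daughters of division-ready CA cells into uniformly chosen vacant
# neighbour sites (ascending cell id; deferred when no site is free).
ca_divide <- function(lat, cells, ready, t = 0, cycle = cycle_params()) {
  occ <- lat$occupancy
  h <- lat$height
  row_of <- function(p) ((p - 1L) %% h) + 1L
  col_of <- function(p) ((p - 1L) %/% h) + 1L
  n_div <- 0L
  for (id in sort(cells$id[ready])) {
    i <- match(id, cells$id)
    p <- match(id, as.vector(occ))
    nb <- site_neighbours(lat, row_of(p), col_of(p))
    vac <- nb[occ[nb] == 0L, , drop = FALSE]
    if (nrow(vac) == 0L) next  # deferred
    pick <- vac[sample.int(nrow(vac), 1L), ]
    md <- make_daughters(cells, i, t, params = cycle, ready = TRUE)
    cells <- md$cells
    occ[row_of(p), col_of(p)] <- md$daughter_ids[1]
    occ[pick[1], pick[2]] <- md$daughter_ids[2]
    n_div <- n_div + 1L
  }
  lat$occupancy <- occ
  list(lattice = lat, cells = cells, n_divisions = n_div)
}
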