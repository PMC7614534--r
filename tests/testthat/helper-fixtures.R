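# Shared fixtures and independent oracles, all built in code.

# random convex polygon: n points on a circle in angular order
random_convex_polygon <- function(n, r = 1) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  cbind(r * cos(ang), r * sin(ang))
}

# O(n^4) empty-circumcircle oracle: edge (i,j) is Delaunay iff some triangle
# (i,j,k) has no other point inside its circumcircle
brute_delaunay_pairs <- function(pts) {
  n <- nrow(pts)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    r2 <- sum((a - c(ux, uy))^2)
    others <- setdiff(1:n, c(i, j, k))
    inside <- any(rowSums(sweep(pts[others, , drop = FALSE], 2,
                                c(ux, uy))^2) < r2 * (1 - 1e-12))
    if (!inside) {
      pairs <- rbind(pairs, c(i, j), c(i, k), c(j, k))
    }
  }
  pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                        pmax(pairs[, 1], pairs[, 2])))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# ray-casting point-in-polygon (for the centroid Monte-Carlo oracle)
point_in_polygon <- function(p, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    if ((ring[i, 2] > p[2]) != (ring[j, 2] > p[2]) &&
        p[1] < (ring[j, 1] - ring[i, 1]) * (p[2] - ring[i, 2]) /
          (ring[j, 2] - ring[i, 2]) + ring[i, 1]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# central-difference gradient of the vertex-model energy
numeric_mesh_gradient <- function(mesh, cells, params, h = 1e-6) {
  g <- matrix(0, nrow(mesh$coords), 2)
  for (i in seq_len(nrow(mesh$coords))) for (d in 1:2) {
    mp <- mesh; mp$coords[i, d] <- mp$coords[i, d] + h
    mm <- mesh; mm$coords[i, d] <- mm$coords[i, d] - h
    g[i, d] <- (tissue_energy(mp, cells, params) -
                  tissue_energy(mm, cells, params)) / (2 * h)
  }
  g
}

# total spring potential of a centre population (for the PM gradient oracle)
centre_potential <- function(coords, pairs, stiffness, rest) {
  if (nrow(pairs) == 0L) return(0)
  d <- sqrt(rowSums((coords[pairs[, 2], , drop = FALSE] -
                       coords[pairs[, 1], , drop = FALSE])^2))
  sum(stiffness / 2 * (d - rest)^2)
}

numeric_centre_gradient <- function(pop, pairs, params, h = 1e-6) {
  g <- matrix(0, nrow(pop$coords), 2)
  for (i in seq_len(nrow(pop$coords))) for (d in 1:2) {
    cp <- pop$coords; cp[i, d] <- cp[i, d] + h
    cm <- pop$coords; cm[i, d] <- cm[i, d] - h
    g[i, d] <- (centre_potential(cp, pairs, params$stiffness, params$rest_length) -
                  centre_potential(cm, pairs, params$stiffness, params$rest_length)) / (2 * h)
  }
  g
}

# T2 fixture that tiles exactly: small central triangle inside a big one,
# three quads between them; collapsing the centre preserves total area
t2_tiling_fixture <- function(eps = 0.05) {
  big <- rbind(c(0, 2), c(-sqrt(3), -1), c(sqrt(3), -1))
  small <- big * eps
  coords <- rbind(small, big)  # 1:3 inner, 4:6 outer
  els <- list(
    c(1, 2, 3),
    c(1, 4, 5, 2),
    c(2, 5, 6, 3),
    c(3, 6, 4, 1)
  )
  vertex_mesh(coords, els)
}

# 4-element honeycomb with one interior edge shrunk below d_t1; returns the
# mesh, the short edge, and the expected adjacency change
shrunk_edge_fixture <- function(shrink = 0.5, d_t1 = 0.1) {
  m <- build_honeycomb_mesh(2, 2, 1)
  e <- mesh_edges(m)
  e <- e[!is.na(e$elem2), ]
  # pick the interior edge whose endpoints each touch 3 elements
  n_elems_of <- function(v) sum(vapply(m$elements, function(r) v %in% r, logical(1)))
  ok <- vapply(seq_len(nrow(e)), function(i) {
    n_elems_of(e$a[i]) == 3L && n_elems_of(e$b[i]) == 3L
  }, logical(1))
  edge <- e[which(ok)[1], ]
  mid <- colMeans(m$coords[c(edge$a, edge$b), ])
  m$coords[edge$a, ] <- mid + shrink * d_t1 / 2 *
    (m$coords[edge$a, ] - mid) / sqrt(sum((m$coords[edge$a, ] - mid)^2))
  m$coords[edge$b, ] <- mid + shrink * d_t1 / 2 *
    (m$coords[edge$b, ] - mid) / sqrt(sum((m$coords[edge$b, ] - mid)^2))
  list(mesh = m, edge = c(edge$a, edge$b),
       sharing = sort(c(edge$elem1, edge$elem2)))
}

# element adjacency pairs computed independently of mesh_edges: two elements
# are adjacent when they share two nodes that are consecutive in both rings
element_adjacency <- function(mesh) {
  n <- length(mesh$elements)
  out <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    shared <- intersect(mesh$elements[[i]], mesh$elements[[j]])
    if (length(shared) >= 2L) {
      ri <- mesh$elements[[i]]
      consec <- any(vapply(seq_along(ri), function(k) {
        nk <- if (k == length(ri)) 1L else k + 1L
        ri[k] %in% shared && ri[nk] %in% shared
      }, logical(1)))
      if (consec) out <- c(out, paste(i, j))
    }
  }
  sort(out)
}

# a small two-type CP blob used by sorting tests
cp_sorting_setup <- function(seed, n_cells = 12, width = 30, radius = 10) {
  set.seed(seed)
  lat <- build_lattice_blob(width, width, radius, n_cells, mode = "CP")
  types <- rep_len(0:1, n_cells)
  cells <- new_cell_table(n_cells, types = sample(types),
                          target_area = mean(lattice_areas(lat)))
  j <- matrix(0, 3, 3)
  j[2, 2] <- j[3, 3] <- 2; j[2, 3] <- j[3, 2] <- 11
  j[1, 2] <- j[2, 1] <- j[1, 3] <- j[3, 1] <- 16
  params <- potts_params(lambda_area = 1, adhesion = j, temperature = 2,
                         sweeps_per_step = 1)
  list(lattice = lat, cells = cells, params = params)
}
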