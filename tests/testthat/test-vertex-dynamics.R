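test_that("tissue energy matches closed forms and a term-enumeration oracle", {
  # relaxed hexagon with only the area term: zero energy
  m <- build_honeycomb_mesh(1, 1, 1)
  cells <- new_cell_table(1, target_area = element_areas(m))
  vp <- vertex_params(k_area = 2, k_perimeter = 0, gamma = 0)
  expect_equal(tissue_energy(m, cells, vp), 0, tolerance = 1e-12)

  # unit square, A0 = 0.5, k_area = 2: (2/2)(1 - 0.5)^2 = 0.25
  sq <- vertex_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4))
  csq <- new_cell_table(1, target_area = 0.5)
  expect_equal(tissue_energy(sq, csq, vertex_params(k_area = 2, k_perimeter = 0,
                                                    gamma = 0)),
               0.25, tolerance = 1e-12)

  # random 4-hexagon mesh vs explicit term-by-term recomputation
  set.seed(31)
  m <- build_honeycomb_mesh(2, 2, 1)
  m$coords <- m$coords + matrix(runif(length(m$coords), -0.05, 0.05), ncol = 2)
  cells <- new_cell_table(4, types = c(0, 1, 1, 0), target_area = 2.2)
  g <- matrix(c(0.3, 0.2, 0.25, 0.2, 0.1, 0.4, 0.25, 0.4, 0.15), 3, 3)
  vp <- vertex_params(k_area = 7, k_perimeter = 0.3, gamma = g, n_types = 2)
  # oracle: walk each element's edges explicitly
  e_oracle <- 0
  for (k in 1:4) {
    ring <- m$elements[[k]]
    pts <- m$coords[ring, ]
    a <- signed_area(pts); p <- ring_perimeter(pts)
    e_oracle <- e_oracle + 7 / 2 * (a - 2.2)^2 + 0.3 / 2 * p^2
  }
  seen <- character(0)
  for (k in 1:4) {
    ring <- m$elements[[k]]
    nseg <- length(ring)
    for (i in seq_len(nseg)) {
      a <- ring[i]; b <- ring[if (i == nseg) 1 else i + 1]
      key <- paste(min(a, b), max(a, b))
      if (key %in% seen) next
      seen <- c(seen, key)
      sharing <- which(vapply(m$elements, function(r) {
        all(c(a, b) %in% r)
      }, logical(1)))
      # keep only elements where a,b are consecutive
      sharing <- sharing[vapply(sharing, function(el) {
        r <- m$elements[[el]]
        ia <- match(a, r); ib <- match(b, r); nn <- length(r)
        abs(ia - ib) %in% c(1, nn - 1)
      }, logical(1))]
      tt <- sort(cells$type[match(m$cell_ids[sharing], cells$id)])
      idx <- if (length(sharing) == 2L) c(tt[1] + 2, tt[2] + 2) else c(1, tt[1] + 2)
      len <- sqrt(sum((m$coords[a, ] - m$coords[b, ])^2))
      e_oracle <- e_oracle + g[idx[1], idx[2]] * len
    }
  }
  expect_equal(tissue_energy(m, cells, vp), e_oracle, tolerance = 1e-12)
})

test_that("nodal forces are the exact negative energy gradient", {
  set.seed(32)
  for (rep in 1:3) {
    m <- build_honeycomb_mesh(2, 2, 1)
    m$coords <- m$coords + matrix(runif(length(m$coords), -0.08, 0.08), ncol = 2)
    cells <- new_cell_table(4, types = sample(0:1, 4, replace = TRUE),
                            target_area = runif(1, 1.5, 3))
    vp <- vertex_params(k_area = runif(1, 5, 60), k_perimeter = runif(1, 0, 1),
                        gamma = runif(1, 0, 0.5), n_types = 2)
    f <- nodal_forces(m, cells, vp)
    g <- numeric_mesh_gradient(m, cells, vp)
    scale <- max(abs(f), 1)
    expect_lt(max(abs(f + g)) / scale, 1e-5)
    # translation invariance: forces sum to zero
    expect_lt(max(abs(colSums(f))), 1e-10)
  }
  # stationarity: a relaxed hexagon with only the area term has zero force
  m <- build_honeycomb_mesh(1, 1, 1)
  cells <- new_cell_table(1, target_area = element_areas(m))
  f0 <- nodal_forces(m, cells, vertex_params(k_perimeter = 0, gamma = 0))
  expect_lt(max(abs(f0)), 1e-9)
})

test_that("T1 swap exchanges exactly the predicted adjacencies and conserves counts", {
  fx <- shrunk_edge_fixture(shrink = 0.5, d_t1 = 0.1)
  m <- fx$mesh
  vp <- vertex_params(d_t1 = 0.1, t1_separation_ratio = 1.5)
  before <- element_adjacency(m)
  gaining <- setdiff(1:4, fx$sharing)
  res <- t1_swap(m, fx$edge, vp)
  expect_true(res$swapped)
  after <- element_adjacency(res$mesh)
  lost <- setdiff(before, after)
  won <- setdiff(after, before)
  expect_equal(lost, paste(fx$sharing[1], fx$sharing[2]))
  expect_equal(won, paste(gaining[1], gaining[2]))
  expect_equal(nrow(res$mesh$coords), nrow(m$coords))
  expect_equal(length(res$mesh$elements), length(m$elements))
  expect_silent(validate_mesh(res$mesh))
  # new edge length equals the separation ratio times the threshold
  d <- sqrt(sum((res$mesh$coords[fx$edge[1], ] - res$mesh$coords[fx$edge[2], ])^2))
  expect_equal(d, 1.5 * 0.1, tolerance = 1e-12)
})

test_that("T1 threshold is strict: an edge exactly at d_t1 does not swap", {
  fx <- shrunk_edge_fixture(shrink = 1, d_t1 = 0.1)  # edge length == d_t1
  vp <- vertex_params(d_t1 = 0.1)
  cells <- new_cell_table(4, target_area = mean(element_areas(fx$mesh)))
  vp$k_area <- 1e-9; vp$noise <- 0  # frozen mechanics: only T1 logic acts
  res <- vm_step(fx$mesh, cells, vp)
  expect_equal(res$n_t1, 0L)
})

test_that("T2 removes one element and two nodes, keeps the tiling area", {
  m <- t2_tiling_fixture(eps = 0.05)
  cells <- new_cell_table(4, target_area = 1)
  vp <- vertex_params(a_t2 = 0.1)
  tri_area <- element_areas(m)[1]
  expect_lt(tri_area, 0.1)
  total_before <- sum(element_areas(m))
  res <- t2_remove(m, 1, cells, vp)
  expect_true(res$removed)
  expect_equal(length(res$mesh$elements), length(m$elements) - 1L)
  expect_equal(nrow(res$mesh$coords), nrow(m$coords) - 2L)
  expect_equal(res$removed_cell_id, 1L)
  expect_false(res$removed_cell_id %in% res$cells$id)
  expect_silent(validate_mesh(res$mesh))
  expect_lt(abs(sum(element_areas(res$mesh)) - total_before), tri_area)

  # non-triangular small element: no action
  sq <- vertex_mesh(rbind(c(0, 0), c(0.1, 0), c(0.1, 0.1), c(0, 0.1)), list(1:4))
  res2 <- t2_remove(sq, 1, new_cell_table(1), vp)
  expect_false(res2$removed)
})

test_that("element division partitions area and shares new nodes with neighbours", {
  # regular hexagon, axis through two opposite vertices: equal daughters
  m <- build_honeycomb_mesh(1, 1, 1)
  cells <- new_cell_table(1, model = "fixed")
  axis <- m$coords[m$elements[[1]][4], ] - m$coords[m$elements[[1]][1], ]
  res <- divide_element(m, 1, cells, axis = axis, t = 0, ready = TRUE)
  expect_true(res$divided)
  a <- element_areas(res$mesh)
  expect_equal(length(a), 2L)
  expect_equal(a[1], a[2], tolerance = 1e-9)
  expect_equal(sum(a), 3 * sqrt(3) / 2, tolerance = 1e-9)
  expect_true(all(lengths(res$mesh$elements) >= 3L))

  # short-axis division inside a honeycomb: neighbours stay consistent
  set.seed(33)
  m <- build_honeycomb_mesh(3, 3, 1)
  cells <- new_cell_table(9, model = "fixed")
  total <- sum(element_areas(m))
  res <- divide_element(m, 5, cells, t = 0, ready = TRUE)
  expect_true(res$divided)
  expect_equal(length(res$mesh$elements), 10L)
  expect_silent(validate_mesh(res$mesh))
  expect_equal(sum(element_areas(res$mesh)), total, tolerance = 1e-9)
  expect_equal(nrow(res$cells), 10L)
})

test_that("heterotypic fraction: closed cases and explicit edge-walk oracle", {
  m <- build_honeycomb_mesh(4, 4, 1)
  mono <- new_cell_table(16, types = 0L, target_area = 1)
  expect_equal(heterotypic_fraction(m, mono), 0)

  single <- build_honeycomb_mesh(1, 1, 1)
  expect_error(heterotypic_fraction(single, new_cell_table(1)),
               class = "tissuesim_undefined_metric")

  # alternating-type columns: oracle walks shared element pairs directly
  types <- rep_len(rep(0:1, 4)[1:4], 16)  # by column within each row
  cells <- new_cell_table(16, types = types, target_area = 1)
  het_len <- 0; tot_len <- 0
  for (i in 1:15) for (j in (i + 1):16) {
    shared <- intersect(m$elements[[i]], m$elements[[j]])
    if (length(shared) == 2L) {
      len <- sqrt(sum((m$coords[shared[1], ] - m$coords[shared[2], ])^2))
      tot_len <- tot_len + len
      if (cells$type[i] != cells$type[j]) het_len <- het_len + len
    }
  }
  expect_equal(heterotypic_fraction(m, cells), het_len / tot_len,
               tolerance = 1e-12)
})

test_that("quasi-static relaxation has non-increasing energy and valid topology", {
  set.seed(34)
  m <- build_honeycomb_mesh(3, 3, 1)
  m$coords <- m$coords + matrix(runif(length(m$coords), -0.1, 0.1), ncol = 2)
  cells <- new_cell_table(9, target_area = mean(element_areas(m)))
  vp <- vertex_params(k_area = 50, k_perimeter = 1, gamma = 0.1, dt = 0.002,
                      d_t1 = 0, a_t2 = 0)
  e_prev <- tissue_energy(m, cells, vp)
  for (i in 1:200) {
    r <- vm_step(m, cells, vp)
    m <- r$mesh; cells <- r$cells
    e <- tissue_energy(m, cells, vp)
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
  expect_silent(validate_mesh(m))
})
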