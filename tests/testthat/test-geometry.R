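test_that("signed area: orientation, known shapes, triangulation additivity", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(signed_area(sq), 1)
  expect_equal(signed_area(sq[4:1, ]), -1)
  expect_error(signed_area(sq[1:2, ]), class = "tissuesim_geometry_error")

  set.seed(11)
  for (rep in 1:5) {
    poly <- random_convex_polygon(7)
    fan <- sum(vapply(2:6, function(k) {
      signed_area(rbind(poly[1, ], poly[k, ], poly[k + 1, ]))
    }, numeric(1)))
    expect_equal(signed_area(poly), fan, tolerance = 1e-12)
  }
})

test_that("perimeter matches direct edge-length summation", {
  expect_equal(ring_perimeter(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 4)
  hexa <- t(sapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3))))
  expect_equal(ring_perimeter(hexa), 6, tolerance = 1e-12)
  set.seed(12)
  poly <- random_convex_polygon(10, r = 2)
  direct <- sum(sapply(1:10, function(i) {
    j <- if (i == 10) 1 else i + 1
    sqrt(sum((poly[j, ] - poly[i, ])^2))
  }))
  expect_equal(ring_perimeter(poly), direct, tolerance = 1e-12)
})

test_that("centroid: known shapes and Monte-Carlo oracle", {
  expect_equal(ring_centroid(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
               c(0.5, 0.5))
  expect_equal(ring_centroid(rbind(c(0, 0), c(1, 0), c(0, 1))),
               c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(ring_centroid(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "tissuesim_geometry_error")

  set.seed(13)
  poly <- random_convex_polygon(8, r = 1.5)
  samp <- cbind(runif(20000, -1.5, 1.5), runif(20000, -1.5, 1.5))
  keep <- apply(samp, 1, point_in_polygon, ring = poly)
  mc <- colMeans(samp[keep, ])
  expect_equal(ring_centroid(poly), mc, tolerance = 0.03)
})

test_that("Delaunay pairs equal the empty-circumcircle oracle", {
  p3 <- rbind(c(0, 0), c(1, 0), c(0.3, 1))
  expect_equal(nrow(delaunay_pairs(p3)), 3L)
  expect_error(delaunay_pairs(p3[1:2, ]), class = "tissuesim_tessellation_error")
  expect_error(delaunay_pairs(cbind(1:5, 2 * (1:5))),
               class = "tissuesim_tessellation_error")

  set.seed(14)
  for (rep in 1:6) {
    pts <- matrix(runif(16), ncol = 2)
    expect_equal(delaunay_pairs(pts), brute_delaunay_pairs(pts))
  }
})

test_that("interior points of a triangular lattice have 6 Delaunay neighbours", {
  g <- expand.grid(i = 0:4, j = 0:4)
  pts <- cbind(g$i + 0.5 * (g$j %% 2), g$j * sqrt(3) / 2)
  # jitter breaks the exact cocircularity of the regular lattice
  set.seed(15)
  pts <- pts + matrix(runif(length(pts), -1e-4, 1e-4), ncol = 2)
  pairs <- delaunay_pairs(pts)
  interior <- which(g$i %in% 1:3 & g$j %in% 1:3 & (g$j %% 2 == 0))
  for (v in interior) {
    expect_equal(sum(pairs == v), 6L)
  }
})

test_that("Voronoi regions partition the box and contain their generators", {
  box <- bounding_box(0, 1, 0, 1)
  one <- voronoi_regions(matrix(c(0.3, 0.7), ncol = 2), box)
  expect_equal(abs(signed_area(one[[1]])), 1)

  two <- voronoi_regions(rbind(c(0.25, 0.5), c(0.75, 0.5)), box)
  expect_equal(sort(sapply(two, function(r) abs(signed_area(r)))), c(0.5, 0.5))

  set.seed(16)
  pts <- matrix(runif(20), ncol = 2)
  regions <- voronoi_regions(pts, box)
  areas <- sapply(regions, function(r) abs(signed_area(r)))
  expect_equal(sum(areas), 1, tolerance = 1e-9)
  for (i in seq_len(nrow(pts))) {
    expect_true(point_in_polygon(pts[i, ], regions[[i]]))
  }
})

test_that("honeycomb meshes validate and have congruent hexagons", {
  m1 <- build_honeycomb_mesh(1, 1, 1)
  expect_equal(length(m1$elements), 1L)
  expect_equal(nrow(m1$coords), 6L)
  expect_equal(element_areas(m1), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_error(build_honeycomb_mesh(0, 2), class = "tissuesim_config_error")
  expect_error(build_honeycomb_mesh(2, 2, -1), class = "tissuesim_config_error")

  for (dims in list(c(2, 2), c(3, 1), c(1, 4), c(4, 3), c(10, 10))) {
    e <- 0.8
    m <- build_honeycomb_mesh(dims[1], dims[2], e)
    expect_silent(validate_mesh(m))
    expect_equal(length(m$elements), dims[1] * dims[2])
    expect_true(all(abs(element_areas(m) - 3 * sqrt(3) / 2 * e^2) < 1e-12))
  }

  # node count equals a brute-force coordinate-dedup construction
  m <- build_honeycomb_mesh(2, 2, 1)
  raw <- NULL
  ang <- pi / 6 + (0:5) * pi / 3
  for (row in 0:1) for (col in 0:1) {
    cx <- sqrt(3) * (col + 0.5 * (row %% 2)); cy <- 1.5 * row
    raw <- rbind(raw, cbind(cx + cos(ang), cy + sin(ang)))
  }
  n_dedup <- sum(!duplicated(round(raw, 6)))
  expect_equal(nrow(m$coords), n_dedup)
})

test_that("lattice blob generators honour mode and connectivity", {
  expect_error(build_lattice_blob(10, 10, 8, 3), class = "tissuesim_config_error")

  set.seed(17)
  # CA: radius covering exactly n sites -> every disc site occupied
  lat <- build_lattice_blob(11, 11, 2, 13, mode = "CA")
  expect_equal(sum(lat$occupancy != 0L), 13L)
  expect_true(all(table(lat$occupancy[lat$occupancy != 0L]) == 1L))

  # CP, one cell: a single connected domain of all disc sites
  lat1 <- build_lattice_blob(15, 15, 5, 1, mode = "CP")
  expect_equal(length(unique(lat1$occupancy[lat1$occupancy != 0L])), 1L)

  # CP: every domain 4-connected (BFS check)
  lat <- build_lattice_blob(21, 21, 8, 6, mode = "CP")
  occ <- lat$occupancy
  for (id in 1:6) {
    sites <- which(occ == id, arr.ind = TRUE)
    expect_gt(nrow(sites), 0)
    seen <- rep(FALSE, nrow(sites))
    key <- paste(sites[, 1], sites[, 2])
    queue <- 1L; seen[1] <- TRUE
    while (length(queue) > 0L) {
      cur <- sites[queue[1], ]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        hit <- match(paste(cur[1] + d[1], cur[2] + d[2]), key)
        if (!is.na(hit) && !seen[hit]) { seen[hit] <- TRUE; queue <- c(queue, hit) }
      }
    }
    expect_true(all(seen), label = sprintf("cell %d 4-connected", id))
  }
})

test_that("mesh validation flags broken meshes", {
  m <- build_honeycomb_mesh(2, 2, 1)
  bad <- m; bad$elements[[1]] <- bad$elements[[1]][1:2]
  expect_error(validate_mesh(bad), class = "tissuesim_mesh_error")
  bad <- m; bad$elements[[2]] <- c(bad$elements[[2]], bad$elements[[2]][1])
  expect_error(validate_mesh(bad), class = "tissuesim_mesh_error")
  bad <- m; bad$coords[1, ] <- bad$coords[2, ] + 1e-12
  expect_error(validate_mesh(bad), class = "tissuesim_mesh_error")
  # clockwise input rings are repaired by the constructor
  cw <- vertex_mesh(rbind(c(0, 0), c(1, 0), c(1, 1)), list(c(3, 2, 1)))
  expect_gt(signed_area(cw$coords[cw$elements[[1]], ]), 0)
})
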