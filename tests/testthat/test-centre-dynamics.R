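test_that("neighbour pairs: cutoff filter matches the all-pairs oracle, VT delegates", {
  pop <- centre_population(rbind(c(0, 0), c(3, 0)), cutoff = 1.5)
  expect_equal(nrow(neighbour_pairs(pop)), 0L)

  set.seed(51)
  coords <- matrix(runif(40, 0, 4), ncol = 2)
  pop <- centre_population(coords, cutoff = 1.2)
  got <- neighbour_pairs(pop)
  oracle <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < 1.2) {
      oracle <- rbind(oracle, c(i, j))
    }
  }
  expect_equal(got, matrix(as.integer(oracle), ncol = 2))

  popv <- centre_population(coords, mode = "voronoi")
  expect_equal(neighbour_pairs(popv), delaunay_pairs(coords))
  collinear <- centre_population(cbind(1:5, 1:5), mode = "voronoi")
  expect_error(neighbour_pairs(collinear), class = "tissuesim_tessellation_error")
})

test_that("spring forces follow Hooke's law and the pair-potential gradient", {
  cp <- centre_params(stiffness = 3, rest_length = 1)
  pop <- centre_population(rbind(c(0, 0), c(1, 0)), cutoff = 1.5)
  f <- spring_forces(pop, neighbour_pairs(pop), cp)
  expect_equal(max(abs(f)), 0)

  delta <- 0.2
  pop <- centre_population(rbind(c(0, 0), c(1 + delta, 0)), cutoff = 2)
  f <- spring_forces(pop, neighbour_pairs(pop), cp)
  expect_equal(f[1, ], c(3 * delta, 0), tolerance = 1e-12)   # attractive
  expect_equal(f[2, ], -f[1, ], tolerance = 1e-12)

  set.seed(52)
  coords <- matrix(runif(30, 0, 3), ncol = 2)
  pop <- centre_population(coords, cutoff = 1.5)
  pairs <- neighbour_pairs(pop)
  f <- spring_forces(pop, pairs, cp)
  g <- numeric_centre_gradient(pop, pairs, cp)
  expect_lt(max(abs(f + g)) / max(abs(f), 1), 1e-5)
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("overdamped Euler: exact linear displacement, analytic two-cell decay", {
  cp <- centre_params(stiffness = 3, rest_length = 1, dt = 0.1, drag = 2)
  pop <- centre_population(matrix(c(0, 0), ncol = 2), cutoff = 1)
  for (i in 1:7) pop <- step_positions(pop, matrix(c(1, -0.5), ncol = 2), cp)
  expect_equal(pop$coords[1, ], 7 * 0.1 / 2 * c(1, -0.5), tolerance = 1e-12)

  expect_error(step_positions(pop, matrix(c(NaN, 0), ncol = 2), cp),
               class = "tissuesim_integration_error")

  # separation relaxes as s + delta0 exp(-2 mu t / eta)
  cp <- centre_params(stiffness = 3, rest_length = 1, dt = 0.001, drag = 1)
  pop <- centre_population(rbind(c(0, 0), c(1.3, 0)), cutoff = 2)
  for (i in 1:1000) {
    pop <- step_positions(pop, spring_forces(pop, neighbour_pairs(pop), cp), cp)
  }
  predicted <- 1 + 0.3 * exp(-2 * 3 * 1)
  expect_lt(abs(abs(diff(pop$coords[, 1])) - predicted) / predicted, 0.01)
})

test_that("centre division places symmetric daughters in uniform directions", {
  set.seed(53)
  cp <- centre_params(newborn_separation = 0.3)
  cyc <- cycle_params()
  angles <- numeric(500)
  for (i in 1:500) {
    pop <- centre_population(matrix(c(2, 3), ncol = 2), cutoff = 1.5)
    cells <- new_cell_table(1, model = "uniform", params = cyc)
    res <- divide_centre_cell(pop, 1L, cells, cp, t = 1, cycle = cyc)
    expect_equal(nrow(res$pop$coords), 2L)
    expect_equal(colMeans(res$pop$coords), c(2, 3), tolerance = 1e-12)
    d <- res$pop$coords[1, ] - res$pop$coords[2, ]
    expect_equal(sqrt(sum(d^2)), 0.3, tolerance = 1e-12)
    angles[i] <- atan2(d[2], d[1])
  }
  # Rayleigh test: do not reject circular uniformity at alpha = 0.01
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  p <- exp(-length(angles) * rbar^2)
  expect_gt(p, 0.01)
})

test_that("sibling rest-length ramp shortens springs then expires", {
  cp <- centre_params(stiffness = 1, rest_length = 1, growth_duration = 2,
                      newborn_separation = 0.4)
  sib <- data.frame(id1 = 1L, id2 = 2L, t0 = 0)
  pop <- centre_population(rbind(c(0, 0), c(1, 0)), cutoff = 2)
  # at birth: rest length 0.4 -> pair at separation 1 is stretched
  f0 <- spring_forces(pop, neighbour_pairs(pop), cp, t = 0, siblings = sib)
  expect_equal(f0[1, 1], 1 * (1 - 0.4), tolerance = 1e-12)
  # halfway: rest length 0.7
  f1 <- spring_forces(pop, neighbour_pairs(pop), cp, t = 1, siblings = sib)
  expect_equal(f1[1, 1], 1 * (1 - 0.7), tolerance = 1e-12)
  # expired: ordinary rest length 1, zero force
  f2 <- spring_forces(pop, neighbour_pairs(pop), cp, t = 5, siblings = sib)
  expect_equal(max(abs(f2)), 0)
})
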