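# Planar geometric kernel: polygon measures, Delaunay/Voronoi tessellation,
# and generators for vertex meshes and lattices. Coordinates are dimensionless
# with one cell diameter as the length unit.

ts_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "tissuesim_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2L) {
    ts_stop("a ring must be an n x 2 numeric matrix", "tissuesim_geometry_error")
  }
  if (nrow(ring) < 3L) {
    ts_stop("a polygon ring needs at least 3 points", "tissuesim_geometry_error")
  }
  if (!all(is.finite(ring))) {
    ts_stop("ring coordinates must be finite", "tissuesim_geometry_error")
  }
  ring
}

#' Signed area of a polygon ring
#'
#' Shoelace formula. Positive for counter-clockwise rings, negative for
#' clockwise ones.
#'
#' @param ring An n x 2 numeric matrix of vertex coordinates (n >= 3), listed
#'   in order around the polygon; the ring is closed implicitly.
#' @return Signed area (length units squared).
#' @examples
#' signed_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # +1
#' @export
signed_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  i2 <- c(seq_len(nrow(ring))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Perimeter of a polygon ring
#'
#' @inheritParams signed_area
#' @return Total edge length, closing the ring.
#' @export
ring_perimeter <- function(ring) {
  ring <- as_ring(ring)
  d <- ring[c(seq_len(nrow(ring))[-1], 1L), , drop = FALSE] - ring
  sum(sqrt(rowSums(d^2)))
}

#' Area-weighted centroid of a polygon ring
#'
#' @inheritParams signed_area
#' @return Length-2 numeric vector (x, y).
#' @export
ring_centroid <- function(ring) {
  ring <- as_ring(ring)
  a <- signed_area(ring)
  if (abs(a) < 1e-14) {
    ts_stop("centroid of a degenerate (zero-area) ring", "tissuesim_geometry_error")
  }
  x <- ring[, 1]; y <- ring[, 2]
  i2 <- c(seq_len(nrow(ring))[-1], 1L)
  cross <- x * y[i2] - x[i2] * y
  c(sum((x + x[i2]) * cross), sum((y + y[i2]) * cross)) / (6 * a)
}

# Second area moments about the centroid; returns the 2x2 covariance-like
# matrix S = [[Ixx, Ixy], [Ixy, Iyy]] with Ixx = int x^2 dA etc. Used for the
# short-axis division rule.
ring_second_moments <- function(ring) {
  ring <- as_ring(ring)
  a <- signed_area(ring)
  cen <- ring_centroid(ring)
  x <- ring[, 1] - cen[1]; y <- ring[, 2] - cen[2]
  i2 <- c(seq_len(nrow(ring))[-1], 1L)
  cross <- x * y[i2] - x[i2] * y
  ixx <- sum((x^2 + x * x[i2] + x[i2]^2) * cross) / 12
  iyy <- sum((y^2 + y * y[i2] + y[i2]^2) * cross) / 12
  ixy <- sum((x * y[i2] + 2 * x * y + 2 * x[i2] * y[i2] + x[i2] * y) * cross) / 24
  m <- matrix(c(ixx, ixy, ixy, iyy), 2, 2)
  if (a < 0) -m else m
}

#' Axis-aligned bounding box
#'
#' @param xmin,xmax,ymin,ymax Box coordinates with `xmin < xmax`, `ymin < ymax`.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(xmin, xmax, ymin, ymax) {
  if (!(is.finite(xmin) && is.finite(xmax) && is.finite(ymin) && is.finite(ymax)) ||
      xmin >= xmax || ymin >= ymax) {
    ts_stop("bounding box requires xmin < xmax and ymin < ymax",
            "tissuesim_geometry_error")
  }
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "bounding_box")
}

box_ring <- function(box) {
  rbind(c(box$xmin, box$ymin), c(box$xmax, box$ymin),
        c(box$xmax, box$ymax), c(box$xmin, box$ymax))
}

# ---- Delaunay triangulation (Bowyer-Watson point insertion) ----------------

# TRUE when p lies strictly inside the circumcircle of triangle (a, b, c).
# Determinant incircle predicate, sign-corrected for triangle orientation.
in_circumcircle <- function(a, b, c, p) {
  m <- rbind(
    c(a[1] - p[1], a[2] - p[2], (a[1] - p[1])^2 + (a[2] - p[2])^2),
    c(b[1] - p[1], b[2] - p[2], (b[1] - p[1])^2 + (b[2] - p[2])^2),
    c(c[1] - p[1], c[2] - p[2], (c[1] - p[1])^2 + (c[2] - p[2])^2)
  )
  orient <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  det(m) * sign(orient) > 0
}

delaunay_triangulate <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) ts_stop("Delaunay needs at least 3 points", "tissuesim_tessellation_error")
  if (!all(is.finite(points))) {
    ts_stop("non-finite point coordinates", "tissuesim_tessellation_error")
  }
  # collinearity check: all cross products (p2-p1) x (pk-p1) ~ 0
  v <- sweep(points, 2, points[1, ])
  cr <- v[, 1] * v[2, 2] - v[, 2] * v[2, 1]
  scale0 <- max(abs(v)) + 1
  if (all(abs(cr) < 1e-12 * scale0^2)) {
    ts_stop("all points are collinear", "tissuesim_tessellation_error")
  }

  # super-triangle comfortably containing every point
  cen <- colMeans(points)
  r <- max(sqrt(rowSums(sweep(points, 2, cen)^2))) + 1
  big <- 64 * r
  sup <- rbind(cen + big * c(0, 1), cen + big * c(-0.866, -0.5),
               cen + big * c(0.866, -0.5))
  pts <- rbind(points, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), ncol = 3)

  for (ip in seq_len(n)) {
    p <- pts[ip, ]
    bad <- logical(nrow(tris))
    for (ti in seq_len(nrow(tris))) {
      tr <- tris[ti, ]
      bad[ti] <- in_circumcircle(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ], p)
    }
    cavity <- tris[bad, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    # boundary of the cavity: edges that appear exactly once
    edges <- rbind(cavity[, c(1, 2), drop = FALSE],
                   cavity[, c(2, 3), drop = FALSE],
                   cavity[, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    for (ei in which(once)) {
      tris <- rbind(tris, c(edges[ei, 1], edges[ei, 2], ip))
    }
  }
  keep <- tris[, 1] <= n & tris[, 2] <= n & tris[, 3] <= n
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0L) {
    ts_stop("degenerate point set: no Delaunay triangle survives",
            "tissuesim_tessellation_error")
  }
  tris
}

#' Delaunay neighbour pairs
#'
#' Unordered index pairs of points that share a Delaunay edge. For points in
#' general position this equals the empty-circumcircle neighbour graph; it
#' defines cell neighbours in the Voronoi-tessellation cell-centre framework.
#'
#' @param points An n x 2 numeric matrix, n >= 3, not all collinear.
#' @return A two-column integer matrix of pairs with `[ ,1] < [ ,2]`, one row
#'   per undirected Delaunay edge, sorted.
#' @export
delaunay_pairs <- function(points) {
  tris <- delaunay_triangulate(points)
  e <- rbind(tris[, 1:2, drop = FALSE], tris[, 2:3, drop = FALSE],
             tris[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  e
}

# Sutherland-Hodgman clip of a convex ring by the half-plane
# {x : (x - m) . d >= 0}.
clip_halfplane <- function(ring, m, d) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  side <- as.numeric((ring[, 1] - m[1]) * d[1] + (ring[, 2] - m[2]) * d[2])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- side[i]; cj <- side[j]
    if (ci >= 0) out <- rbind(out, ring[i, ])
    if ((ci > 0 && cj < 0) || (ci < 0 && cj > 0)) {
      t <- ci / (ci - cj)
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  out
}

#' Voronoi regions clipped to a bounding box
#'
#' Each generator's region is its nearest-point cell intersected with the box,
#' obtained by half-plane clipping against every perpendicular bisector.
#' Unbounded regions are always clipped, never dropped; the regions partition
#' the box.
#'
#' @param points An n x 2 matrix of generators (n >= 1), all inside `box`.
#' @param box A [bounding_box()].
#' @return A list of counter-clockwise polygon rings, one per generator.
#' @export
voronoi_regions <- function(points, box) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) {
    ts_stop("voronoi_regions needs at least one generator", "tissuesim_tessellation_error")
  }
  if (!all(is.finite(points))) {
    ts_stop("non-finite generator coordinates", "tissuesim_tessellation_error")
  }
  inside <- points[, 1] >= box$xmin & points[, 1] <= box$xmax &
    points[, 2] >= box$ymin & points[, 2] <= box$ymax
  if (!all(inside)) {
    ts_stop("all generators must lie inside the bounding box",
            "tissuesim_tessellation_error")
  }
  n <- nrow(points)
  lapply(seq_len(n), function(i) {
    ring <- box_ring(box)
    for (j in seq_len(n)) {
      if (j == i) next
      m <- (points[i, ] + points[j, ]) / 2
      d <- points[i, ] - points[j, ]
      ring <- clip_halfplane(ring, m, d)
      if (nrow(ring) < 3L) break
    }
    ring
  })
}
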