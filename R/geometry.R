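# Planar geometry helpers: alpha shapes over cell centroids, polygon areas,
# point-in-polygon tests and union areas. Coordinates are µm throughout.

#' Concave hull (alpha shape) of a point set
#'
#' Computes the alpha shape of a set of cell centroids: the union of all
#' Delaunay triangles whose circumradius is at most `alpha`. For convex point
#' sets and large `alpha` this equals the convex hull; smaller `alpha` lets the
#' boundary follow concavities. To guarantee that every input point lies inside
#' or on the boundary, any point left uncovered by the circumradius filter has
#' its smallest-circumradius incident triangle restored.
#'
#' @param x,y numeric coordinates (µm).
#' @param alpha circumradius threshold (µm).
#' @return an object of class `tls_shape`: a list with `area` (µm²),
#'   `triangles` (matrix of vertex indices into the deduplicated points),
#'   `points` (deduplicated coordinate matrix), `rings` (list of boundary ring
#'   coordinate matrices) and `degenerate` (TRUE when fewer than 3 distinct
#'   non-collinear points were supplied, in which case `area` is 0).
#' @examples
#' sq <- alpha_shape(c(0, 100, 100, 0), c(0, 0, 100, 100), alpha = 1e6)
#' sq$area # 10000
#' @export
alpha_shape <- function(x, y, alpha) {
  stopifnot(length(x) == length(y), is.finite(alpha), alpha > 0)
  keep <- !duplicated(cbind(x, y))
  pts <- cbind(x = x[keep], y = y[keep])
  degenerate <- list(
    area = 0, triangles = matrix(integer(), 0, 3), points = pts,
    rings = list(), degenerate = TRUE
  )
  class(degenerate) <- "tls_shape"
  if (nrow(pts) < 3) return(degenerate)

  dt <- cpp_delaunay(pts[, 1], pts[, 2])
  tri <- dt$tri
  if (nrow(tri) == 0) return(degenerate) # all collinear
  r <- sqrt(dt$r2)
  keep_tri <- r <= alpha

  # restore coverage: every point must be a vertex of some kept triangle
  covered <- unique(as.vector(tri[keep_tri, , drop = FALSE]))
  uncovered <- setdiff(seq_len(nrow(pts)), covered)
  while (length(uncovered) > 0) {
    p <- uncovered[1]
    inc <- which(!keep_tri & (tri[, 1] == p | tri[, 2] == p | tri[, 3] == p))
    if (length(inc) == 0) {
      uncovered <- uncovered[-1] # isolated vertex of degenerate mesh
      next
    }
    keep_tri[inc[which.min(r[inc])]] <- TRUE
    covered <- unique(as.vector(tri[keep_tri, , drop = FALSE]))
    uncovered <- setdiff(seq_len(nrow(pts)), covered)
  }

  tri <- tri[keep_tri, , drop = FALSE]
  if (nrow(tri) == 0) return(degenerate)
  a <- tri_areas(pts, tri)
  pos <- a > 0
  tri <- tri[pos, , drop = FALSE]
  if (nrow(tri) == 0) return(degenerate)

  out <- list(
    area = sum(a[pos]),
    triangles = tri,
    points = pts,
    rings = boundary_rings(pts, tri),
    degenerate = FALSE
  )
  class(out) <- "tls_shape"
  out
}

# unsigned triangle areas for index-triple matrix
tri_areas <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

# boundary edges (used by exactly one kept triangle) chained into rings
boundary_rings <- function(pts, tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  bnd <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  # adjacency walk; boundary vertices of a triangulated region have even degree
  adj <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  rings <- list()
  for (start in unique(as.vector(bnd))) {
    repeat {
      nxt <- Filter(function(v) is.null(used[[ekey(start, v)]]),
                    adj[[as.character(start)]])
      if (length(nxt) == 0) break
      ring <- start
      cur <- start
      repeat {
        cand <- Filter(function(v) is.null(used[[ekey(cur, v)]]),
                       adj[[as.character(cur)]])
        if (length(cand) == 0) break
        v <- cand[[1]]
        used[[ekey(cur, v)]] <- TRUE
        ring <- c(ring, v)
        cur <- v
        if (cur == start) break
      }
      if (length(ring) >= 4 && ring[1] == ring[length(ring)]) {
        rings[[length(rings) + 1]] <- pts[ring, , drop = FALSE]
      }
    }
  }
  rings
}

#' Which points fall inside a shape
#'
#' Boundary-inclusive membership test against the triangle cover of a
#' [alpha_shape()] result.
#'
#' @param shape a `tls_shape`.
#' @param px,py query coordinates (µm).
#' @return logical vector.
#' @export
points_in_shape <- function(shape, px, py) {
  if (isTRUE(shape$degenerate) || nrow(shape$triangles) == 0) {
    return(rep(FALSE, length(px)))
  }
  tx <- matrix(shape$points[shape$triangles, 1], ncol = 3)
  ty <- matrix(shape$points[shape$triangles, 2], ncol = 3)
  cpp_points_in_tris(px, py, tx, ty)
}

shape_bbox <- function(shape) {
  if (isTRUE(shape$degenerate) || nrow(shape$points) == 0) {
    return(c(0, 0, -1, -1))
  }
  c(min(shape$points[, 1]), min(shape$points[, 2]),
    max(shape$points[, 1]), max(shape$points[, 2]))
}

#' Area of the union of shapes
#'
#' Overlaps are not double-counted. Shapes whose bounding boxes are disjoint
#' contribute their exact areas; groups of genuinely overlapping shapes are
#' measured by grid sampling at `grid_um` resolution, so union area is always
#' at most the sum of areas, with equality exactly when shapes are pairwise
#' disjoint.
#'
#' @param shapes list of `tls_shape` objects.
#' @param grid_um sampling resolution (µm) for overlapping groups.
#' @return total area in µm².
#' @export
union_area <- function(shapes, grid_um = 5) {
  shapes <- Filter(function(s) !isTRUE(s$degenerate), shapes)
  n <- length(shapes)
  if (n == 0) return(0)
  if (n == 1) return(shapes[[1]]$area)
  bb <- t(vapply(shapes, shape_bbox, numeric(4)))
  overlap <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bb[i, 3] < bb[j, 1] || bb[j, 3] < bb[i, 1] ||
          bb[i, 4] < bb[j, 2] || bb[j, 4] < bb[i, 2]) next
      # bbox overlap: check actual overlap via mutual vertex containment
      ov <- any(points_in_shape(shapes[[j]], shapes[[i]]$points[, 1],
                                shapes[[i]]$points[, 2])) ||
        any(points_in_shape(shapes[[i]], shapes[[j]]$points[, 1],
                            shapes[[j]]$points[, 2]))
      overlap[i, j] <- overlap[j, i] <- ov
    }
  }
  g <- igraph::graph_from_adjacency_matrix(overlap, mode = "undirected")
  comp <- igraph::components(g)$membership
  total <- 0
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1) {
      total <- total + shapes[[members]]$area
      next
    }
    # grid-sample the union over the group's bounding box
    gb <- c(min(bb[members, 1]), min(bb[members, 2]),
            max(bb[members, 3]), max(bb[members, 4]))
    gx <- seq(gb[1] + grid_um / 2, gb[3], by = grid_um)
    gy <- seq(gb[2] + grid_um / 2, gb[4], by = grid_um)
    pts <- expand.grid(x = gx, y = gy)
    inside <- rep(FALSE, nrow(pts))
    for (m in members) {
      inside <- inside | points_in_shape(shapes[[m]], pts$x, pts$y)
    }
    total <- total + sum(inside) * grid_um^2
  }
  total
}

# ---- simple polygons (annotation regions) ------------------------------

# signed ring area (shoelace); positive for counter-clockwise rings
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a polygon with holes
#' @param poly list with `outer` (ring coordinate matrix) and `holes`
#'   (list of ring matrices).
#' @return area in µm² (outer minus holes).
#' @export
polygon_area <- function(poly) {
  abs(ring_area_signed(poly$outer)) -
    sum(vapply(poly$holes, function(h) abs(ring_area_signed(h)), numeric(1)))
}

# even-odd ray casting, boundary-inclusive; ring need not be closed
points_in_ring <- function(px, py, ring) {
  if (nrow(ring) >= 2 &&
      all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  scale <- max(abs(ring), 1)
  tol <- 1e-9 * scale
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    # on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    onb <- onb | (abs(cross) <= tol * (abs(xj - xi) + abs(yj - yi) + 1) & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onb
}

#' Which points fall inside a polygon (holes respected)
#' @param poly polygon as in [polygon_area()].
#' @param px,py query coordinates.
#' @return logical vector.
#' @export
points_in_polygon <- function(poly, px, py) {
  inside <- points_in_ring(px, py, poly$outer)
  for (h in poly$holes) inside <- inside & !points_in_ring(px, py, h)
  inside
}

# does a ring self-intersect? O(m^2) segment pair test; fine for annotations
ring_is_simple <- function(ring) {
  if (nrow(ring) >= 2 &&
      all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  seg <- cbind(ring, ring[c(2:n, 1), , drop = FALSE])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through closure
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# one-shot repair: drop duplicate consecutive vertices, then re-check
repair_ring <- function(ring) {
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  dup <- c(FALSE, rowSums(abs(diff(ring))) == 0)
  ring[!dup, , drop = FALSE]
}
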