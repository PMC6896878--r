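# Planar polygon primitives shared by the geography generator, adjacency and
# dilation code. All coordinates are planar meters; a "geometry" is a list of
# rings, each an n x 2 matrix of vertices (not closed: last != first). The
# first ring is the exterior; any further rings are holes (even-odd rule).

#' Signed area of a vertex ring (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param ring numeric matrix with two columns (x, y), vertices in order,
#'   not closed.
#' @return signed area in square meters.
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' @keywords internal
ring_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

#' Area of a polygon geometry (exterior minus holes)
#' @param geom list of rings; first exterior, rest holes.
#' @return area in square meters.
#' @keywords internal
polygon_area <- function(geom) {
  a <- abs(ring_area(geom[[1L]]))
  if (length(geom) > 1L)
    a <- a - sum(vapply(geom[-1L], function(r) abs(ring_area(r)), numeric(1)))
  a
}

#' @keywords internal
polygon_centroid <- function(geom) ring_centroid(geom[[1L]])

#' Even-odd point-in-polygon test over all rings of a geometry
#' @keywords internal
points_in_polygon <- function(px, py, geom) {
  inside <- rep(FALSE, length(px))
  for (ring in geom)
    inside <- xor(inside, cpp_points_in_ring(px, py, ring[, 1L], ring[, 2L]))
  inside
}

# ring -> segment table (x1, y1, x2, y2), closing the ring
#' @keywords internal
ring_segments <- function(ring) {
  n <- nrow(ring)
  cbind(ring[, 1L], ring[, 2L],
        ring[c(2:n, 1L), 1L], ring[c(2:n, 1L), 2L])
}

# all segments of a list of geometries with a group id per geometry
#' @keywords internal
geoms_segments <- function(geoms) {
  segs <- lapply(seq_along(geoms), function(i) {
    s <- do.call(rbind, lapply(geoms[[i]], ring_segments))
    cbind(s, i)
  })
  do.call(rbind, segs)
}

#' Distance from points to a set of polygon geometries
#'
#' Zero for points inside (or on the boundary of) any geometry, otherwise the
#' Euclidean distance to the nearest boundary segment. Also returns the index
#' of the geometry owning the nearest boundary, which for interior points is
#' the containing geometry.
#'
#' @param px,py point coordinates (meters).
#' @param geoms list of polygon geometries (lists of rings).
#' @return list with numeric `dist` and integer `which` (1-based geometry
#'   index), each of length `length(px)`.
#' @keywords internal
points_to_geoms_dist <- function(px, py, geoms) {
  segs <- geoms_segments(geoms)
  res <- cpp_point_segments_dist(px, py, segs[, 1L], segs[, 2L],
                                 segs[, 3L], segs[, 4L],
                                 as.integer(segs[, 5L]))
  d <- res$dist
  wh <- res$group
  inside_any <- rep(FALSE, length(px))
  for (i in seq_along(geoms)) {
    inside <- points_in_polygon(px, py, geoms[[i]]) & !inside_any
    if (any(inside)) {
      d[inside] <- 0
      wh[inside] <- i
      inside_any <- inside_any | inside
    }
  }
  list(dist = d, which = wh)
}

# clip a convex ring by the half-plane a*x + b*y + c <= 0 (Sutherland-Hodgman)
#' @keywords internal
clip_halfplane <- function(ring, a, b, c) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  f <- a * ring[, 1L] + b * ring[, 2L] + c
  if (all(f <= 0)) return(ring)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- f[i] <= 0; pj_in <- f[j] <= 0
    if (pi_in) out <- rbind(out, ring[i, ])
    if (pi_in != pj_in) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  out
}

#' Voronoi tessellation of seed points clipped to a rectangle
#'
#' Each cell is built by clipping the rectangle with the perpendicular-
#' bisector half-planes against all other seeds, so cells are convex, tile
#' the rectangle exactly, and need no external geometry library.
#'
#' @param seeds k x 2 matrix of seed coordinates inside the rectangle.
#' @param rect numeric `c(xmin, ymin, xmax, ymax)`.
#' @return list of k single-ring geometries in seed order.
#' @keywords internal
voronoi_cells <- function(seeds, rect) {
  k <- nrow(seeds)
  base <- matrix(c(rect[1L], rect[2L],
                   rect[3L], rect[2L],
                   rect[3L], rect[4L],
                   rect[1L], rect[4L]), ncol = 2L, byrow = TRUE)
  lapply(seq_len(k), function(i) {
    cell <- base
    si <- seeds[i, ]
    for (j in seq_len(k)) {
      if (j == i) next
      sj <- seeds[j, ]
      dx <- sj - si
      m <- (si + sj) / 2
      # keep points nearer to si: dx . (p - m) <= 0
      cell <- clip_halfplane(cell, dx[1L], dx[2L],
                             -(dx[1L] * m[1L] + dx[2L] * m[2L]))
      if (nrow(cell) < 3L) break
    }
    list(cell)
  })
}

# simplicity check: no two non-adjacent edges of a ring intersect
#' @keywords internal
ring_is_simple <- function(ring, tol = 0) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  segs <- ring_segments(ring)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in seq.int(i + 2L, jmax)) {
      if (segments_cross(segs[i, ], segs[j, ])) return(FALSE)
    }
  }
  TRUE
}

# proper crossing test for two segments c(x1,y1,x2,y2)
#' @keywords internal
segments_cross <- function(s, t) {
  o <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  o1 <- o(s[1], s[2], s[3], s[4], t[1], t[2])
  o2 <- o(s[1], s[2], s[3], s[4], t[3], t[4])
  o3 <- o(t[1], t[2], t[3], t[4], s[1], s[2])
  o4 <- o(t[1], t[2], t[3], t[4], s[3], s[4])
  (o1 != o2) && (o3 != o4) && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}
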