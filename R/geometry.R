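# Lightweight planar geometry. Geometries are lists of rings; a ring is an
# n x 2 numeric matrix of vertices (closing vertex optional). Multiple rings
# are combined with the even-odd rule, so holes and multipolygons both work
# for containment tests. Exact overlap areas are available for axis-aligned
# rectangles (the synthetic generator's world); general polygons use a
# deterministic dense sampling fallback.

#' Build a rectangular ring
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds; max must exceed min.
#' @return a 4 x 2 vertex matrix usable as a geometry ring.
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin)
    psrb_stop("degenerate rectangle", "geometry_input")
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Coerce a geometry to a list of rings
#' @keywords internal
#' @noRd
as_rings <- function(geom) {
  if (is.matrix(geom)) return(list(geom))
  if (is.list(geom) && all(vapply(geom, is.matrix, logical(1)))) return(geom)
  psrb_stop("geometry must be a ring matrix or list of ring matrices",
            "geometry_input")
}

#' Drop a duplicated closing vertex
#' @keywords internal
#' @noRd
open_ring <- function(ring) {
  n <- nrow(ring)
  if (n > 1L && all(ring[1, ] == ring[n, ])) ring[-n, , drop = FALSE] else ring
}

#' Even-odd point-in-polygon test
#'
#' Vectorised crossing-number test over all rings of a geometry; a point
#' inside an odd number of rings is inside the polygon, so holes are
#' supported naturally.
#'
#' @param px,py point coordinate vectors of equal length.
#' @param geom a ring matrix or list of ring matrices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, geom) {
  rings <- lapply(as_rings(geom), open_ring)
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    if (n < 3L) next
    xs <- ring[, 1]; ys <- ring[, 2]
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[j[k]]; y2 <- ys[j[k]]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Polygon area (shoelace)
#'
#' Sum of absolute shoelace areas over rings. Intended for disjoint outer
#' rings (multipolygons); holes are not subtracted.
#'
#' @param geom ring matrix or list of rings.
#' @return non-negative area in squared map units.
#' @export
polygon_area <- function(geom) {
  sum(vapply(as_rings(geom), function(r) {
    r <- open_ring(r); n <- nrow(r)
    if (n < 3L) return(0)
    j <- c(2:n, 1L)
    abs(sum(r[, 1] * r[j, 2] - r[j, 1] * r[, 2])) / 2
  }, numeric(1)))
}

#' Bounding box of a geometry
#' @param geom ring matrix or list of rings.
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
geom_bbox <- function(geom) {
  pts <- do.call(rbind, as_rings(geom))
  c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
}

#' Is a geometry a single axis-aligned rectangle?
#' @keywords internal
#' @noRd
is_axis_rect <- function(geom) {
  rings <- as_rings(geom)
  if (length(rings) != 1L) return(FALSE)
  r <- open_ring(rings[[1]])
  if (nrow(r) != 4L) return(FALSE)
  length(unique(r[, 1])) == 2L && length(unique(r[, 2])) == 2L &&
    all(table(r[, 1]) == 2L) && all(table(r[, 2]) == 2L)
}

#' Rectangle intersection, or NULL when empty
#' @keywords internal
#' @noRd
rect_clip <- function(a, b) {
  lo <- pmax(a[1:2], b[1:2]); hi <- pmin(a[3:4], b[3:4])
  if (any(hi <= lo)) NULL else c(lo, hi)
}

#' Area of (site intersect union of rectangles) by coordinate compression
#'
#' Exact for axis-aligned rectangles: the plane restricted to the site is
#' partitioned into the grid induced by every rectangle edge, and a
#' partition cell is covered iff its center lies in some rectangle.
#'
#' @param site_bbox `c(xmin, ymin, xmax, ymax)` of the (rectangular) site.
#' @param rects list of `c(xmin, ymin, xmax, ymax)` covering rectangles.
#' @return covered area inside the site.
#' @keywords internal
#' @noRd
rect_union_area_in <- function(site_bbox, rects) {
  clipped <- Filter(Negate(is.null), lapply(rects, rect_clip, b = site_bbox))
  if (!length(clipped)) return(0)
  xs <- sort(unique(unlist(lapply(clipped, function(r) r[c(1, 3)]))))
  ys <- sort(unique(unlist(lapply(clipped, function(r) r[c(2, 4)]))))
  if (length(xs) < 2L || length(ys) < 2L) return(0)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  wx <- diff(xs); wy <- diff(ys)
  covered <- matrix(FALSE, length(cy), length(cx))
  for (r in clipped) {
    ix <- cx > r[1] & cx < r[3]
    iy <- cy > r[2] & cy < r[4]
    covered[iy, ix] <- TRUE
  }
  sum((wy %o% wx)[covered])
}
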