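# Minimal planar polygon geometry for study-area handling.
#
# The analysis needs only a handful of operations on a single simple polygon
# in lon/lat: parsing (WKT / GeoJSON), validity (closed, non-self-
# intersecting), area, point-in-polygon, and the area of intersection with an
# axis-aligned grid cell (Sutherland-Hodgman clipping against a rectangle).
# Coordinates are treated as planar; distances in km go through the
# equirectangular projection in [project_km()].

#' Construct a study polygon
#'
#' @param coords two-column matrix of (lon, lat) vertices. The ring may be
#'   given open or closed; it is stored closed (first vertex repeated last).
#' @return an object of class `study_polygon`.
#' @export
study_polygon <- function(coords) {
  coords <- as.matrix(coords)
  .check(ncol(coords) == 2, "polygon coordinates must have two columns (lon, lat)")
  .check(all(is.finite(coords)), "polygon coordinates must be finite")
  if (all(coords[1, ] == coords[nrow(coords), ])) {
    ring <- coords
  } else {
    ring <- rbind(coords, coords[1, ])
  }
  .check(nrow(ring) >= 4, "a polygon needs at least 3 distinct vertices")
  .check(all(ring[, 1] >= -180 & ring[, 1] <= 180), "longitude outside [-180, 180]")
  .check(all(ring[, 2] >= -90 & ring[, 2] <= 90), "latitude outside [-90, 90]")
  if (.ring_self_intersects(ring)) {
    stop("polygon ring is self-intersecting", call. = FALSE)
  }
  dimnames(ring) <- list(NULL, c("lon", "lat"))
  structure(list(ring = ring), class = "study_polygon")
}

#' @export
print.study_polygon <- function(x, ...) {
  bb <- polygon_bbox(x)
  cat(sprintf(
    "study_polygon: %d vertices, area %.4f deg^2, bbox lon [%.3f, %.3f] lat [%.3f, %.3f]\n",
    nrow(x$ring) - 1L, polygon_area(x), bb[1], bb[2], bb[3], bb[4]
  ))
  invisible(x)
}

#' Shoelace area of a study polygon (square degrees)
#' @param poly a `study_polygon`.
#' @export
polygon_area <- function(poly) {
  r <- poly$ring
  n <- nrow(r) - 1L
  x <- r[seq_len(n), 1]; y <- r[seq_len(n), 2]
  xn <- r[seq_len(n) + 1L, 1]; yn <- r[seq_len(n) + 1L, 2]
  abs(sum(x * yn - xn * y)) / 2
}

#' Bounding box of a study polygon
#' @param poly a `study_polygon`.
#' @return numeric `(xmin, xmax, ymin, ymax)`.
#' @export
polygon_bbox <- function(poly) {
  r <- poly$ring
  c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2]))
}

# TRUE when any two non-adjacent edges properly cross (shared endpoints of
# consecutive edges are allowed, spikes/crossings are not).
.ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent edges (and the closing edge's adjacency with the first)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_cross(
        ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]
      )) {
        return(TRUE)
      }
    }
  }
  FALSE
}

.cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

.segments_cross <- function(p1, p2, q1, q2) {
  d1 <- .cross2(q1, q2, p1)
  d2 <- .cross2(q1, q2, p2)
  d3 <- .cross2(p1, p2, q1)
  d4 <- .cross2(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(p, a, b) {
    min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p1, q1, q2)) || (d2 == 0 && on_seg(p2, q1, q2)) ||
    (d3 == 0 && on_seg(q1, p1, p2)) || (d4 == 0 && on_seg(q2, p1, p2))
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Ray casting with an explicit boundary check, vectorized over points.
#'
#' @param lon,lat numeric vectors of point coordinates.
#' @param poly a `study_polygon`.
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  r <- poly$ring
  n <- nrow(r) - 1L
  vapply(seq_along(lon), function(i) {
    px <- lon[i]; py <- lat[i]
    inside <- FALSE
    for (e in seq_len(n)) {
      x1 <- r[e, 1]; y1 <- r[e, 2]; x2 <- r[e + 1L, 1]; y2 <- r[e + 1L, 2]
      # boundary: collinear and within the segment bbox
      if (.cross2(c(x1, y1), c(x2, y2), c(px, py)) == 0 &&
          px >= min(x1, x2) && px <= max(x1, x2) &&
          py >= min(y1, y2) && py <= max(y1, y2)) {
        return(TRUE)
      }
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# Sutherland-Hodgman clip of the polygon ring against an axis-aligned
# rectangle; returns the clipped ring (possibly with duplicate vertices,
# harmless for area) or NULL when empty.
.clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  pts <- ring[-nrow(ring), , drop = FALSE]
  clip_halfplane <- function(pts, inside, intersect) {
    if (nrow(pts) == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1L) n else i - 1L, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- clip_halfplane(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  pts <- clip_halfplane(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  pts <- clip_halfplane(pts, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  pts <- clip_halfplane(pts, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  if (nrow(pts) < 3L) NULL else pts
}

#' Area of intersection between a polygon and an axis-aligned rectangle
#'
#' @param poly a `study_polygon`.
#' @param xmin,xmax,ymin,ymax rectangle bounds (degrees).
#' @return intersection area in square degrees (0 when disjoint).
#' @export
polygon_rect_area <- function(poly, xmin, xmax, ymin, ymax) {
  pts <- .clip_ring_rect(poly$ring, xmin, xmax, ymin, ymax)
  if (is.null(pts)) return(0)
  n <- nrow(pts)
  xs <- pts[, 1]; ys <- pts[, 2]
  xn <- xs[c(2:n, 1)]; yn <- ys[c(2:n, 1)]
  abs(sum(xs * yn - xn * ys)) / 2
}

# km per degree used throughout; documented constants so tests are exact.
.KM_PER_DEG_LAT <- 110.574
.KM_PER_DEG_LON <- 111.320

#' Project lon/lat to planar km (equirectangular)
#'
#' x = (lon - ref_lon) * 111.320 * cos(ref_lat), y = (lat - ref_lat) * 110.574.
#' Adequate for regional study areas a few degrees across.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param ref reference point `(lon, lat)`; defaults to the centroid of the
#'   inputs.
#' @return data.frame with columns `x`, `y` in km and the reference as
#'   attribute `ref`.
#' @export
project_km <- function(lon, lat, ref = NULL) {
  if (is.null(ref)) ref <- c(mean(lon), mean(lat))
  x <- (lon - ref[1]) * .KM_PER_DEG_LON * cos(ref[2] * pi / 180)
  y <- (lat - ref[2]) * .KM_PER_DEG_LAT
  structure(data.frame(x = x, y = y), ref = ref)
}

#' Convert a cell side length in km to degrees of latitude
#'
#' Divides by 110.574 km per degree and rounds to 2 decimals, the precision
#' at which grid cell sizes are reported (e.g. 91.58 km -> 0.83 deg).
#'
#' @param L length in km (> 0).
#' @return degrees, rounded to 2 decimals.
#' @export
km_to_degrees <- function(L) {
  .check(all(L > 0), "L must be positive")
  round(L / .KM_PER_DEG_LAT, 2)
}
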