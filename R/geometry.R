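# Planar geometry helpers shared across modules. All coordinates are projected
# meters by package contract; nothing here reprojects or handles lon/lat.

#' Arc length of a polyline
#'
#' @param coords Two-column numeric matrix of vertex coordinates (meters).
#' @return Total length in meters.
#' @keywords internal
polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

# Decompose a polyline into straight pieces (x1, y1, x2, y2 rows).
polyline_to_segments <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(matrix(numeric(0), ncol = 4))
  cbind(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2])
}

# Closest point on a polyline to p = c(x, y). Returns offset (arc length from
# the first vertex), the foot coordinates, and the Euclidean distance. Ties
# between pieces resolve to the lowest offset.
project_point_polyline <- function(p, coords) {
  segs <- polyline_to_segments(coords)
  piece_len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  cum0 <- c(0, cumsum(piece_len))[seq_len(nrow(segs))]
  dx <- segs[, 3] - segs[, 1]
  dy <- segs[, 4] - segs[, 2]
  L2 <- dx^2 + dy^2
  t <- ifelse(L2 > 0, ((p[1] - segs[, 1]) * dx + (p[2] - segs[, 2]) * dy) / L2, 0)
  t <- pmin(1, pmax(0, t))
  fx <- segs[, 1] + t * dx
  fy <- segs[, 2] + t * dy
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  best <- which.min(d2)  # which.min takes the first, i.e. lowest offset
  list(offset = cum0[best] + t[best] * piece_len[best],
       x = fx[best], y = fy[best], dist = sqrt(d2[best]))
}

# Point at arc length s along a polyline (s clamped to [0, length]).
point_along_polyline <- function(coords, s) {
  piece <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(piece))
  s <- min(max(s, 0), cum[length(cum)])
  k <- findInterval(s, cum, rightmost.closed = TRUE)
  k <- min(k, length(piece))
  t <- if (piece[k] > 0) (s - cum[k]) / piece[k] else 0
  coords[k, ] + t * (coords[k + 1, ] - coords[k, ])
}

# Sub-polyline between arc lengths from_s and to_s (0 <= from_s < to_s <= len).
substring_polyline <- function(coords, from_s, to_s) {
  piece <- sqrt(rowSums(diff(coords)^2))
  cum <- c(0, cumsum(piece))
  len <- cum[length(cum)]
  from_s <- min(max(from_s, 0), len)
  to_s <- min(max(to_s, 0), len)
  keep <- which(cum > from_s + 1e-12 & cum < to_s - 1e-12)
  pts <- rbind(point_along_polyline(coords, from_s),
               coords[keep, , drop = FALSE],
               point_along_polyline(coords, to_s))
  unname(pts)
}

# Signed area of a ring (closed or open vertex list); positive = CCW.
ring_signed_area <- function(coords) {
  x <- coords[, 1]; y <- coords[, 2]
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a simple polygon
#'
#' Shoelace area of an outer ring minus the area of any interior rings.
#'
#' @param rings A single two-column matrix, or a list of them (first ring
#'   exterior, the rest holes).
#' @return Area in squared input units.
#' @export
polygon_area <- function(rings) {
  if (is.matrix(rings)) return(abs(ring_signed_area(rings)))
  areas <- vapply(rings, function(r) abs(ring_signed_area(r)), numeric(1))
  if (length(areas) == 0) return(0)
  areas[1] - sum(areas[-1])
}

# Vectorized point-in-ring test via mgcv::in.out; pts is an n x 2 matrix.
points_in_ring <- function(pts, ring) {
  if (nrow(pts) == 0) return(logical(0))
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  mgcv::in.out(rbind(ring, ring[1, , drop = FALSE]), pts)
}

# Points inside a polygon-with-holes (list of rings, first exterior).
points_in_polygon <- function(pts, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- points_in_ring(pts, rings[[1]])
  for (h in rings[-1]) inside <- inside & !points_in_ring(pts, h)
  inside
}

# Sample points along the edges of a ring at roughly `spacing` intervals,
# always including the vertices. Used for raster overlap predicates.
sample_ring_boundary <- function(ring, spacing) {
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring2 <- rbind(ring, ring[1, , drop = FALSE])
  out <- vector("list", nrow(ring))
  for (k in seq_len(nrow(ring))) {
    a <- ring2[k, ]; b <- ring2[k + 1, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(1L, ceiling(len / spacing))
    t <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    out[[k]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}
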