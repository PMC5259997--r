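# Vector outlines of buffer masks. Boundary cell edges are linked into closed
# rings that follow the cell boundaries exactly, so the shoelace area of the
# traced multipolygon equals the mask area (cell count x cell area) to
# floating-point precision. Interior is kept on the left, so exterior rings
# come out counter-clockwise and holes clockwise (the GeoJSON convention).

# Directions: 0 = East, 1 = North, 2 = West, 3 = South.
DIR_STEP <- matrix(c(1L, 0L, 0L, 1L, -1L, 0L, 0L, -1L), ncol = 2, byrow = TRUE)

trace_mask_rings <- function(mask, grid) {
  nx <- nrow(mask); ny <- ncol(mask)
  shift <- function(di, dj) {
    out <- matrix(FALSE, nx, ny)
    si <- seq_len(nx) + di; sj <- seq_len(ny) + dj
    oki <- si >= 1 & si <= nx; okj <- sj >= 1 & sj <= ny
    out[oki, okj] <- mask[si[oki], sj[okj]]
    out
  }
  up <- shift(0L, 1L); dn <- shift(0L, -1L)
  lf <- shift(-1L, 0L); rt <- shift(1L, 0L)
  # boundary edges per exposed side; vertices in cell-corner units
  # (corner (a,b) = world (x0 - h/2 + a*h, y0 - h/2 + b*h))
  mk <- function(sel, fa, fb, dir) {
    ij <- which(sel, arr.ind = TRUE)
    if (nrow(ij) == 0) return(NULL)
    cbind(fa(ij[, 1], ij[, 2]), fb(ij[, 1], ij[, 2]), dir)
  }
  ed <- rbind(
    mk(mask & !up, function(i, j) i, function(i, j) j, 2L),          # top, W
    mk(mask & !dn, function(i, j) i - 1L, function(i, j) j - 1L, 0L), # bottom, E
    mk(mask & !lf, function(i, j) i - 1L, function(i, j) j, 3L),      # left, S
    mk(mask & !rt, function(i, j) i, function(i, j) j - 1L, 1L)       # right, N
  )
  if (is.null(ed) || nrow(ed) == 0) return(list())
  from_a <- ed[, 1]; from_b <- ed[, 2]; dir <- ed[, 3]
  to_a <- from_a + DIR_STEP[dir + 1L, 1]
  to_b <- from_b + DIR_STEP[dir + 1L, 2]
  keyf <- function(a, b) a * (ny + 2) + b
  out_key <- keyf(from_a, from_b) * 4 + dir
  # successor of each directed edge: prefer left turn, then straight, then
  # right (left preference splits saddle corners without ring crossings)
  succ <- rep(NA_integer_, nrow(ed))
  base <- keyf(to_a, to_b) * 4
  for (turn in c(1L, 0L, 3L)) {
    cand <- match(base + (dir + turn) %% 4L, out_key)
    succ[is.na(succ) & !is.na(cand)] <- cand[is.na(succ) & !is.na(cand)]
  }
  if (anyNA(succ)) stop("internal error: open boundary chain")
  used <- logical(nrow(ed))
  rings <- list()
  for (e0 in seq_len(nrow(ed))) {
    if (used[e0]) next
    verts_a <- integer(0); verts_b <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      verts_a <- c(verts_a, from_a[e]); verts_b <- c(verts_b, from_b[e])
      e <- succ[e]
      if (e == e0) break
    }
    rings[[length(rings) + 1L]] <-
      cbind(grid$x0 - grid$h / 2 + verts_a * grid$h,
            grid$y0 - grid$h / 2 + verts_b * grid$h)
  }
  rings
}

#' Vector multipolygon outline of a buffer
#'
#' Traces the buffer's cell mask into exact cell-boundary rings and groups
#' holes with their exterior rings. The summed shoelace area of the rings
#' equals `buffer_area(buffer)`.
#'
#' @param buffer A `buffer_polygon`.
#' @return List of polygons; each polygon is a list of ring matrices (first
#'   exterior, counter-clockwise; then holes, clockwise).
#' @export
buffer_multipolygon <- function(buffer) {
  rings <- trace_mask_rings(buffer$mask, buffer$grid)
  if (length(rings) == 0) return(list())
  sa <- vapply(rings, ring_signed_area, numeric(1))
  outers <- which(sa > 0)
  holes <- which(sa < 0)
  polys <- lapply(outers, function(i) list(rings[[i]]))
  if (length(holes) > 0) {
    outer_area <- sa[outers]
    for (hidx in holes) {
      r <- rings[[hidx]]
      # point just inside the hole region: midpoint of the first edge, offset
      # to the right of the walking direction (the non-mask side)
      mid <- (r[1, ] + r[2, ]) / 2
      d <- r[2, ] - r[1, ]
      nrm <- c(d[2], -d[1]) / sqrt(sum(d^2))
      p <- matrix(mid + nrm * buffer$grid$h / 4, ncol = 2)
      host <- NA_integer_
      for (o in order(outer_area)) {
        if (points_in_ring(p, rings[[outers[o]]])) { host <- o; break }
      }
      if (is.na(host)) next  # orphan hole: drop (cannot occur on valid masks)
      polys[[host]] <- c(polys[[host]], list(r))
    }
  }
  polys
}

#' Write buffers to GeoJSON
#'
#' One MultiPolygon feature per buffer with properties `participant_id`,
#' `method`, `trim` and `area_m2`.
#'
#' @param buffers List of `buffer_polygon` objects.
#' @param path Output file.
#' @export
write_buffers_geojson <- function(buffers, path) {
  if (inherits(buffers, "buffer_polygon")) buffers <- list(buffers)
  feats <- lapply(buffers, function(b) {
    polys <- buffer_multipolygon(b)
    coords <- lapply(polys, function(poly)
      lapply(poly, function(r) {
        r <- rbind(r, r[1, , drop = FALSE])
        lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
      }))
    list(type = "Feature",
         properties = list(participant_id = b$participant_id, method = b$method,
                           trim = b$trim, area_m2 = b$area),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  write_geojson(feats, path)
}
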