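# Service-area computation: snap a home location onto the walkable network and
# expand shortest paths outward to a metric cutoff, keeping partial edges. The
# reached sub-network is the common substrate of all three buffer types.

#' Snap a point to the nearest walkable network location
#'
#' Returns the closest point (Euclidean) on any walkable edge polyline. Ties
#' are broken by lowest edge id, then lowest offset.
#'
#' @param point Numeric `c(x, y)` in meters.
#' @param net A `street_network`.
#' @param max_snap_distance Distance above which a warning is recorded
#'   (default 500 m); the snap is still returned.
#' @return A `network_location`: list with `edge_id`, `offset` (meters from
#'   the edge's first node), snapped `x`, `y`, and `snap_distance`.
#' @export
snap_to_network <- function(point, net, max_snap_distance = 500) {
  walk_ids <- net$edges$id[net$edges$walkable]
  if (length(walk_ids) == 0) stop("cannot snap: network has no walkable edges")
  best <- NULL
  for (e in walk_ids) {
    pr <- project_point_polyline(point, net$geoms[[e]])
    if (is.null(best) || pr$dist < best$snap_distance - 1e-12 ||
        (abs(pr$dist - best$snap_distance) <= 1e-12 &&
         (e < best$edge_id || (e == best$edge_id && pr$offset < best$offset)))) {
      best <- list(edge_id = e, offset = pr$offset, x = pr$x, y = pr$y,
                   snap_distance = pr$dist)
    }
  }
  if (best$snap_distance > max_snap_distance)
    warning(sprintf("snap distance %.1f m exceeds %.1f m", best$snap_distance,
                    max_snap_distance))
  structure(best, class = "network_location")
}

# Merge a set of [from, to] intervals into maximal disjoint intervals.
merge_intervals <- function(from, to, tol = 1e-9) {
  o <- order(from)
  from <- from[o]; to <- to[o]
  out_f <- from[1]; out_t <- to[1]
  res <- list()
  for (k in seq_along(from)[-1]) {
    if (from[k] <= out_t + tol) {
      out_t <- max(out_t, to[k])
    } else {
      res[[length(res) + 1L]] <- c(out_f, out_t)
      out_f <- from[k]; out_t <- to[k]
    }
  }
  res[[length(res) + 1L]] <- c(out_f, out_t)
  do.call(rbind, res)
}

#' Sub-network reachable within a network-distance cutoff
#'
#' Single-source shortest-path expansion from a snapped origin (the origin
#' splits its host edge in both directions). Each edge is included up to the
#' offset where the remaining distance budget runs out; an edge reachable from
#' both endpoints contributes the union of its partial reaches, merged into
#' maximal intervals so no length is double counted.
#'
#' @param net A `street_network` (expected already filtered to walkable edges;
#'   non-walkable edges are never traversed).
#' @param origin A `network_location` on a walkable edge of `net`.
#' @param cutoff Network distance in meters (default 1000).
#' @return A `reached_subnetwork`: origin, cutoff, `segments` data.frame
#'   (edge_id, from_offset, to_offset), per-segment geometry, `total_length`.
#' @export
reachable_subnetwork <- function(net, origin, cutoff = 1000) {
  if (!inherits(origin, "network_location")) stop("origin must be a network_location")
  if (cutoff <= 0) stop("cutoff must be positive")
  e0 <- origin$edge_id
  erow <- match(e0, net$edges$id)
  if (is.na(erow)) stop("origin edge not present in network")
  if (!net$edges$walkable[erow]) stop("origin lies on a non-walkable edge")

  walk <- net$edges[net$edges$walkable, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = walk$from, to = walk$to, weight = walk$length),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  u <- net$edges$from[erow]
  v <- net$edges$to[erow]
  len0 <- net$edges$length[erow]
  dmat <- igraph::distances(g, v = as.character(c(u, v)),
                            algorithm = "dijkstra")
  du <- dmat[1, as.character(net$nodes$id)]
  dv <- dmat[2, as.character(net$nodes$id)]
  # distance from the origin to every node: leave the host edge via either end
  d0 <- pmin(origin$offset + du, (len0 - origin$offset) + dv)

  seg_edge <- integer(0); seg_from <- numeric(0); seg_to <- numeric(0)
  for (k in seq_len(nrow(walk))) {
    e <- walk$id[k]
    len <- walk$length[k]
    iv <- NULL
    if (e == e0) {
      # direct reach along the host edge in both directions
      iv <- rbind(iv, c(max(0, origin$offset - cutoff),
                        min(len, origin$offset + cutoff)))
    }
    ba <- cutoff - d0[walk$from[k]]  # budget left at node_a
    bb <- cutoff - d0[walk$to[k]]    # budget left at node_b
    if (ba > 0) iv <- rbind(iv, c(0, min(len, ba)))
    if (bb > 0) iv <- rbind(iv, c(max(0, len - bb), len))
    if (is.null(iv)) next
    iv <- merge_intervals(iv[, 1], iv[, 2])
    keep <- iv[, 2] - iv[, 1] > 1e-9
    iv <- iv[keep, , drop = FALSE]
    if (nrow(iv) == 0) next
    seg_edge <- c(seg_edge, rep(e, nrow(iv)))
    seg_from <- c(seg_from, iv[, 1])
    seg_to <- c(seg_to, iv[, 2])
  }
  geoms <- lapply(seq_along(seg_edge), function(i)
    substring_polyline(net$geoms[[seg_edge[i]]], seg_from[i], seg_to[i]))
  structure(list(origin = origin, cutoff = cutoff,
                 segments = data.frame(edge_id = seg_edge,
                                       from_offset = seg_from,
                                       to_offset = seg_to),
                 geoms = geoms,
                 total_length = sum(seg_to - seg_from)),
            class = "reached_subnetwork")
}

#' @exportS3Method base::print
print.reached_subnetwork <- function(x, ...) {
  cat(sprintf("<reached_subnetwork> cutoff %.0f m, %d segments, %.1f m reached\n",
              x$cutoff, nrow(x$segments), x$total_length))
  invisible(x)
}

# Straight pieces (x1,y1,x2,y2 matrix) of all reached geometry.
reach_segments_matrix <- function(reach) {
  pieces <- lapply(reach$geoms, polyline_to_segments)
  m <- do.call(rbind, pieces)
  if (is.null(m)) matrix(numeric(0), ncol = 4) else m
}

#' Export reached segments as GeoJSON LineStrings
#'
#' Mirrors the dissolved line features of the sausage workflow: one file of
#' LineString features tagged with the participant id.
#'
#' @param reach A `reached_subnetwork`.
#' @param participant_id Id written into each feature's properties.
#' @param path Output file.
#' @export
write_reach_geojson <- function(reach, participant_id, path) {
  feats <- lapply(seq_along(reach$geoms), function(i) {
    g <- reach$geoms[[i]]
    list(type = "Feature",
         properties = list(participant_id = participant_id,
                           edge_id = reach$segments$edge_id[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(r) as.numeric(g[r, ]))))
  })
  write_geojson(feats, path)
}
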