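# Fixtures built in code, plus the independent oracles used against the
# implementation (densified-graph reach, Monte-Carlo buffer area).

# Straight east-west road from (0, 0) to (len, 0), one edge.
make_straight_road <- function(len = 4000) {
  street_network(list(rbind(c(0, 0), c(len, 0))))
}

# Four arms of `arm` meters meeting at a central degree-4 node.
make_plus <- function(arm = 1500, center = c(10000, 10000)) {
  street_network(list(rbind(center, center + c(arm, 0)),
                      rbind(center, center + c(-arm, 0)),
                      rbind(center, center + c(0, arm)),
                      rbind(center, center + c(0, -arm))))
}

# Ladder: two parallel rails nblk blocks long, rungs every `bs` meters, fully
# noded. bs = 150 keeps the detailed-trimmed closing below the block-filling
# threshold, so the three methods are strictly ordered at trim 25.
make_ladder <- function(bs = 150, nblk = 6, orig = c(10000, 20000)) {
  xs <- orig[1] + (0:nblk) * bs
  g <- list()
  for (y in orig[2] + c(0, bs))
    for (k in 1:nblk) g[[length(g) + 1]] <- rbind(c(xs[k], y), c(xs[k + 1], y))
  for (x in xs) g[[length(g) + 1]] <- rbind(c(x, orig[2]), c(x, orig[2] + bs))
  street_network(g)
}

# Random pruned-grid network (walkable only) with a snapped interior origin.
make_random_city_net <- function(seed, blocks = 5, block_size = 100,
                                 prune = 0.15) {
  cfg <- city_config(grid_blocks = c(blocks, blocks), block_size = block_size,
                     edge_prune_prob = prune, limited_access_fraction = 0)
  generate_network(cfg, seed = seed)
}

# Independent reach oracle: densify every edge into <= `step` m straight
# pieces (splitting the origin's host edge exactly at the origin), run
# Dijkstra on the densified graph, and accumulate per-piece reached length
# analytically (within a piece the distance is linear from its nearer end).
densified_reach_oracle <- function(net, origin, cutoff, step = 1) {
  vkey <- character(0); vx <- numeric(0); vy <- numeric(0)
  vid <- function(x, y) {
    k <- sprintf("%.9f_%.9f", x, y)
    i <- match(k, vkey)
    if (is.na(i)) {
      vkey[[length(vkey) + 1L]] <<- k
      vx[[length(vx) + 1L]] <<- x; vy[[length(vy) + 1L]] <<- y
      i <- length(vkey)
    }
    i
  }
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  add_chain <- function(geom, breaks) {
    len <- bufcomp:::polyline_length(geom)
    ss <- sort(unique(pmin(pmax(c(0, len, breaks), 0), len)))
    # subdivide each span into <= step pieces
    allb <- unlist(lapply(seq_len(length(ss) - 1), function(i) {
      n <- max(1, ceiling((ss[i + 1] - ss[i]) / step))
      seq(ss[i], ss[i + 1], length.out = n + 1)
    }))
    allb <- sort(unique(allb))
    pts <- t(vapply(allb, function(s) bufcomp:::point_along_polyline(geom, s), numeric(2)))
    ids <- vapply(seq_len(nrow(pts)), function(i) vid(pts[i, 1], pts[i, 2]),
                  integer(1))
    for (i in seq_len(length(ids) - 1)) {
      ef <<- c(ef, ids[i]); et <<- c(et, ids[i + 1])
      ew <<- c(ew, allb[i + 1] - allb[i])
    }
  }
  for (e in seq_len(nrow(net$edges))) {
    if (!net$edges$walkable[e]) next
    br <- if (net$edges$id[e] == origin$edge_id) origin$offset else numeric(0)
    add_chain(net$geoms[[e]], br)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew), directed = FALSE,
    vertices = data.frame(name = seq_along(vx)))
  o <- vid(origin$x, origin$y)
  d <- igraph::distances(g, v = as.character(o))[1, as.character(seq_along(vx))]
  # within a piece the distance from either end is linear, so the reached
  # subset is [0, A] u [w - B, w] with union length min(A + B, w)
  A <- pmin(ew, pmax(0, cutoff - d[ef]))
  B <- pmin(ew, pmax(0, cutoff - d[et]))
  sum(pmin(A + B, ew))
}

# Monte-Carlo area oracle for a union of capsules (segments buffered by r).
mc_capsule_union_area <- function(segs, r, n = 1e6, seed = 99) {
  set.seed(seed)
  xmin <- min(segs[, c(1, 3)]) - r; xmax <- max(segs[, c(1, 3)]) + r
  ymin <- min(segs[, c(2, 4)]) - r; ymax <- max(segs[, c(2, 4)]) + r
  px <- stats::runif(n, xmin, xmax)
  py <- stats::runif(n, ymin, ymax)
  d <- bufcomp:::min_dist_to_segments(cbind(px, py), segs)
  mean(d <= r) * (xmax - xmin) * (ymax - ymin)
}

# Sample points along every reached segment (for containment checks).
reach_sample_points <- function(reach, spacing = 10) {
  do.call(rbind, lapply(reach$geoms, bufcomp:::sample_ring_boundary,
                        spacing = spacing))
}
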