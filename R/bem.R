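# The eleven built-environment measures (BEMs) computed per participant and
# buffer: net residential density, intersection count/density, transit stop
# count/density, private recreation count/density, park count and total area,
# land-use-mix entropy, and the walkability index (z-score sum). Assignment
# rules follow the any-intersection convention for polygons and optional
# network snapping for point features.

SQ_M_PER_ACRE <- 4046.8564224

#' Polygon features assigned to a buffer
#'
#' A parcel or park is included if any portion of its geometry intersects the
#' buffer (a shared boundary counts); downstream measures then use the
#' feature's full area and full unit count, never clipped values.
#'
#' @param buffer A `buffer_polygon`.
#' @param polygons A `parcel_set` or `park_set`.
#' @return Integer vector of included feature ids.
#' @export
assign_polygons <- function(buffer, polygons) {
  ids <- integer(0)
  for (k in seq_len(nrow(polygons$features))) {
    g <- polygons$geoms[[k]]
    if (!validate_ring(g[[1]])) {
      warning("skipping invalid polygon feature id ", polygons$features$id[k])
      next
    }
    if (polygon_intersects_buffer(buffer, g))
      ids <- c(ids, polygons$features$id[k])
  }
  ids
}

#' Count point features inside a buffer, optionally network-snapped
#'
#' With `snapped = TRUE` each point is first moved to its nearest location on
#' the walkable street network (so destinations just off the roadway are still
#' captured by narrow buffers); with `snapped = FALSE` raw coordinates are
#' used. Points on the buffer boundary count as inside.
#'
#' @param buffer A `buffer_polygon`.
#' @param points A `point_feature_set`.
#' @param net A `street_network` (required when `snapped = TRUE`).
#' @param snapped Snap points to the network first (default TRUE).
#' @return Named integer vector with one count per feature class.
#' @export
count_snapped_points <- function(buffer, points, net = NULL, snapped = TRUE) {
  counts <- stats::setNames(integer(length(POINT_FEATURE_CLASSES)),
                            POINT_FEATURE_CLASSES)
  if (nrow(points) == 0) return(counts)
  xy <- cbind(points$x, points$y)
  if (snapped) {
    if (is.null(net)) stop("snapped point counting requires the street network")
    for (k in seq_len(nrow(points))) {
      loc <- snap_to_network(xy[k, ], net, max_snap_distance = Inf)
      xy[k, ] <- c(loc$x, loc$y)
    }
  }
  inside <- points_in_buffer(buffer, xy)
  tab <- table(factor(points$feature_class[inside], levels = POINT_FEATURE_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Net residential density
#'
#' Residential units per km^2 of residential land: the summed unit count of
#' included residential parcels divided by their summed full-parcel area.
#' Returns 0 with attribute `missing_denominator = TRUE` when no residential
#' parcel is included.
#'
#' @param buffer A `buffer_polygon`.
#' @param parcels A `parcel_set`.
#' @param included Ids from [assign_polygons()]; computed when omitted.
#' @return Units per residential km^2.
#' @export
net_residential_density <- function(buffer, parcels,
                                    included = assign_polygons(buffer, parcels)) {
  f <- parcels$features
  res <- f[f$id %in% included & f$land_use_class == "residential", , drop = FALSE]
  if (nrow(res) == 0 || sum(res$area) <= 0)
    return(structure(0, missing_denominator = TRUE))
  sum(res$residential_units) / (sum(res$area) / 1e6)
}

#' Road intersection count and density within a buffer
#'
#' An intersection is a walkable-network node of degree >= `min_degree`
#' (default 3) whose coordinates fall inside the buffer.
#'
#' @param buffer A `buffer_polygon`.
#' @param net A `street_network`.
#' @param min_degree Minimum walkable degree counting as an intersection.
#' @return List with `count` and `density` (per km^2 of buffer).
#' @export
intersection_metrics <- function(buffer, net, min_degree = 3) {
  deg <- node_degrees(net, walkable_only = TRUE)
  cand <- net$nodes[deg >= min_degree, , drop = FALSE]
  count <- if (nrow(cand) == 0) 0L else
    sum(points_in_buffer(buffer, cbind(cand$x, cand$y)))
  list(count = as.integer(count), density = count / (buffer$area / 1e6))
}

#' Land-use-mix entropy
#'
#' Normalized Shannon entropy of the included full-parcel area shares across
#' the configured land-use categories: with `A_i` the included area of
#' category i and `p_i = A_i / sum(A)`,
#' `LUM = -sum(p_i log p_i) / log(k)` over the k configured categories.
#' 0 when at most one category is present; 1 when all k shares are equal.
#' The "other" class is excluded from the default categories.
#'
#' @param buffer A `buffer_polygon`.
#' @param parcels A `parcel_set`.
#' @param categories Land-use categories entering the entropy (fixed k).
#' @param included Ids from [assign_polygons()]; computed when omitted.
#' @return Value in \[0, 1\].
#' @export
land_use_mix <- function(buffer, parcels,
                         categories = c("residential", "retail", "civic",
                                        "recreational"),
                         included = assign_polygons(buffer, parcels)) {
  f <- parcels$features
  f <- f[f$id %in% included & f$land_use_class %in% categories, , drop = FALSE]
  A <- vapply(categories, function(cl) sum(f$area[f$land_use_class == cl]),
              numeric(1))
  if (sum(A > 0) <= 1) return(0)
  p <- A[A > 0] / sum(A)
  -sum(p * log(p)) / log(length(categories))
}

#' Park count and total area within a buffer
#'
#' Included parks contribute their full areas (any-intersection rule).
#'
#' @param buffer A `buffer_polygon`.
#' @param parks A `park_set`.
#' @param unit `"m2"` (default) or `"acres"` for the area sum.
#' @param included Ids from [assign_polygons()]; computed when omitted.
#' @return List with `count` and `area_sum`.
#' @export
park_metrics <- function(buffer, parks, unit = c("m2", "acres"),
                         included = assign_polygons(buffer, parks)) {
  unit <- match.arg(unit)
  a <- sum(parks$features$area[parks$features$id %in% included])
  if (unit == "acres") a <- a / SQ_M_PER_ACRE
  list(count = length(included), area_sum = a)
}

#' Walkability index across an analysis sample
#'
#' Sum of sample z-scores of net residential density, land-use mix and
#' intersection density, computed separately per (method, trim) group; the
#' sample mean of the index is 0 by construction.
#'
#' @param res_density,land_use_mix,intersection_density Numeric vectors over
#'   participants of one (method, trim) group.
#' @return Numeric vector of index values (mean 0).
#' @export
walkability_index <- function(res_density, land_use_mix, intersection_density) {
  comps <- list(res_density = res_density, land_use_mix = land_use_mix,
                intersection_density = intersection_density)
  if (length(res_density) < 2) stop("walkability index needs >= 2 participants")
  z <- lapply(names(comps), function(nm) {
    v <- comps[[nm]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero variance in walkability component: ", nm)
    (v - mean(v)) / s
  })
  z[[1]] + z[[2]] + z[[3]]
}

#' Compute the full BEM table for a cohort
#'
#' Snaps each participant home to the walkable network, expands the 1 km (by
#' default) service area, constructs the requested buffers, and evaluates all
#' eleven BEMs per participant, method and trim.
#'
#' @param participants Validated participant data.frame.
#' @param net Walkable `street_network`.
#' @param parcels A `parcel_set`.
#' @param points A `point_feature_set`.
#' @param parks A `park_set`.
#' @param methods Buffer methods to run.
#' @param trims Trim distances in meters (default 25).
#' @param cutoff Network distance cutoff, meters (default 1000).
#' @param snapped Snap point features to the network before counting.
#' @param resolution Buffer grid cell size, meters.
#' @param ... Passed on to [network_buffers()] (surrogate radii, hole filling).
#' @return Data frame keyed by (participant_id, method, trim) with columns
#'   res_density, intersection_count, intersection_density, transit_count,
#'   transit_density, recreation_count, recreation_density, park_count,
#'   park_area_sum, land_use_mix, walk_index, plus buffer_area_m2.
#' @export
compute_bem_table <- function(participants, net, parcels, points, parks,
                              methods = BUFFER_METHODS, trims = 25,
                              cutoff = 1000, snapped = TRUE, resolution = 2,
                              ...) {
  # snap point features once (shared across participants/buffers)
  pts_xy <- cbind(points$x, points$y)
  if (snapped && nrow(points) > 0) {
    for (k in seq_len(nrow(points))) {
      loc <- snap_to_network(pts_xy[k, ], net, max_snap_distance = Inf)
      pts_xy[k, ] <- c(loc$x, loc$y)
    }
  }
  rows <- list()
  for (p in seq_len(nrow(participants))) {
    loc <- snap_to_network(c(participants$x[p], participants$y[p]), net)
    reach <- reachable_subnetwork(net, loc, cutoff = cutoff)
    for (trim in trims) {
      bufs <- network_buffers(reach, trim = trim, methods = methods,
                              resolution = resolution,
                              participant_id = participants$id[p], ...)
      for (m in names(bufs)) {
        b <- bufs[[m]]
        inc_parcels <- assign_polygons(b, parcels)
        inc_parks <- assign_polygons(b, parks)
        inside <- points_in_buffer(b, pts_xy)
        cnt <- table(factor(points$feature_class[inside],
                            levels = POINT_FEATURE_CLASSES))
        im <- intersection_metrics(b, net)
        pm <- park_metrics(b, parks, included = inc_parks)
        akm2 <- b$area / 1e6
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = participants$id[p], method = m, trim = trim,
          buffer_area_m2 = b$area,
          res_density = as.numeric(net_residential_density(b, parcels,
                                                           included = inc_parcels)),
          intersection_count = im$count,
          intersection_density = im$density,
          transit_count = as.integer(cnt[["transit_stop"]]),
          transit_density = as.integer(cnt[["transit_stop"]]) / akm2,
          recreation_count = as.integer(cnt[["private_recreation"]]),
          recreation_density = as.integer(cnt[["private_recreation"]]) / akm2,
          park_count = pm$count,
          park_area_sum = pm$area_sum,
          land_use_mix = land_use_mix(b, parcels, included = inc_parcels),
          stringsAsFactors = FALSE)
      }
    }
  }
  bem <- do.call(rbind, rows)
  bem$walk_index <- NA_real_
  for (m in unique(bem$method)) {
    for (trim in unique(bem$trim)) {
      sel <- bem$method == m & bem$trim == trim
      bem$walk_index[sel] <- walkability_index(bem$res_density[sel],
                                               bem$land_use_mix[sel],
                                               bem$intersection_density[sel])
    }
  }
  bem
}

#' The eleven BEM column names
#' @export
BEM_COLUMNS <- c("res_density", "intersection_count", "intersection_density",
                 "transit_count", "transit_density", "recreation_count",
                 "recreation_density", "park_count", "park_area_sum",
                 "land_use_mix", "walk_index")

#' Write a BEM table to tidy CSV
#' @param bem Data frame from [compute_bem_table()].
#' @param path Output file.
#' @export
write_bem_table <- function(bem, path) {
  utils::write.csv(bem, path, row.names = FALSE)
  invisible(path)
}
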