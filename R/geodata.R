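# Data model and I/O for street networks, parcels, point features, parks and
# participants. Coordinates are planar projected meters throughout; the package
# never reprojects (upstream responsibility). GeoJSON is used as the carrier
# format (RFC 7946 structure) but with planar meter coordinates by contract.

NODE_SNAP_TOL <- 1e-6

#' Land-use classes recognised by the package
#' @export
LAND_USE_CLASSES <- c("residential", "retail", "civic", "recreational", "other")

#' Point feature classes recognised by the package
#' @export
POINT_FEATURE_CLASSES <- c("transit_stop", "private_recreation")

# Road classes that pedestrians cannot traverse (configurable per call).
DEFAULT_NON_WALKABLE <- c("limited_access_highway", "highway_ramp")

# ---------------------------------------------------------------------------
# StreetNetwork

#' Construct a street network
#'
#' A planar embedded graph of road centerlines. Nodes are created at shared
#' polyline endpoints (coordinate snapping at 1e-6 m); each edge carries its
#' polyline geometry, arc length, road class, and a walkability flag.
#'
#' @param geoms List of two-column coordinate matrices, one polyline per edge.
#' @param road_class Character vector of road classes, one per edge.
#' @param non_walkable Road classes pedestrians may not use.
#' @return An object of class `street_network` with elements `nodes`
#'   (data.frame: id, x, y), `edges` (data.frame: id, from, to, length,
#'   road_class, walkable) and `geoms`.
#' @export
street_network <- function(geoms, road_class = rep("street", length(geoms)),
                           non_walkable = DEFAULT_NON_WALKABLE) {
  stopifnot(length(geoms) == length(road_class))
  key_of <- function(x, y) paste(round(x / NODE_SNAP_TOL), round(y / NODE_SNAP_TOL))
  node_key <- character(0)
  node_x <- numeric(0)
  node_y <- numeric(0)
  get_node <- function(x, y) {
    k <- key_of(x, y)
    i <- match(k, node_key)
    if (is.na(i)) {
      node_key[[length(node_key) + 1L]] <<- k
      node_x[[length(node_x) + 1L]] <<- x
      node_y[[length(node_y) + 1L]] <<- y
      i <- length(node_key)
    }
    i
  }
  ne <- length(geoms)
  from <- to <- integer(ne)
  len <- numeric(ne)
  for (e in seq_len(ne)) {
    g <- as.matrix(geoms[[e]])
    storage.mode(g) <- "double"
    if (!all(is.finite(g))) stop("edge ", e, ": non-finite coordinates")
    len[e] <- polyline_length(g)
    if (len[e] <= 0) stop("edge ", e, ": zero-length geometry")
    from[e] <- get_node(g[1, 1], g[1, 2])
    to[e] <- get_node(g[nrow(g), 1], g[nrow(g), 2])
    geoms[[e]] <- unname(g)
  }
  net <- structure(list(
    nodes = data.frame(id = seq_along(node_x), x = node_x, y = node_y),
    edges = data.frame(id = seq_len(ne), from = from, to = to, length = len,
                       road_class = as.character(road_class),
                       walkable = !(road_class %in% non_walkable),
                       stringsAsFactors = FALSE),
    geoms = geoms
  ), class = "street_network")
  validate_network(net)
  net
}

#' Validate street-network invariants
#'
#' Checks that edge endpoints coincide with node coordinates (1e-6 m), that
#' stored lengths equal polyline arc lengths (1e-6 m), that all lengths are
#' strictly positive and coordinates finite.
#'
#' @param net A `street_network`.
#' @return The network, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "street_network"))
  for (e in seq_len(nrow(net$edges))) {
    g <- net$geoms[[e]]
    a <- net$nodes[net$edges$from[e], c("x", "y")]
    b <- net$nodes[net$edges$to[e], c("x", "y")]
    if (max(abs(as.numeric(a) - g[1, ])) > NODE_SNAP_TOL ||
        max(abs(as.numeric(b) - g[nrow(g), ])) > NODE_SNAP_TOL)
      stop("edge ", e, ": endpoints do not coincide with node coordinates")
    if (abs(polyline_length(g) - net$edges$length[e]) > 1e-6)
      stop("edge ", e, ": stored length differs from arc length")
    if (net$edges$length[e] <= 0) stop("edge ", e, ": non-positive length")
  }
  if (!all(is.finite(as.matrix(net$nodes[, c("x", "y")]))))
    stop("non-finite node coordinates")
  invisible(net)
}

#' @exportS3Method base::print
print.street_network <- function(x, ...) {
  cat(sprintf("<street_network> %d nodes, %d edges (%d walkable), total %.1f km\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$walkable),
              sum(x$edges$length) / 1000))
  invisible(x)
}

#' Node degrees of a street network
#'
#' Loop edges contribute 2 to their node's degree.
#'
#' @param net A `street_network`.
#' @param walkable_only Count only walkable edges.
#' @return Integer vector over nodes (in `net$nodes` order).
#' @export
node_degrees <- function(net, walkable_only = FALSE) {
  ed <- net$edges
  if (walkable_only) ed <- ed[ed$walkable, , drop = FALSE]
  tabulate(c(ed$from, ed$to), nbins = nrow(net$nodes))
}

#' Restrict a network to its walkable edges
#'
#' Drops non-walkable edges (limited-access highways, ramps by default) and
#' any node left without an incident edge. The input is untouched.
#'
#' @param net A `street_network`.
#' @return A new `street_network`; warns and returns an empty network when no
#'   walkable edge remains.
#' @export
filter_walkable <- function(net) {
  keep <- which(net$edges$walkable)
  if (length(keep) == 0) {
    warning("no walkable edges remain after filtering")
  }
  street_network(net$geoms[keep], net$edges$road_class[keep],
                 non_walkable = unique(net$edges$road_class[!net$edges$walkable]))
}

# igraph view of a network; vertex names are node ids, edge weights lengths.
network_graph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$length, edge_id = net$edges$id),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
}

# ---------------------------------------------------------------------------
# GeoJSON plumbing (structure via jsonlite; planar meters by contract)

read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  gj
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

coords_matrix <- function(coord_list) {
  do.call(rbind, lapply(coord_list, function(p) c(p[[1]], p[[2]])))
}

# All-feature sanity check: planar meters expected, so a dataset living
# entirely inside the lon/lat range is treated as unprojected input.
check_projected <- function(xy, path) {
  if (nrow(xy) > 0 && all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90))
    stop("coordinates of ", path, " fall entirely within lon/lat range; ",
         "planar projected meters are required")
}

#' Load a street network from GeoJSON
#'
#' Features must be LineStrings with a `road_class` property; coordinates must
#' be planar projected meters. Nodes are created at shared endpoints
#' (1e-6 m snapping) and the walkable flag is derived from `road_class`.
#'
#' @param path GeoJSON file.
#' @param non_walkable Road classes treated as non-walkable.
#' @return A `street_network`.
#' @export
load_network <- function(path, non_walkable = DEFAULT_NON_WALKABLE) {
  gj <- read_geojson(path)
  geoms <- vector("list", length(gj$features))
  rc <- character(length(gj$features))
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    if (is.null(f$geometry$type) || f$geometry$type != "LineString")
      stop("feature ", k, " of ", path, " is not a LineString (got ",
           f$geometry$type %||% "NULL", ")")
    geoms[[k]] <- coords_matrix(f$geometry$coordinates)
    rc[k] <- f$properties$road_class %||% "street"
    if (polyline_length(geoms[[k]]) <= 0)
      stop("feature ", k, " of ", path, ": zero-length edge")
  }
  check_projected(do.call(rbind, geoms), path)
  street_network(geoms, rc, non_walkable = non_walkable)
}

#' Write a street network to GeoJSON
#'
#' @param net A `street_network`.
#' @param path Output file.
#' @export
write_network_geojson <- function(net, path) {
  feats <- lapply(seq_len(nrow(net$edges)), function(e) {
    g <- net$geoms[[e]]
    list(type = "Feature",
         properties = list(edge_id = net$edges$id[e],
                           road_class = net$edges$road_class[e]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(i) as.numeric(g[i, ]))))
  })
  write_geojson(feats, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Parcels, parks, point features

validate_ring <- function(ring) {
  is.matrix(ring) && ncol(ring) == 2 && nrow(ring) >= 3 &&
    all(is.finite(ring)) && abs(ring_signed_area(ring)) > 0
}

#' Construct a parcel set
#'
#' @param geoms List of polygons; each polygon is a two-column ring matrix or
#'   a list of ring matrices (first exterior, rest holes).
#' @param land_use_class Character vector in
#'   `r paste(LAND_USE_CLASSES, collapse = ", ")`.
#' @param residential_units Non-negative integer counts; must be 0 unless the
#'   parcel is residential.
#' @return A `parcel_set`: data.frame `features` (id, land_use_class,
#'   residential_units, area with full-parcel areas in m^2) plus `geoms`.
#' @export
parcel_set <- function(geoms, land_use_class, residential_units) {
  geoms <- lapply(geoms, function(g) if (is.matrix(g)) list(unname(g)) else lapply(g, unname))
  n <- length(geoms)
  stopifnot(length(land_use_class) == n, length(residential_units) == n)
  if (!all(land_use_class %in% LAND_USE_CLASSES))
    stop("unknown land_use_class: ",
         paste(setdiff(land_use_class, LAND_USE_CLASSES), collapse = ", "))
  if (any(residential_units < 0)) stop("negative residential_units")
  bad <- residential_units > 0 & land_use_class != "residential"
  if (any(bad))
    stop("non-residential parcel with residential_units > 0: parcel ",
         which(bad)[1])
  area <- vapply(geoms, polygon_area, numeric(1))
  ok <- vapply(geoms, function(g) validate_ring(g[[1]]), logical(1)) & area > 0
  if (!all(ok)) stop("invalid parcel polygon: parcel ", which(!ok)[1])
  structure(list(features = data.frame(id = seq_len(n),
                                       land_use_class = as.character(land_use_class),
                                       residential_units = as.integer(residential_units),
                                       area = area, stringsAsFactors = FALSE),
                 geoms = geoms),
            class = "parcel_set")
}

#' Construct a park set
#'
#' @param geoms List of polygons (as in [parcel_set()]).
#' @return A `park_set` with features (id, area in m^2) and geometries.
#' @export
park_set <- function(geoms) {
  geoms <- lapply(geoms, function(g) if (is.matrix(g)) list(unname(g)) else lapply(g, unname))
  area <- vapply(geoms, polygon_area, numeric(1))
  if (any(area <= 0)) stop("park with non-positive area: park ", which(area <= 0)[1])
  structure(list(features = data.frame(id = seq_along(geoms), area = area),
                 geoms = geoms),
            class = "park_set")
}

#' Construct a point feature set
#'
#' @param x,y Numeric coordinate vectors (meters).
#' @param feature_class Character vector in
#'   `r paste(POINT_FEATURE_CLASSES, collapse = ", ")`.
#' @return A `point_feature_set` data.frame (id, x, y, feature_class).
#' @export
point_feature_set <- function(x, y, feature_class) {
  stopifnot(length(x) == length(y), length(x) == length(feature_class))
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite point coordinates")
  if (!all(feature_class %in% POINT_FEATURE_CLASSES))
    stop("unknown feature_class: ",
         paste(setdiff(feature_class, POINT_FEATURE_CLASSES), collapse = ", "))
  structure(data.frame(id = seq_along(x), x = x, y = y,
                       feature_class = as.character(feature_class),
                       stringsAsFactors = FALSE),
            class = c("point_feature_set", "data.frame"))
}

polygon_geoms_from_geojson <- function(gj, path) {
  lapply(seq_along(gj$features), function(k) {
    f <- gj$features[[k]]
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon")
      stop("feature ", k, " of ", path, " is not a Polygon")
    lapply(f$geometry$coordinates, coords_matrix)
  })
}

#' Load parcels from GeoJSON
#'
#' Polygon features with properties `land_use_class` and `residential_units`.
#'
#' @param path GeoJSON file.
#' @return A `parcel_set`.
#' @export
load_parcels <- function(path) {
  gj <- read_geojson(path)
  geoms <- polygon_geoms_from_geojson(gj, path)
  luc <- vapply(gj$features, function(f) f$properties$land_use_class %||% NA_character_,
                character(1))
  units <- vapply(gj$features, function(f) as.numeric(f$properties$residential_units %||% 0),
                  numeric(1))
  check_projected(do.call(rbind, lapply(geoms, `[[`, 1)), path)
  parcel_set(geoms, luc, units)
}

#' Load parks from GeoJSON
#' @param path GeoJSON file of Polygon features.
#' @return A `park_set`.
#' @export
load_parks <- function(path) {
  gj <- read_geojson(path)
  geoms <- polygon_geoms_from_geojson(gj, path)
  check_projected(do.call(rbind, lapply(geoms, `[[`, 1)), path)
  park_set(geoms)
}

#' Load point features (transit stops, private recreation) from GeoJSON
#' @param path GeoJSON file of Point features with a `feature_class` property.
#' @return A `point_feature_set`.
#' @export
load_points <- function(path) {
  gj <- read_geojson(path)
  xy <- t(vapply(gj$features, function(f) {
    if (is.null(f$geometry$type) || f$geometry$type != "Point")
      stop("non-Point feature in ", path)
    c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]])
  }, numeric(2)))
  fc <- vapply(gj$features, function(f) f$properties$feature_class %||% NA_character_,
               character(1))
  check_projected(xy, path)
  point_feature_set(xy[, 1], xy[, 2], fc)
}

write_polygon_geojson <- function(geoms, props_list, path) {
  feats <- lapply(seq_along(geoms), function(k) {
    rings <- geoms[[k]]
    list(type = "Feature",
         properties = props_list[[k]],
         geometry = list(type = "Polygon",
                         coordinates = lapply(rings, function(r) {
                           if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
                           lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
                         })))
  })
  write_geojson(feats, path)
}

#' Write parcels / parks / points to GeoJSON
#' @param x A `parcel_set`, `park_set` or `point_feature_set`.
#' @param path Output file.
#' @export
write_features_geojson <- function(x, path) {
  if (inherits(x, "parcel_set")) {
    props <- lapply(seq_len(nrow(x$features)), function(k)
      list(id = x$features$id[k],
           land_use_class = x$features$land_use_class[k],
           residential_units = x$features$residential_units[k]))
    write_polygon_geojson(x$geoms, props, path)
  } else if (inherits(x, "park_set")) {
    props <- lapply(x$features$id, function(id) list(id = id))
    write_polygon_geojson(x$geoms, props, path)
  } else if (inherits(x, "point_feature_set")) {
    feats <- lapply(seq_len(nrow(x)), function(k)
      list(type = "Feature",
           properties = list(id = x$id[k], feature_class = x$feature_class[k]),
           geometry = list(type = "Point",
                           coordinates = c(x$x[k], x$y[k]))))
    write_geojson(feats, path)
  } else stop("unsupported feature set class")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Participants

PARTICIPANT_COLUMNS <- c("id", "x", "y", "age", "gender", "education",
                         "marital", "employment", "cluster_id", "ses_stratum",
                         "walkability_stratum", "city",
                         "walk_transport_days", "walk_transport_min",
                         "walk_leisure_days", "walk_leisure_min", "sitting_min")

OUTCOME_COLUMNS <- c("walk_transport_days", "walk_transport_min",
                     "walk_leisure_days", "walk_leisure_min", "sitting_min")

EDUCATION_LEVELS <- c("less_than_high_school", "high_school_or_some_college",
                      "college_or_higher")

#' Validate a participant table
#'
#' Enforces the closed covariate vocabularies, outcome ranges (day counts in
#' 0-7, minute totals non-negative) and non-empty cluster ids.
#'
#' @param df A data.frame with the documented participant columns.
#' @return The validated data.frame, invisibly.
#' @export
validate_participants <- function(df) {
  missing_cols <- setdiff(PARTICIPANT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("participant table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  chk <- function(col, ok) {
    bad <- which(!ok)
    if (length(bad) > 0)
      stop("participant row id ", df$id[bad[1]], ": invalid ", col,
           " (", df[[col]][bad[1]], ")")
  }
  chk("age", is.finite(df$age) & df$age >= 18 & df$age <= 100)
  chk("gender", df$gender %in% c("female", "male"))
  chk("education", df$education %in% EDUCATION_LEVELS)
  chk("marital", df$marital %in% c("married_or_partner", "other"))
  chk("employment", df$employment %in% c("yes", "no"))
  chk("cluster_id", !is.na(df$cluster_id) & nzchar(as.character(df$cluster_id)))
  chk("ses_stratum", df$ses_stratum %in% c("low", "high"))
  chk("walkability_stratum", df$walkability_stratum %in% c("low", "high"))
  for (col in c("walk_transport_days", "walk_leisure_days"))
    chk(col, is.finite(df[[col]]) & df[[col]] >= 0 & df[[col]] <= 7)
  for (col in c("walk_transport_min", "walk_leisure_min", "sitting_min"))
    chk(col, is.finite(df[[col]]) & df[[col]] >= 0)
  invisible(df)
}

#' Load a participant table from CSV
#'
#' UTF-8 CSV with "." decimal separator and the documented header (see
#' [validate_participants()]).
#'
#' @param path CSV file.
#' @return A validated participant data.frame.
#' @export
load_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_participants(df)
  df
}

#' Write a participant table to CSV
#' @param df Participant data.frame.
#' @param path Output file.
#' @export
write_participants <- function(df, path) {
  utils::write.csv(df[, PARTICIPANT_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
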