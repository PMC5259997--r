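# Data model and I/O: network construction, walkability filtering, feature
# validation, GeoJSON/CSV round trips.

test_that("collinear segments sharing an endpoint form a 3-node, 2-edge network", {
  net <- street_network(list(rbind(c(1000, 0), c(2000, 0)),
                             rbind(c(2000, 0), c(3000, 0))))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$length, c(1000, 1000))
  # shared endpoint resolves to one node
  expect_equal(net$edges$to[1], net$edges$from[2])
})

test_that("walkability flag is derived from the road-class deny list", {
  net <- street_network(list(rbind(c(1000, 0), c(2000, 0)),
                             rbind(c(2000, 0), c(3000, 0)),
                             rbind(c(3000, 0), c(4000, 0))),
                        road_class = c("street", "limited_access_highway",
                                       "highway_ramp"))
  expect_equal(net$edges$walkable, c(TRUE, FALSE, FALSE))
  # custom deny list
  net2 <- street_network(list(rbind(c(1000, 0), c(2000, 0))),
                         road_class = "service_road",
                         non_walkable = "service_road")
  expect_false(net2$edges$walkable)
})

test_that("filter_walkable keeps walkable edges only and leaves input intact", {
  geoms <- lapply(0:9, function(k) rbind(c(1000 + 100 * k, 0),
                                         c(1100 + 100 * k, 0)))
  rc <- rep("street", 10)
  rc[c(2, 5, 8)] <- "limited_access_highway"
  net <- street_network(geoms, rc)
  wnet <- filter_walkable(net)
  expect_equal(nrow(wnet$edges), 7)
  expect_true(all(wnet$edges$walkable))
  expect_equal(nrow(net$edges), 10)  # original untouched
  expect_warning(filter_walkable(street_network(list(rbind(c(1000, 0), c(2000, 0))),
                                                "limited_access_highway")),
                 "no walkable")
})

test_that("network loader rejects malformed input", {
  bad_point <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(road_class = "street"),
         geometry = list(type = "Point", coordinates = c(1000, 2000))))),
    bad_point, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(bad_point), "not a LineString")

  lonlat <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(road_class = "street"),
         geometry = list(type = "LineString",
                         coordinates = list(c(-122.3, 47.6), c(-122.2, 47.7)))))),
    lonlat, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(lonlat), "lon/lat")

  expect_error(street_network(list(rbind(c(1000, 0), c(1000, 0)))),
               "zero-length")
})

test_that("network GeoJSON round trip preserves geometry and attributes", {
  net <- generate_network(city_config(grid_blocks = c(4, 4),
                                      edge_prune_prob = 0.2,
                                      limited_access_fraction = 0.1), seed = 11)
  f <- tempfile(fileext = ".geojson")
  write_network_geojson(net, f)
  net2 <- load_network(f)
  expect_equal(nrow(net2$edges), nrow(net$edges))
  expect_equal(net2$edges$road_class, net$edges$road_class)
  expect_equal(net2$edges$walkable, net$edges$walkable)
  for (e in seq_along(net$geoms))
    expect_lt(max(abs(net2$geoms[[e]] - net$geoms[[e]])), 1e-6)
  # degree-sum identity on the loaded network
  expect_equal(sum(node_degrees(net2)), 2 * nrow(net2$edges))
})

test_that("parcel validation enforces unit and class rules", {
  sq <- function(x, y, s = 50) rbind(c(x, y), c(x + s, y), c(x + s, y + s),
                                     c(x, y + s))
  ps <- parcel_set(list(sq(1000, 0), sq(1100, 0)),
                   c("residential", "retail"), c(12, 0))
  expect_equal(ps$features$area, c(2500, 2500))
  expect_error(parcel_set(list(sq(0, 0)), "retail", 5), "residential_units")
  expect_error(parcel_set(list(sq(0, 0)), "residential", -1), "negative")
  expect_error(parcel_set(list(sq(0, 0)), "industrial", 0), "land_use_class")
})

test_that("parcels, parks and points survive a GeoJSON round trip", {
  sq <- function(x, y, s = 60) rbind(c(x, y), c(x + s, y), c(x + s, y + s),
                                     c(x, y + s))
  parcels <- parcel_set(list(sq(1000, 0), sq(1100, 0), sq(1200, 0)),
                        c("residential", "civic", "recreational"), c(30, 0, 0))
  parks <- park_set(list(sq(1000, 200, 80)))
  pts <- point_feature_set(c(1010, 1220), c(40, 90),
                           c("transit_stop", "private_recreation"))
  d <- tempfile(); dir.create(d)
  write_features_geojson(parcels, file.path(d, "parcels.geojson"))
  write_features_geojson(parks, file.path(d, "parks.geojson"))
  write_features_geojson(pts, file.path(d, "points.geojson"))
  p2 <- load_parcels(file.path(d, "parcels.geojson"))
  k2 <- load_parks(file.path(d, "parks.geojson"))
  x2 <- load_points(file.path(d, "points.geojson"))
  expect_equal(p2$features$land_use_class, parcels$features$land_use_class)
  expect_equal(p2$features$residential_units, parcels$features$residential_units)
  expect_equal(p2$features$area, parcels$features$area, tolerance = 1e-9)
  expect_equal(k2$features$area, parks$features$area, tolerance = 1e-9)
  expect_equal(x2$feature_class, pts$feature_class)
  expect_lt(max(abs(c(x2$x - pts$x, x2$y - pts$y))), 1e-6)
})

test_that("participant loader validates schema and outcome ranges", {
  city <- generate_city(city_config(grid_blocks = c(4, 4)), n = 8,
                        n_clusters = 3, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_participants(city$participants, f)
  df <- load_participants(f)
  expect_equal(nrow(df), 8)
  expect_equal(df$cluster_id, city$participants$cluster_id)

  bad <- city$participants
  bad$walk_transport_days[3] <- 9
  expect_error(validate_participants(bad), "walk_transport_days")
  expect_error(validate_participants(bad[, -4]), "missing column")
  bad2 <- city$participants
  bad2$education[1] <- "phd"
  expect_error(validate_participants(bad2), "education")
})
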