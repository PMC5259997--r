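# Built-environment measures: assignment rules, snapping, densities, entropy,
# walkability index, and cross-checks against exhaustive oracles.

straight_buffer <- function(trim = 25, resolution = 1) {
  net <- make_straight_road()
  loc <- snap_to_network(c(2000, 0), net)
  reach <- reachable_subnetwork(net, loc, 1000)
  list(net = net, reach = reach,
       buf = sausage_buffer(reach, trim = trim, resolution = resolution))
}

sq <- function(x, y, w, h = w) rbind(c(x, y), c(x + w, y), c(x + w, y + h),
                                     c(x, y + h))

test_that("polygons are assigned by the any-intersection rule", {
  fx <- straight_buffer(trim = 25, resolution = 0.5)
  parks <- park_set(list(
    sq(1500, -10, 20),   # wholly inside the buffer band
    sq(1600, 24, 60),    # overlaps the buffer edge by a 1 m strip
    sq(1700, 26, 60),    # 1 m outside
    sq(5000, 0, 60)))    # far outside the reach
  inc <- assign_polygons(fx$buf, parks)
  expect_equal(inc, c(1, 2))
  # included parks contribute their FULL areas
  pm <- park_metrics(fx$buf, parks, included = inc)
  expect_equal(pm$count, 2)
  expect_equal(pm$area_sum, 20^2 + 60^2)
  expect_equal(park_metrics(fx$buf, parks, unit = "acres",
                            included = inc)$area_sum,
               (400 + 3600) / 4046.8564224)
})

test_that("a polygon fully enclosing the buffer is assigned", {
  fx <- straight_buffer()
  giant <- park_set(list(sq(-500, -500, 5000, 1000)))
  expect_equal(assign_polygons(fx$buf, giant), 1)
})

test_that("point features off the roadway are captured when snapped", {
  fx <- straight_buffer()
  pts <- point_feature_set(c(1500, 3800), c(40, 5),
                           c("transit_stop", "transit_stop"))
  unsnapped <- count_snapped_points(fx$buf, pts, snapped = FALSE)
  snapped <- count_snapped_points(fx$buf, pts, net = fx$net, snapped = TRUE)
  expect_equal(unname(unsnapped["transit_stop"]), 0L)  # 40 m > 25 m trim
  # the 1500 m stop snaps onto the reached road; the 3800 m stop snaps onto an
  # unreached part of the network and stays uncounted
  expect_equal(unname(snapped["transit_stop"]), 1L)
  empty <- point_feature_set(numeric(0), numeric(0), character(0))
  expect_equal(sum(count_snapped_points(fx$buf, empty, snapped = FALSE)), 0L)
})

test_that("snapped counts are >= unsnapped counts for near-street features", {
  # all points within trim-reach of reached streets once snapped
  net <- filter_walkable(make_random_city_net(5))
  loc <- snap_to_network(c(10250, 10250), net)
  reach <- reachable_subnetwork(net, loc, 400)
  buf <- sausage_buffer(reach, trim = 25, resolution = 1)
  set.seed(42)
  base <- reach_sample_points(reach, spacing = 80)
  pts <- point_feature_set(base[, 1] + runif(nrow(base), -30, 30),
                           base[, 2] + runif(nrow(base), -30, 30),
                           rep("transit_stop", nrow(base)))
  s <- count_snapped_points(buf, pts, net = net, snapped = TRUE)
  u <- count_snapped_points(buf, pts, net = net, snapped = FALSE)
  expect_gte(s["transit_stop"], u["transit_stop"])
})

test_that("net residential density divides units by residential land only", {
  fx <- straight_buffer(trim = 75)
  parcels <- parcel_set(list(sq(1200, -100, 200, 100),   # residential, 2 ha
                             sq(1500, -100, 200, 100),   # residential, 2 ha
                             sq(1800, -100, 200, 100)),  # retail (ignored)
                        c("residential", "residential", "retail"),
                        c(120, 80, 0))
  inc <- assign_polygons(fx$buf, parcels)
  expect_equal(inc, c(1, 2, 3))
  expect_equal(as.numeric(net_residential_density(fx$buf, parcels,
                                                  included = inc)),
               200 / 0.04)
  # linearity in unit counts
  parcels2 <- parcel_set(parcels$geoms, parcels$features$land_use_class,
                         parcels$features$residential_units * 2)
  expect_equal(as.numeric(net_residential_density(fx$buf, parcels2,
                                                  included = inc)),
               2 * 200 / 0.04)
  # no residential parcels -> 0 with a missing-denominator flag
  retail_only <- parcel_set(list(sq(1800, -100, 200, 100)), "retail", 0)
  d0 <- net_residential_density(fx$buf, retail_only)
  expect_equal(as.numeric(d0), 0)
  expect_true(attr(d0, "missing_denominator"))
})

test_that("intersections are degree >= 3 walkable nodes inside the buffer", {
  plus <- make_plus()
  loc <- snap_to_network(c(10000, 10000), plus)
  reach <- reachable_subnetwork(plus, loc, 1000)
  buf <- sausage_buffer(reach, trim = 25, resolution = 1)
  im <- intersection_metrics(buf, plus)
  expect_equal(im$count, 1L)  # only the central degree-4 node
  expect_equal(im$density, 1 / (buf$area / 1e6))

  fx <- straight_buffer()
  expect_equal(intersection_metrics(fx$buf, fx$net)$count, 0L)
})

test_that("grid-city intersection counts match a point-in-polygon oracle", {
  net <- filter_walkable(make_random_city_net(9))
  loc <- snap_to_network(c(10250, 10250), net)
  reach <- reachable_subnetwork(net, loc, 450)
  for (b in network_buffers(reach, trim = 25, resolution = 1)) {
    deg <- node_degrees(net, walkable_only = TRUE)
    cand <- net$nodes[deg >= 3, ]
    polys <- buffer_multipolygon(b)
    oracle <- sum(vapply(seq_len(nrow(cand)), function(k) {
      any(vapply(polys, function(poly)
        bufcomp:::points_in_polygon(cbind(cand$x[k], cand$y[k]), poly),
        logical(1)))
    }, logical(1)))
    expect_equal(intersection_metrics(b, net)$count, oracle)
  }
})

test_that("land-use-mix entropy hits its closed-form values", {
  fx <- straight_buffer(trim = 75)
  mk <- function(classes, sizes) {
    parcel_set(lapply(seq_along(classes), function(k)
      sq(1200 + 250 * (k - 1), -80, sizes[k], sizes[k])),
      classes, ifelse(classes == "residential", 10, 0))
  }
  four_even <- mk(c("residential", "retail", "civic", "recreational"),
                  rep(100, 4))
  expect_equal(land_use_mix(fx$buf, four_even), 1.0, tolerance = 1e-12)
  single <- mk("residential", 100)
  expect_equal(land_use_mix(fx$buf, single), 0)
  two_even <- mk(c("residential", "retail"), c(100, 100))
  expect_equal(land_use_mix(fx$buf, two_even), log(2) / log(4))
  # invariant under uniform scaling of all areas
  two_scaled <- mk(c("residential", "retail"), c(50, 50))
  expect_equal(land_use_mix(fx$buf, two_scaled),
               land_use_mix(fx$buf, two_even))
  # "other" parcels stay out of the entropy by default
  with_other <- mk(c("residential", "retail", "other"), c(100, 100, 180))
  expect_equal(land_use_mix(fx$buf, with_other), log(2) / log(4))
})

test_that("walkability index is the sum of component z-scores with mean 0", {
  rd <- c(1000, 2000, 3000, 4000, 5000)
  lum <- c(0.2, 0.4, 0.1, 0.8, 0.6)
  id <- c(40, 90, 20, 150, 70)
  wi <- walkability_index(rd, lum, id)
  z <- function(v) (v - mean(v)) / sd(v)
  expect_equal(wi, z(rd) + z(lum) + z(id))
  expect_lt(abs(mean(wi)), 1e-9)
  expect_equal(sd(z(rd)), 1)
  # a participant sitting at all three component means scores 0
  rd2 <- c(rd, mean(rd)); lum2 <- c(lum, mean(lum)); id2 <- c(id, mean(id))
  expect_equal(walkability_index(rd2, lum2, id2)[6], 0, tolerance = 1e-9)
  expect_error(walkability_index(rep(1, 5), lum, id), "zero variance")
})

test_that("densities in a computed BEM table recompute as count over area", {
  city <- generate_city(city_config(grid_blocks = c(8, 8)), n = 5,
                        n_clusters = 2, seed = 13)
  wnet <- filter_walkable(city$net)
  bem <- compute_bem_table(city$participants, wnet, city$parcels, city$points,
                           city$parks, trims = 25, cutoff = 600,
                           resolution = 3)
  akm2 <- bem$buffer_area_m2 / 1e6
  expect_equal(bem$intersection_density, bem$intersection_count / akm2,
               tolerance = 1e-9)
  expect_equal(bem$transit_density, bem$transit_count / akm2,
               tolerance = 1e-9)
  expect_equal(bem$recreation_density, bem$recreation_count / akm2,
               tolerance = 1e-9)
  expect_true(all(bem$land_use_mix >= 0 & bem$land_use_mix <= 1))
  expect_true(all(bem[, c("intersection_count", "transit_count",
                          "recreation_count", "park_count")] >= 0))
  # counts never shrink as buffers grow within a participant/trim
  for (pid in unique(bem$participant_id)) {
    g <- bem[bem$participant_id == pid, ]
    g <- g[match(c("sausage", "detailed_trimmed", "detailed"), g$method), ]
    for (col in c("intersection_count", "transit_count", "recreation_count",
                  "park_count"))
      expect_true(all(diff(g[[col]]) >= 0))
  }
})
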