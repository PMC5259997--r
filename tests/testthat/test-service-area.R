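# Snapping and network reach: perpendicular projection, tie rules, partial
# edges, interval merging, and the densified-graph oracle.

test_that("snapping finds the perpendicular foot on a straight road", {
  net <- make_straight_road()
  loc <- snap_to_network(c(500, 10), net)
  expect_equal(loc$edge_id, 1)
  expect_equal(c(loc$x, loc$y), c(500, 0))
  expect_equal(loc$offset, 500)
  expect_equal(loc$snap_distance, 10)
})

test_that("a point on a node snaps with zero distance and endpoint offset", {
  net <- street_network(list(rbind(c(1000, 0), c(2000, 0)),
                             rbind(c(2000, 0), c(3000, 0))))
  loc <- snap_to_network(c(2000, 0), net)
  expect_equal(loc$snap_distance, 0)
  expect_true((loc$edge_id == 1 && loc$offset == 1000) ||
                (loc$edge_id == 2 && loc$offset == 0))
})

test_that("snap ties resolve to the lowest edge id", {
  # two parallel roads equidistant from the probe point
  net <- street_network(list(rbind(c(1000, 100), c(2000, 100)),
                             rbind(c(1000, -100), c(2000, -100))))
  loc <- snap_to_network(c(1500, 0), net)
  expect_equal(loc$edge_id, 1)
  expect_equal(loc$snap_distance, 100)
})

test_that("snapping ignores non-walkable edges and warns on long snaps", {
  net <- street_network(list(rbind(c(1000, 0), c(2000, 0)),
                             rbind(c(1000, 50), c(2000, 50))),
                        road_class = c("limited_access_highway", "street"))
  loc <- snap_to_network(c(1500, 10), net)
  expect_equal(loc$edge_id, 2)  # nearest walkable, not nearest overall
  expect_warning(snap_to_network(c(1500, 2000), net, max_snap_distance = 500),
                 "snap distance")
  empty <- suppressWarnings(filter_walkable(
    street_network(list(rbind(c(1000, 0), c(2000, 0))),
                   "limited_access_highway")))
  expect_error(snap_to_network(c(0, 0), empty), "no walkable")
})

test_that("reach on a straight road is symmetric around the origin", {
  net <- make_straight_road()
  loc <- snap_to_network(c(2000, 10), net)
  reach <- reachable_subnetwork(net, loc, 1000)
  expect_equal(nrow(reach$segments), 1)  # two directions merge into one interval
  expect_equal(reach$segments$from_offset, 1000)
  expect_equal(reach$segments$to_offset, 3000)
  expect_equal(reach$total_length, 2000)
})

test_that("reach from a plus-network center covers 1 km down each arm", {
  net <- make_plus()
  loc <- snap_to_network(c(10000, 10000), net)
  reach <- reachable_subnetwork(net, loc, 1000)
  expect_equal(reach$total_length, 4000)
  expect_equal(nrow(reach$segments), 4)
})

test_that("reach input contracts are enforced", {
  net <- make_straight_road()
  loc <- snap_to_network(c(2000, 0), net)
  expect_error(reachable_subnetwork(net, loc, 0), "positive")
  expect_error(reachable_subnetwork(net, loc, -5), "positive")
  mixed <- street_network(list(rbind(c(1000, 0), c(2000, 0)),
                               rbind(c(2000, 0), c(3000, 0))),
                          c("street", "limited_access_highway"))
  bad_loc <- structure(list(edge_id = 2, offset = 500, x = 2500, y = 0,
                            snap_distance = 0), class = "network_location")
  expect_error(reachable_subnetwork(mixed, bad_loc), "non-walkable")
})

test_that("an edge reachable from both ends merges overlapping partial reaches", {
  # square loop of four 100 m sides: cutoff 200 wraps around and overlaps on
  # the far side, which must merge into a single full-edge segment
  sq <- street_network(list(rbind(c(1000, 0), c(1100, 0)),
                            rbind(c(1100, 0), c(1100, 100)),
                            rbind(c(1100, 100), c(1000, 100)),
                            rbind(c(1000, 100), c(1000, 0))))
  loc <- snap_to_network(c(1050, 0), sq)
  reach <- reachable_subnetwork(sq, loc, 200)
  expect_equal(reach$total_length, 400)
  far <- reach$segments[reach$segments$edge_id == 3, ]
  expect_equal(nrow(far), 1)
  expect_equal(c(far$from_offset, far$to_offset), c(0, 100))
})

test_that("a far edge reached from both ends can keep a gap in the middle", {
  # 400 m square, origin mid-bottom, cutoff 700: the opposite side is entered
  # from both of its ends (600 m each) but its midpoint is 800 m away
  sq <- street_network(list(rbind(c(1000, 0), c(1400, 0)),
                            rbind(c(1400, 0), c(1400, 400)),
                            rbind(c(1400, 400), c(1000, 400)),
                            rbind(c(1000, 400), c(1000, 0))))
  loc <- snap_to_network(c(1200, 0), sq)
  reach <- reachable_subnetwork(sq, loc, 700)
  far <- reach$segments[reach$segments$edge_id == 3, ]
  expect_equal(nrow(far), 2)  # two disjoint partial reaches
  expect_equal(reach$total_length, 700 * 2)
  expect_equal(reach$total_length, densified_reach_oracle(sq, loc, 700),
               tolerance = 1e-9)
})

test_that("reach monotonicity: larger cutoffs extend every interval", {
  for (s in 1:5) {
    net <- filter_walkable(make_random_city_net(s))
    set.seed(s)
    loc <- snap_to_network(c(10000 + runif(1, 50, 450),
                             10000 + runif(1, 50, 450)), net)
    r1 <- reachable_subnetwork(net, loc, 250)
    r2 <- reachable_subnetwork(net, loc, 400)
    expect_lte(r1$total_length, r2$total_length)
    # every reached interval of the smaller cutoff lies inside one of the
    # larger cutoff's intervals for the same edge
    for (i in seq_len(nrow(r1$segments))) {
      seg <- r1$segments[i, ]
      host <- r2$segments[r2$segments$edge_id == seg$edge_id, ]
      expect_true(any(host$from_offset <= seg$from_offset + 1e-9 &
                        host$to_offset >= seg$to_offset - 1e-9))
    }
  }
})

test_that("a cutoff beyond the network diameter reaches the whole component", {
  net <- filter_walkable(make_random_city_net(3))
  loc <- snap_to_network(c(10250, 10250), net)
  reach <- reachable_subnetwork(net, loc, 1e6)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to), directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  comp <- igraph::components(g)
  m0 <- comp$membership[net$edges$from[match(loc$edge_id, net$edges$id)]]
  in_comp <- comp$membership[net$edges$from] == m0
  expect_equal(reach$total_length, sum(net$edges$length[in_comp]))
})

test_that("reach matches the densified-graph oracle on random pruned grids", {
  for (s in 1:6) {
    net <- filter_walkable(make_random_city_net(s))
    set.seed(100 + s)
    loc <- snap_to_network(c(10000 + runif(1, 50, 450),
                             10000 + runif(1, 50, 450)), net)
    reach <- reachable_subnetwork(net, loc, 300)
    expect_equal(reach$total_length, densified_reach_oracle(net, loc, 300),
                 tolerance = 1e-3)
  }
})

test_that("reach exports as participant-tagged GeoJSON line features", {
  net <- make_plus()
  loc <- snap_to_network(c(10000, 10000), net)
  reach <- reachable_subnetwork(net, loc, 800)
  f <- tempfile(fileext = ".geojson")
  write_reach_geojson(reach, participant_id = 42, f)
  gj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(length(gj$features), 4)
  expect_equal(gj$features[[1]]$properties$participant_id, 42)
  expect_equal(gj$features[[1]]$geometry$type, "LineString")
})
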