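# Seeded synthetic-city generator: a pruned street grid spanning the
# low-to-high connectivity contrast, land-use parcels tiling the blocks, point
# features scattered along streets, block parks, and a participant cohort with
# SES x walkability strata, spatially contiguous recruitment clusters, and
# outcomes drawn from a latent-Gaussian model with a cluster random intercept.
# Every stage is a pure function of its config and seed.

#' Synthetic city configuration
#'
#' @param grid_blocks `c(m, n)` blocks (the street grid has (m+1) x (n+1)
#'   nodes).
#' @param block_size Block edge length, meters.
#' @param edge_prune_prob Probability of deleting each grid edge; spans the
#'   low/high street-connectivity contrast with one parameter.
#' @param limited_access_fraction Fraction of surviving edges flagged as
#'   limited-access highway (non-walkable).
#' @param category_shares Named probabilities over land-use classes for
#'   parcels.
#' @param units_per_residential_parcel Poisson mean of the unit count of a
#'   residential parcel.
#' @param parcels_per_block Parcels tiling each block (1, 2 or 4).
#' @param point_intensity Named per-class intensities, features per km of
#'   street.
#' @param point_jitter Perpendicular offset of point features from the street
#'   centerline, meters.
#' @param park_block_prob Probability that a block hosts a park.
#' @param origin South-west corner of the grid (defaults to a projected-CRS
#'   style false easting/northing).
#' @return A `city_config` list.
#' @export
city_config <- function(grid_blocks = c(12, 12), block_size = 100,
                        edge_prune_prob = 0.1, limited_access_fraction = 0.03,
                        category_shares = c(residential = 0.55, retail = 0.15,
                                            civic = 0.10, recreational = 0.10,
                                            other = 0.10),
                        units_per_residential_parcel = 30,
                        parcels_per_block = 4,
                        point_intensity = c(transit_stop = 0.8,
                                            private_recreation = 0.5),
                        point_jitter = 15,
                        park_block_prob = 0.05,
                        origin = c(10000, 10000)) {
  stopifnot(block_size > 0, edge_prune_prob >= 0, edge_prune_prob < 1,
            limited_access_fraction >= 0, limited_access_fraction < 1,
            all(category_shares >= 0), abs(sum(category_shares) - 1) < 1e-9,
            all(names(category_shares) %in% LAND_USE_CLASSES),
            parcels_per_block %in% c(1, 2, 4))
  structure(list(grid_blocks = grid_blocks, block_size = block_size,
                 edge_prune_prob = edge_prune_prob,
                 limited_access_fraction = limited_access_fraction,
                 category_shares = category_shares,
                 units_per_residential_parcel = units_per_residential_parcel,
                 parcels_per_block = parcels_per_block,
                 point_intensity = point_intensity,
                 point_jitter = point_jitter,
                 park_block_prob = park_block_prob,
                 origin = origin),
            class = "city_config")
}

#' Generate a pruned-grid street network
#'
#' (m+1) x (n+1) grid nodes at `block_size` spacing; each edge is removed
#' independently with `edge_prune_prob`, and a random fraction of survivors is
#' flagged limited-access (non-walkable). Retries (up to 100 times) until the
#' largest walkable component carries at least 80% of all nodes, so cohort
#' homes always sit on one connected component.
#'
#' @param cfg A `city_config`.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A `street_network`.
#' @export
generate_network <- function(cfg, seed = 1) {
  set.seed(seed)
  m <- cfg$grid_blocks[1]; n <- cfg$grid_blocks[2]
  bs <- cfg$block_size
  ox <- cfg$origin[1]; oy <- cfg$origin[2]
  node_xy <- function(i, j) c(ox + i * bs, oy + j * bs)
  build <- function() {
    geoms <- list(); k <- 0L
    for (j in 0:n) for (i in 0:(m - 1)) {
      k <- k + 1L; geoms[[k]] <- rbind(node_xy(i, j), node_xy(i + 1, j))
    }
    for (i in 0:m) for (j in 0:(n - 1)) {
      k <- k + 1L; geoms[[k]] <- rbind(node_xy(i, j), node_xy(i, j + 1))
    }
    keep <- stats::runif(k) >= cfg$edge_prune_prob
    geoms <- geoms[keep]
    rc <- rep("street", length(geoms))
    nla <- round(cfg$limited_access_fraction * length(geoms))
    if (nla > 0) rc[sample.int(length(geoms), nla)] <- "limited_access_highway"
    street_network(geoms, rc)
  }
  for (try in seq_len(100)) {
    net <- build()
    walk <- net$edges[net$edges$walkable, , drop = FALSE]
    if (nrow(walk) == 0) next
    g <- igraph::graph_from_data_frame(
      data.frame(from = walk$from, to = walk$to), directed = FALSE,
      vertices = data.frame(name = net$nodes$id))
    comp <- igraph::components(g)
    if (max(comp$csize) >= 0.8 * nrow(net$nodes)) return(net)
  }
  stop("could not generate a connected walkable network in 100 attempts")
}

# interior square of block (i, j), inset from the street centerlines
block_rect <- function(cfg, i, j, inset = 5) {
  bs <- cfg$block_size
  x0 <- cfg$origin[1] + i * bs + inset
  y0 <- cfg$origin[2] + j * bs + inset
  x1 <- cfg$origin[1] + (i + 1) * bs - inset
  y1 <- cfg$origin[2] + (j + 1) * bs - inset
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

#' Generate parcels, point features and parks for a city
#'
#' Parcels tile the block interiors with classes drawn from the configured
#' shares; point features fall along streets at Poisson intensities per km of
#' street (with a perpendicular jitter off the centerline); parks occupy
#' random blocks.
#'
#' @param net The city `street_network`.
#' @param cfg A `city_config`.
#' @param seed Integer seed.
#' @return List with `parcels`, `points`, `parks`.
#' @export
generate_features <- function(net, cfg, seed = 1) {
  set.seed(seed + 1L)
  m <- cfg$grid_blocks[1]; n <- cfg$grid_blocks[2]
  bs <- cfg$block_size
  # parcels
  geoms <- list(); luc <- character(0); units <- integer(0)
  for (j in 0:(n - 1)) for (i in 0:(m - 1)) {
    rect <- block_rect(cfg, i, j)
    sub <- switch(as.character(cfg$parcels_per_block),
      "1" = list(rect),
      "2" = {
        xm <- (rect[1, 1] + rect[2, 1]) / 2
        list(rbind(rect[1, ], c(xm, rect[1, 2]), c(xm, rect[3, 2]), rect[4, ]),
             rbind(c(xm, rect[1, 2]), rect[2, ], rect[3, ], c(xm, rect[3, 2])))
      },
      "4" = {
        xm <- (rect[1, 1] + rect[2, 1]) / 2
        ym <- (rect[1, 2] + rect[4, 2]) / 2
        list(rbind(rect[1, ], c(xm, rect[1, 2]), c(xm, ym), c(rect[1, 1], ym)),
             rbind(c(xm, rect[1, 2]), rect[2, ], c(rect[2, 1], ym), c(xm, ym)),
             rbind(c(rect[1, 1], ym), c(xm, ym), c(xm, rect[4, 2]), rect[4, ]),
             rbind(c(xm, ym), c(rect[2, 1], ym), rect[3, ], c(xm, rect[3, 2])))
      })
    for (g in sub) {
      cls <- sample(names(cfg$category_shares), 1, prob = cfg$category_shares)
      geoms[[length(geoms) + 1L]] <- g
      luc <- c(luc, cls)
      units <- c(units, if (cls == "residential")
        stats::rpois(1, cfg$units_per_residential_parcel) else 0L)
    }
  }
  parcels <- parcel_set(geoms, luc, units)
  # point features along streets
  total_km <- sum(net$edges$length) / 1000
  px <- numeric(0); py <- numeric(0); pcls <- character(0)
  for (cls in names(cfg$point_intensity)) {
    npt <- stats::rpois(1, cfg$point_intensity[[cls]] * total_km)
    if (npt == 0) next
    eidx <- sample.int(nrow(net$edges), npt, replace = TRUE,
                       prob = net$edges$length)
    for (e in eidx) {
      g <- net$geoms[[e]]
      s <- stats::runif(1, 0, net$edges$length[e])
      p <- point_along_polyline(g, s)
      d <- g[nrow(g), ] - g[1, ]
      nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
      off <- sample(c(-1, 1), 1) * stats::runif(1, 2, cfg$point_jitter)
      px <- c(px, p[1] + off * nrm[1]); py <- c(py, p[2] + off * nrm[2])
      pcls <- c(pcls, cls)
    }
  }
  points <- point_feature_set(px, py, pcls)
  # block parks
  park_geoms <- list()
  for (j in 0:(n - 1)) for (i in 0:(m - 1)) {
    if (stats::runif(1) < cfg$park_block_prob) {
      scale <- stats::runif(1, 0.5, 1)
      rect <- block_rect(cfg, i, j)
      ctr <- colMeans(rect)
      park_geoms[[length(park_geoms) + 1L]] <-
        t(ctr + t((rect - rep(ctr, each = 4)) * scale))
    }
  }
  parks <- if (length(park_geoms) > 0) park_set(park_geoms) else
    structure(list(features = data.frame(id = integer(0), area = numeric(0)),
                   geoms = list()), class = "park_set")
  list(parcels = parcels, points = points, parks = parks)
}

#' Outcome model configuration
#'
#' Latent-Gaussian outcome generator: for each outcome the linear predictor is
#' `intercept + beta_walkability * z(true walkability) + covariate terms +
#' cluster intercept ~ N(0, sd_cluster^2) + N(0, sd_resid^2)`, mapped to the
#' outcome support by family: `"days"` clamps the rounded predictor to 0-7,
#' `"minutes"` exponentiates a log-scale predictor, `"identity"` returns the
#' predictor unchanged (testing only). Default intercepts are anchored to the
#' pooled outcome means reported for comparable adult cohorts (3 walking days
#' and ~160 min transport walking, ~2 days and ~110 min leisure walking,
#' ~2400 sitting min per week).
#'
#' @param outcomes Named list of per-outcome parameter lists (family,
#'   intercept, beta_walkability, sd_cluster, sd_resid, covariate effects).
#' @return An `outcome_model_config`.
#' @export
outcome_model_config <- function(outcomes = NULL) {
  default <- list(
    walk_transport_days = list(family = "days", intercept = 3.0,
                               beta_walkability = 0.8, sd_cluster = 0.5,
                               sd_resid = 1.8,
                               covariates = c(age = -0.10, male = 0.10,
                                              employed = 0.20)),
    walk_transport_min = list(family = "minutes", intercept = log(160),
                              beta_walkability = 0.30, sd_cluster = 0.15,
                              sd_resid = 0.55,
                              covariates = c(age = -0.02, male = 0.02,
                                             employed = 0.05)),
    walk_leisure_days = list(family = "days", intercept = 1.9,
                             beta_walkability = 0.35, sd_cluster = 0.4,
                             sd_resid = 1.6,
                             covariates = c(age = 0.05, male = -0.05,
                                            employed = 0.0)),
    walk_leisure_min = list(family = "minutes", intercept = log(110),
                            beta_walkability = 0.15, sd_cluster = 0.15,
                            sd_resid = 0.60,
                            covariates = c(age = 0.02, male = -0.02,
                                           employed = 0.0)),
    sitting_min = list(family = "minutes", intercept = log(2400),
                       beta_walkability = -0.08, sd_cluster = 0.06,
                       sd_resid = 0.25,
                       covariates = c(age = 0.0, male = 0.02,
                                      employed = 0.05)))
  if (!is.null(outcomes)) default[names(outcomes)] <- outcomes
  for (o in default) stopifnot(o$sd_cluster >= 0, o$sd_resid >= 0,
                               o$family %in% c("days", "minutes", "identity"))
  structure(list(outcomes = default), class = "outcome_model_config")
}

# crow-fly "true" walkability in a fixed circular window, so that no network
# buffer method is privileged by construction
true_walkability <- function(homes, net, parcels, window = 1000) {
  deg <- node_degrees(net, walkable_only = TRUE)
  ints <- net$nodes[deg >= 3, , drop = FALSE]
  cent <- t(vapply(parcels$geoms, function(g) colMeans(g[[1]]), numeric(2)))
  f <- parcels$features
  win_km2 <- pi * window^2 / 1e6
  vals <- t(vapply(seq_len(nrow(homes)), function(k) {
    hx <- homes[k, 1]; hy <- homes[k, 2]
    near <- (cent[, 1] - hx)^2 + (cent[, 2] - hy)^2 <= window^2
    res <- near & f$land_use_class == "residential"
    rd <- if (any(res) && sum(f$area[res]) > 0)
      sum(f$residential_units[res]) / (sum(f$area[res]) / 1e6) else 0
    A <- vapply(c("residential", "retail", "civic", "recreational"),
                function(cl) sum(f$area[near & f$land_use_class == cl]),
                numeric(1))
    lum <- if (sum(A > 0) <= 1) 0 else {
      p <- A[A > 0] / sum(A); -sum(p * log(p)) / log(4)
    }
    idens <- sum((ints$x - hx)^2 + (ints$y - hy)^2 <= window^2) / win_km2
    c(rd, lum, idens)
  }, numeric(3)))
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  z(vals[, 1]) + z(vals[, 2]) + z(vals[, 3])
}

#' Generate a participant cohort on a synthetic city
#'
#' Homes are placed just off streets of the largest walkable component;
#' recruitment clusters are spatially contiguous (k-means on home
#' coordinates); SES and walkability strata come from median splits of a
#' synthetic SES gradient and of true local walkability measured in a fixed
#' 1 km circular window (so no buffer method is privileged by construction);
#' outcomes follow the latent-Gaussian model of [outcome_model_config()].
#'
#' @param net The city `street_network`.
#' @param features List from [generate_features()].
#' @param n Cohort size.
#' @param n_clusters Number of recruitment clusters (`n >= n_clusters >= 1`).
#' @param outcome_cfg An `outcome_model_config`.
#' @param seed Integer seed.
#' @param city City label written to every row.
#' @param home_setback Range of perpendicular home offsets from the street,
#'   meters.
#' @return A validated participant data.frame (plus a `true_walkability`
#'   attribute used by calibration tests).
#' @export
generate_cohort <- function(net, features, n = 200, n_clusters = 20,
                            outcome_cfg = outcome_model_config(), seed = 1,
                            city = "synthcity", home_setback = c(5, 25)) {
  stopifnot(n >= n_clusters, n_clusters >= 1)
  set.seed(seed + 2L)
  walk <- net$edges[net$edges$walkable, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = walk$from, to = walk$to), directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  comp <- igraph::components(g)
  main_nodes <- which(comp$membership == which.max(comp$csize))
  ok_edges <- which(walk$from %in% main_nodes & walk$to %in% main_nodes)
  eidx <- sample(ok_edges, n, replace = TRUE, prob = walk$length[ok_edges])
  homes <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    e <- eidx[k]
    geom <- net$geoms[[walk$id[e]]]
    p <- point_along_polyline(geom, stats::runif(1, 0, walk$length[e]))
    d <- geom[nrow(geom), ] - geom[1, ]
    nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
    off <- sample(c(-1, 1), 1) * stats::runif(1, home_setback[1], home_setback[2])
    homes[k, ] <- p + off * nrm
  }
  km <- stats::kmeans(homes, centers = min(n_clusters, n), nstart = 5)
  cluster_id <- paste0("c", km$cluster)
  wscore <- true_walkability(homes, net, features$parcels)
  ses_score <- (homes[, 1] - min(homes[, 1])) /
    max(1e-9, diff(range(homes[, 1]))) + stats::rnorm(n, 0, 0.2)
  walk_str <- ifelse(wscore > stats::median(wscore), "high", "low")
  ses_str <- ifelse(ses_score > stats::median(ses_score), "high", "low")
  age <- pmin(66, pmax(18, round(stats::rnorm(n, 42, 12))))
  gender <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.53, 0.47))
  education <- sample(EDUCATION_LEVELS, n, replace = TRUE,
                      prob = c(0.11, 0.42, 0.47))
  marital <- sample(c("married_or_partner", "other"), n, replace = TRUE,
                    prob = c(0.59, 0.41))
  employment <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.78, 0.22))
  zw <- if (stats::sd(wscore) > 0) (wscore - mean(wscore)) / stats::sd(wscore)
        else wscore * 0
  df <- data.frame(id = seq_len(n), x = homes[, 1], y = homes[, 2],
                   age = age, gender = gender, education = education,
                   marital = marital, employment = employment,
                   cluster_id = cluster_id, ses_stratum = ses_str,
                   walkability_stratum = walk_str, city = city,
                   stringsAsFactors = FALSE)
  families <- character(0)
  for (nm in names(outcome_cfg$outcomes)) {
    oc <- outcome_cfg$outcomes[[nm]]
    families <- c(families, oc$family)
    cl_eff <- stats::rnorm(max(km$cluster), 0, oc$sd_cluster)
    lp <- oc$intercept + oc$beta_walkability * zw +
      oc$covariates[["age"]] * (age - 42) / 10 +
      oc$covariates[["male"]] * (gender == "male") +
      oc$covariates[["employed"]] * (employment == "yes") +
      cl_eff[km$cluster] + stats::rnorm(n, 0, oc$sd_resid)
    df[[nm]] <- switch(oc$family,
                       days = pmin(7, pmax(0, round(lp))),
                       minutes = exp(lp),
                       identity = lp)
  }
  if (all(families %in% c("days", "minutes"))) validate_participants(df)
  attr(df, "true_walkability") <- wscore
  df
}

#' Generate a complete synthetic city dataset
#'
#' Runs [generate_network()], [generate_features()] and [generate_cohort()]
#' under one seed.
#'
#' @param cfg A `city_config`.
#' @param n,n_clusters Cohort size and cluster count.
#' @param outcome_cfg An `outcome_model_config`.
#' @param seed Integer seed.
#' @return List with `net`, `parcels`, `points`, `parks`, `participants`.
#' @export
generate_city <- function(cfg = city_config(), n = 200, n_clusters = 20,
                          outcome_cfg = outcome_model_config(), seed = 1) {
  net <- generate_network(cfg, seed)
  feats <- generate_features(net, cfg, seed)
  participants <- generate_cohort(net, feats, n = n, n_clusters = n_clusters,
                                  outcome_cfg = outcome_cfg, seed = seed)
  list(net = net, parcels = feats$parcels, points = feats$points,
       parks = feats$parks, participants = participants)
}

#' Write a synthetic city dataset to a directory
#'
#' Emits `network.geojson`, `parcels.geojson`, `points.geojson`,
#' `parks.geojson` and `participants.csv`, all loadable by the corresponding
#' `load_*` functions.
#'
#' @param city List from [generate_city()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_geojson(city$net, file.path(dir, "network.geojson"))
  write_features_geojson(city$parcels, file.path(dir, "parcels.geojson"))
  write_features_geojson(city$points, file.path(dir, "points.geojson"))
  write_features_geojson(city$parks, file.path(dir, "parks.geojson"))
  write_participants(city$participants, file.path(dir, "participants.csv"))
  invisible(dir)
}
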