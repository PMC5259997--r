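# Config-driven orchestration of the full workflow: snap -> reach -> three
# buffers -> BEM table -> paired BEM comparisons -> association models per
# stratum -> coefficient z tests -> agreement tables, with a manifest that
# makes reruns reproducible and byte-identical under a fixed seed.

#' Assemble a pipeline run configuration
#'
#' Either `inputs` (paths to network/parcels/points/parks GeoJSON and a
#' participant CSV) or `synth` (synthetic-city settings) must be provided.
#'
#' @param inputs Named list of paths: `network`, `parcels`, `points`, `parks`,
#'   `participants`.
#' @param synth Named list: arguments of [city_config()] under `city`, plus
#'   `n_participants` (or `n`) and `n_clusters`.
#' @param seed Integer seed used for every source of randomness.
#' @param trims Trim distances to run (meters).
#' @param report_trim Trim used for the reported comparisons (default the
#'   smallest trim).
#' @param methods Buffer methods (>= 2 required for comparisons).
#' @param method_pairs List of method pairs to compare; defaults to sausage
#'   vs detailed-trimmed and sausage vs detailed.
#' @param snapped Snap point features to the network before counting.
#' @param resolution Buffer grid cell size, meters.
#' @param closing_radius,closing_radius_dt Surrogate closing radii (NULL =
#'   method defaults).
#' @param strata `"pooled"`, `"city"` or `"quadrant"`.
#' @param alpha Significance level for agreement tabulation.
#' @param cutoff Network distance cutoff, meters.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(inputs = NULL, synth = NULL, seed = 1, trims = 25,
                            report_trim = NULL, methods = BUFFER_METHODS,
                            method_pairs = list(c("sausage", "detailed_trimmed"),
                                                c("sausage", "detailed")),
                            snapped = TRUE, resolution = 2,
                            closing_radius = NULL, closing_radius_dt = NULL,
                            strata = c("pooled", "city", "quadrant"),
                            alpha = 0.05, cutoff = 1000, out_dir = "bufcomp_out") {
  strata <- match.arg(strata)
  if (is.null(inputs) && is.null(synth))
    stop("config needs either `inputs` or `synth`")
  if (length(methods) < 2)
    stop("comparison requires at least two buffer methods")
  if (!all(unlist(method_pairs) %in% methods))
    stop("method_pairs refer to methods not being run")
  if (any(trims <= 0)) stop("trims must be positive")
  structure(list(inputs = inputs, synth = synth, seed = seed, trims = trims,
                 report_trim = report_trim %||% min(trims), methods = methods,
                 method_pairs = method_pairs, snapped = snapped,
                 resolution = resolution, closing_radius = closing_radius,
                 closing_radius_dt = closing_radius_dt, strata = strata,
                 alpha = alpha, cutoff = cutoff, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file; top-level keys are [pipeline_config()] arguments.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$method_pairs))
    raw$method_pairs <- lapply(seq_len(NROW(raw$method_pairs)), function(i)
      unlist(raw$method_pairs[i][[1]] %||% raw$method_pairs[i, ]))
  do.call(pipeline_config, raw)
}

model_covariates <- function(participants) {
  data.frame(age = participants$age,
             gender = factor(participants$gender),
             education = factor(participants$education, levels = EDUCATION_LEVELS),
             marital = factor(participants$marital),
             employment = factor(participants$employment),
             ses_stratum = factor(participants$ses_stratum),
             walkability_stratum = factor(participants$walkability_stratum))
}

drop_constant_columns <- function(df) {
  keep <- vapply(df, function(col) length(unique(col)) >= 2, logical(1))
  df[, keep, drop = FALSE]
}

stratum_labels <- function(participants, strata) {
  switch(strata,
         pooled = rep("pooled", nrow(participants)),
         city = participants$city,
         quadrant = {
           if (any(is.na(participants$ses_stratum)) ||
               any(is.na(participants$walkability_stratum)))
             stop("quadrant stratification requires ses and walkability strata")
           paste0("ses_", participants$ses_stratum, "/walk_",
                  participants$walkability_stratum)
         })
}

#' Run the full buffer-comparison pipeline
#'
#' Executes every stage on loaded or synthesized inputs and writes tidy CSV
#' results plus a JSON manifest to the configured output directory. Reruns
#' with the same config and seed produce byte-identical outputs.
#'
#' @param config A `run_config` from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML/JSON config.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `manifest`, `bem`, `ttests`, `fits`,
#'   `comparisons`, `agreement`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[bufcomp] ", sprintf(...))
  set.seed(config$seed)

  # ---- stage: inputs -------------------------------------------------------
  if (!is.null(config$synth)) {
    s <- config$synth
    cfg <- do.call(city_config, s$city %||% list())
    city <- generate_city(cfg, n = s$n_participants %||% s$n %||% 200,
                          n_clusters = s$n_clusters %||% 20,
                          seed = config$seed)
    net <- city$net; parcels <- city$parcels; points <- city$points
    parks <- city$parks; participants <- city$participants
    say("synthesized city: %d nodes, %d edges, %d participants",
        nrow(net$nodes), nrow(net$edges), nrow(participants))
  } else {
    net <- load_network(config$inputs$network)
    parcels <- load_parcels(config$inputs$parcels)
    points <- load_points(config$inputs$points)
    parks <- load_parks(config$inputs$parks)
    participants <- load_participants(config$inputs$participants)
    say("loaded inputs: %d edges, %d parcels, %d points, %d parks, %d participants",
        nrow(net$edges), nrow(parcels$features), nrow(points),
        nrow(parks$features), nrow(participants))
  }
  if (config$strata == "quadrant") stratum_labels(participants, "quadrant")
  wnet <- filter_walkable(net)

  # ---- stage: buffers + BEMs ----------------------------------------------
  extra <- list()
  if (!is.null(config$closing_radius)) extra$closing_radius <- config$closing_radius
  if (!is.null(config$closing_radius_dt)) extra$closing_radius_dt <- config$closing_radius_dt
  bem <- do.call(compute_bem_table,
                 c(list(participants = participants, net = wnet,
                        parcels = parcels, points = points, parks = parks,
                        methods = config$methods, trims = config$trims,
                        cutoff = config$cutoff, snapped = config$snapped,
                        resolution = config$resolution), extra))
  say("BEM table: %d rows", nrow(bem))

  # ---- stage: paired BEM comparisons --------------------------------------
  rt <- config$report_trim
  ttests <- list()
  for (pair in config$method_pairs) {
    b1 <- bem[bem$method == pair[1] & bem$trim == rt, ]
    b2 <- bem[bem$method == pair[2] & bem$trim == rt, ]
    b2 <- b2[match(b1$participant_id, b2$participant_id), ]
    for (col in BEM_COLUMNS) {
      tt <- paired_ttest(b1[[col]], b2[[col]])
      ttests[[length(ttests) + 1L]] <- data.frame(
        bem_name = col, method_1 = pair[1], method_2 = pair[2], trim = rt,
        n = nrow(b1), t = tt$t, df = tt$df, p = tt$p,
        mse = mse(b1[[col]], b2[[col]]), status = tt$status,
        stringsAsFactors = FALSE)
    }
  }
  ttests <- do.call(rbind, ttests)
  say("paired BEM tests: %d rows", nrow(ttests))

  # ---- stage: association models ------------------------------------------
  labels <- stratum_labels(participants, config$strata)
  covars <- model_covariates(participants)
  fits <- list()
  skipped <- 0L
  for (lab in unique(labels)) {
    sel <- labels == lab
    part_s <- participants[sel, ]
    cov_s <- drop_constant_columns(covars[sel, , drop = FALSE])
    if (length(unique(part_s$cluster_id)) < 2) {
      say("stratum %s skipped: fewer than 2 clusters", lab)
      next
    }
    for (m in config$methods) {
      bm <- bem[bem$method == m & bem$trim == rt, ]
      bm <- bm[match(part_s$id, bm$participant_id), ]
      for (bcol in BEM_COLUMNS) {
        if (stats::sd(bm[[bcol]]) == 0) next  # constant BEM in this stratum
        for (ocol in OUTCOME_COLUMNS) {
          f <- fit_association(part_s[[ocol]], bm[[bcol]], cov_s,
                               part_s$cluster_id, term = "linear",
                               outcome_name = ocol, bem_name = bcol,
                               method = m, trim = rt, stratum = lab)
          if (!f$converged) skipped <- skipped + 1L
          fits[[length(fits) + 1L]] <- f
        }
      }
    }
  }
  say("association fits: %d (%d non-converged)", length(fits), skipped)

  # ---- stage: coefficient comparisons -------------------------------------
  fkey <- vapply(fits, function(f)
    paste(f$stratum, f$bem_name, f$outcome_name, f$method, sep = "|"),
    character(1))
  comparisons <- list()
  for (pair in config$method_pairs) {
    for (lab in unique(labels)) {
      for (bcol in BEM_COLUMNS) for (ocol in OUTCOME_COLUMNS) {
        i1 <- match(paste(lab, bcol, ocol, pair[1], sep = "|"), fkey)
        i2 <- match(paste(lab, bcol, ocol, pair[2], sep = "|"), fkey)
        if (is.na(i1) || is.na(i2)) next
        if (!fits[[i1]]$converged || !fits[[i2]]$converged) {
          say("comparison skipped (non-converged): %s %s %s", lab, bcol, ocol)
          next
        }
        comparisons[[length(comparisons) + 1L]] <-
          compare_coefficients(fits[[i1]], fits[[i2]], alpha = config$alpha)
      }
    }
  }
  cmp_df <- comparisons_to_df(comparisons)
  agreement <- tabulate_agreement(cmp_df)
  say("coefficient comparisons: %d; differing in significance: %d",
      nrow(cmp_df), sum(agreement$n_differing))

  # ---- stage: outputs ------------------------------------------------------
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fits_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(stratum = f$stratum, outcome_name = f$outcome_name,
               bem_name = f$bem_name, method = f$method, trim = f$trim,
               b = f$b, se = f$se, p = f$p, n = f$n, converged = f$converged,
               stringsAsFactors = FALSE)))
  paths <- list(bem = "bem_table.csv", ttests = "bem_pair_tests.csv",
                fits = "association_fits.csv",
                comparisons = "coef_comparisons.csv",
                agreement = "agreement.csv")
  objs <- list(bem = bem, ttests = ttests, fits = fits_df,
               comparisons = cmp_df, agreement = agreement)
  for (nm in names(paths))
    utils::write.csv(objs[[nm]], file.path(config$out_dir, paths[[nm]]),
                     row.names = FALSE)
  jsonlite::write_json(
    list(agreement = agreement,
         by_outcome = lapply(split(cmp_df, cmp_df$outcome_name), function(g)
           list(n_pairs = nrow(g),
                n_any_significant = sum(g$status != "neither"),
                n_differing = sum(g$status %in% c("only_method_1",
                                                  "only_method_2"))))),
    file.path(config$out_dir, "agreement.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_plain <- unclass(config)
  cfg_plain$out_dir <- NULL  # run location must not change the config hash
  cfg_file <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bufcomp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stage_rows = list(participants = nrow(participants), bem = nrow(bem),
                      bem_pair_tests = nrow(ttests),
                      association_fits = nrow(fits_df),
                      non_converged = skipped,
                      coef_comparisons = nrow(cmp_df)),
    outputs = paths)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote results to %s", config$out_dir)
  invisible(list(manifest = manifest, bem = bem, ttests = ttests,
                 fits = fits_df, comparisons = cmp_df, agreement = agreement))
}
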