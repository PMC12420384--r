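pipeline_defaults <- function() {
  list(
    seed = 1,
    stages = c("simulate", "features", "fit", "sensitivity", "scaling",
               "gdm"),
    landscape = list(extent_km = c(40, 40), pixel_size_km = 2,
                     n_regions = 4, n_topo_units = 3, seed = NULL),
    species = list(n_species = 30, n_families = 10, endemic_fraction = 0.4,
                   seed = NULL),
    design = list(n_clusters = 20, points_per_cluster = 3, n_visits = 4,
                  n_observers = 3, seed = NULL),
    occupancy = list(method = "map", chains = 2, warmup = 150, iter = 150,
                     n_predict_draws = 1, seed = NULL),
    sensitivity = list(threshold = 0.2, quantiles = c(0.25, 0.5, 0.75),
                       n_sequences = 50, n_draws = NULL, seed = NULL),
    scaling = list(areas = c(290, 860, 2600), threshold = 0.2,
                   quantile = 0.5, seed = NULL),
    gdm = list(response = "sorensen", n_boot = 50,
               detection_corrected = FALSE, seed = NULL)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills documented defaults, checks
#' types and cross-field constraints, and reports every violation at once.
#' Omitted stage seeds are filled from the top-level seed with a warning.
#'
#' @param config path to a YAML file, or a (possibly partial) configuration
#'   list.
#' @return a normalized configuration list of class `msom_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list")
  def <- pipeline_defaults()
  errors <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    errors <- c(errors, paste("unknown config key(s):",
                              paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), names(def))) {
    if (is.list(def[[sec]]) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad) > 0)
        errors <- c(errors, paste0("unknown key(s) in '", sec, "': ",
                                   paste(bad, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])

  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(cfg$sensitivity$threshold > 0 && cfg$sensitivity$threshold < 1,
      "sensitivity$threshold must lie in (0, 1)")
  chk(cfg$scaling$threshold > 0 && cfg$scaling$threshold < 1,
      "scaling$threshold must lie in (0, 1)")
  chk(all(diff(cfg$scaling$areas) > 0),
      "scaling$areas must be strictly increasing")
  chk(all(cfg$sensitivity$quantiles > 0 & cfg$sensitivity$quantiles < 1),
      "sensitivity$quantiles must lie in (0, 1)")
  chk(cfg$landscape$n_regions >= 1, "landscape$n_regions must be >= 1")
  chk(all(cfg$landscape$extent_km %% cfg$landscape$pixel_size_km == 0),
      "landscape$extent_km must be divisible by pixel_size_km")
  chk(cfg$occupancy$method %in% c("map", "mcmc"),
      "occupancy$method must be 'map' or 'mcmc'")
  chk(cfg$gdm$response %in% c("sorensen", "simpson"),
      "gdm$response must be 'sorensen' or 'simpson'")
  chk(all(cfg$stages %in% def$stages),
      paste("stages must be among:", paste(def$stages, collapse = ", ")))
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)

  filled <- character(0)
  for (sec in c("landscape", "species", "design", "occupancy",
                "sensitivity", "scaling", "gdm")) {
    if (is.null(cfg[[sec]]$seed)) {
      cfg[[sec]]$seed <- cfg$seed
      filled <- c(filled, sec)
    }
  }
  if (length(filled) > 0)
    warning("seed(s) filled from top-level seed for: ",
            paste(filled, collapse = ", "))
  class(cfg) <- "msom_config"
  cfg
}

write_stage <- function(manifest, stage, file, writer, seed, t0) {
  writer(file)
  rbind(manifest, data.frame(
    stage = stage, file = basename(file),
    md5 = unname(tools::md5sum(file)), seed = seed,
    runtime_s = round(as.numeric(Sys.time()) - t0, 3)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- synthetic data, biogeographic
#' features, occupancy fit and prediction, sensitivity metrics, hexagon
#' scaling, GDM -- writing plain-text artifacts and a manifest (stage, file,
#' content hash, seed, runtime) to `out_dir`. Re-running with an identical
#' configuration reproduces identical artifact hashes.
#'
#' @param config an `msom_config` (or anything [validate_config()] accepts).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest data.frame (also written as
#'   manifest.csv).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("msom_run_")) {
  cfg <- if (inherits(config, "msom_config")) config else
    suppressWarnings(validate_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- NULL
  stages <- cfg$stages
  need <- function(stage, what, obj) {
    if (is.null(obj))
      stop("stage '", stage, "' needs upstream artifact '", what,
           "' but its stage is disabled")
  }
  landscape <- pool <- design <- truth <- detections <- NULL
  features <- fit <- cube <- NULL

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    landscape <- do.call(make_landscape, cfg$landscape)
    pool <- make_species_pool(landscape,
                              n_species = cfg$species$n_species,
                              n_families = cfg$species$n_families,
                              endemic_fraction = cfg$species$endemic_fraction,
                              seed = cfg$species$seed)
    design <- make_sampling_design(
      landscape, n_clusters = cfg$design$n_clusters,
      points_per_cluster = cfg$design$points_per_cluster,
      n_visits = cfg$design$n_visits,
      n_observers = cfg$design$n_observers, seed = cfg$design$seed)
    truth <- simulate_truth(landscape, pool, design,
                            seed = cfg$species$seed)
    detections <- simulate_detections(truth, design, pool,
                                      seed = cfg$design$seed)
    man <- write_stage(man, "simulate", file.path(out_dir, "landscape.csv"),
                       function(f) write.csv(landscape$pixels, f,
                                             row.names = FALSE),
                       cfg$landscape$seed, t0)
    man <- write_stage(man, "simulate",
                       file.path(out_dir, "species_pool.json"),
                       function(f) jsonlite::write_json(
                         list(species = pool$species,
                              traits = as.data.frame(pool$traits),
                              ranges = pool$ranges), f, digits = NA),
                       cfg$species$seed, t0)
    man <- write_stage(man, "simulate", file.path(out_dir, "design.csv"),
                       function(f) write.csv(design$points, f,
                                             row.names = FALSE),
                       cfg$design$seed, t0)
    man <- write_stage(man, "simulate", file.path(out_dir, "detections.csv"),
                       function(f) write.csv(as.data.frame(detections), f,
                                             row.names = FALSE),
                       cfg$design$seed, t0)
    man <- write_stage(man, "simulate",
                       file.path(out_dir, "truth_params.json"),
                       function(f) jsonlite::write_json(truth$params, f,
                                                        digits = NA),
                       cfg$species$seed, t0)
  }
  if ("features" %in% stages) {
    t0 <- as.numeric(Sys.time())
    for (o in c("landscape", "pool", "design", "detections"))
      need("features", o, get(o))
    features <- clip_pairs(species_point_features(design$points, pool,
                                                  landscape))
    pairs <- site_pair_table(design$points, landscape)
    man <- write_stage(man, "features", file.path(out_dir, "features.csv"),
                       function(f) write.csv(features, f, row.names = FALSE),
                       cfg$landscape$seed, t0)
    man <- write_stage(man, "features", file.path(out_dir, "pairs.csv"),
                       function(f) write.csv(pairs, f, row.names = FALSE),
                       cfg$landscape$seed, t0)
  }
  if ("fit" %in% stages) {
    t0 <- as.numeric(Sys.time())
    for (o in c("detections", "features", "pool", "design"))
      need("fit", o, get(o))
    fit <- fit_occupancy(detections, features, pool, design,
                         method = cfg$occupancy$method,
                         chains = cfg$occupancy$chains,
                         warmup = cfg$occupancy$warmup,
                         iter = cfg$occupancy$iter,
                         seed = cfg$occupancy$seed)
    nd <- min(cfg$occupancy$n_predict_draws, nrow(fit$draws))
    cube <- predict_occupancy(fit, landscape, pool,
                              draw_ids = seq_len(nd),
                              seed = cfg$occupancy$seed)
    man <- write_stage(man, "fit", file.path(out_dir, "draws.csv"),
                       function(f) write.csv(fit$draws, f,
                                             row.names = FALSE),
                       cfg$occupancy$seed, t0)
    man <- write_stage(man, "fit", file.path(out_dir, "occupancy_cube.csv"),
                       function(f) {
                         d <- dim(cube)
                         long <- data.frame(
                           species = rep(seq_len(d[1]), d[2] * 2 * d[4]),
                           pixel = rep(rep(seq_len(d[2]), each = d[1]),
                                       2 * d[4]),
                           scenario = rep(rep(c("forest", "pasture"),
                                              each = d[1] * d[2]), d[4]),
                           draw = rep(seq_len(d[4]), each = d[1] * d[2] * 2),
                           psi = as.numeric(cube))
                         write.csv(long, f, row.names = FALSE)
                       }, cfg$occupancy$seed, t0)
  }
  if ("sensitivity" %in% stages) {
    t0 <- as.numeric(Sys.time())
    need("sensitivity", "cube", cube)
    regions <- cube_pixel_info(cube)$region_id
    nd <- cfg$sensitivity$n_draws %||% n_draws(cube)
    nd <- min(nd, n_draws(cube))
    rel <- do.call(rbind, lapply(cfg$sensitivity$quantiles, function(qq)
      regional_relative_sensitivity(cube, regions,
                                    tau = cfg$sensitivity$threshold,
                                    q = qq, draws = seq_len(nd))))
    traj <- pooling_trajectory(cube, regions,
                               tau = cfg$sensitivity$threshold, q = 0.5,
                               n_sequences = cfg$sensitivity$n_sequences,
                               draws = seq_len(nd),
                               seed = cfg$sensitivity$seed)
    man <- write_stage(man, "sensitivity",
                       file.path(out_dir, "regional_ratios.csv"),
                       function(f) write.csv(rel, f, row.names = FALSE),
                       cfg$sensitivity$seed, t0)
    man <- write_stage(man, "sensitivity",
                       file.path(out_dir, "trajectory.csv"),
                       function(f) write.csv(traj$summary, f,
                                             row.names = FALSE),
                       cfg$sensitivity$seed, t0)
  }
  if ("scaling" %in% stages) {
    t0 <- as.numeric(Sys.time())
    need("scaling", "cube", cube)
    rec <- hex_scaling_records(cube, landscape, areas = cfg$scaling$areas,
                               tau = cfg$scaling$threshold,
                               q = cfg$scaling$quantile,
                               seed = cfg$scaling$seed)
    man <- write_stage(man, "scaling", file.path(out_dir, "scaling.csv"),
                       function(f) write.csv(rec, f, row.names = FALSE),
                       cfg$scaling$seed, t0)
    if (!is.null(rec) && length(unique(rec$draw)) >= 1 && nrow(rec) >= 3) {
      reg <- fit_scaling_regression(rec)
      man <- write_stage(man, "scaling",
                         file.path(out_dir, "regression.csv"),
                         function(f) write.csv(reg$coefs, f,
                                               row.names = FALSE),
                         cfg$scaling$seed, t0)
    }
  }
  if ("gdm" %in% stages) {
    t0 <- as.numeric(Sys.time())
    for (o in c("detections", "design")) need("gdm", o, get(o))
    fits <- list()
    for (stratum in c("forest", "pasture")) {
      pts <- design$points[design$points$land_use == stratum, ]
      det_s <- detections[detections$point_id %in% pts$point_id, ]
      comm <- with(det_s, tapply(y, list(point_id, species_id), max))
      comm[is.na(comm)] <- 0
      pt_ids <- as.integer(rownames(comm))
      dis <- pair_dissimilarities(comm, pt_ids)
      pr <- site_pair_table(pts[match(pt_ids, pts$point_id), ], landscape)
      g <- fit_gdm(dis[[cfg$gdm$response]],
                   pred_pair = list(geo_km = pr$geo_km,
                                    valley_m = pr$valley_m,
                                    mountain_m = pr$mountain_m),
                   pred_site = list(elev = cbind(pr$elev_i, pr$elev_j),
                                    precip = cbind(pr$precip_i,
                                                   pr$precip_j)))
      fits[[stratum]] <- list(alpha0 = g$alpha0, coefs = g$coefs,
                              knots = g$knots, rms = g$rms)
    }
    man <- write_stage(man, "gdm", file.path(out_dir, "gdm_fits.json"),
                       function(f) jsonlite::write_json(fits, f,
                                                        digits = NA),
                       cfg$gdm$seed, t0)
  }
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
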