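#' Pipeline configuration
#'
#' All tunables of the segmentation pipeline in one nested list, with the
#' operating defaults: 3-class intensity k-means with 8 restarts, closing
#' disc of 3 px, snake weights (0.1, 0.6, 0.3) with 50 control points, and
#' aggregation over the 20 middle slices.
#'
#' @param kmeans list: `restarts`, `tol`.
#' @param morphology list: `closing_radius_px`, `density_sigma`.
#' @param snake list passed to [snake_config()] (`alpha`, `beta`, `gamma`,
#'   `n_points`, `search_window_px`, `max_iter`, `move_tol`,
#'   `field_sigma`).
#' @param compartments list: `n_middle`, `min_muscle_area_frac`,
#'   `touch_dist_px`, `bridge_occupancy`, `band_depth_px`.
#' @param seed integer seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(kmeans = list(), morphology = list(),
                            snake = list(), compartments = list(),
                            seed = 1L) {
  defaults <- list(
    kmeans = list(restarts = 8L, tol = 1e-8),
    morphology = list(closing_radius_px = 3L, density_sigma = 4),
    snake = list(alpha = 0.1, beta = 0.6, gamma = 0.3, n_points = 50L,
                 search_window_px = 7L, max_iter = 500L, move_tol = 0.02,
                 field_sigma = 3),
    compartments = list(n_middle = 20L, min_muscle_area_frac = 0.2,
                        touch_dist_px = 1.5, bridge_occupancy = 0.75,
                        band_depth_px = 3L),
    seed = 1L
  )
  merge_section <- function(name, user) {
    d <- defaults[[name]]
    unknown <- setdiff(names(user), names(d))
    if (length(unknown)) {
      stop("unknown config key(s) in '", name, "': ", paste(unknown, collapse = ", "))
    }
    utils::modifyList(d, user)
  }
  cfg <- list(kmeans = merge_section("kmeans", kmeans),
              morphology = merge_section("morphology", morphology),
              snake = merge_section("snake", snake),
              compartments = merge_section("compartments", compartments),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected, so a round trip through
#' [write_pipeline_config()] and [read_pipeline_config()] is lossless.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("kmeans", "morphology", "snake", "compartments", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  pipeline_config(kmeans = raw$kmeans %||% list(),
                  morphology = raw$morphology %||% list(),
                  snake = raw$snake %||% list(),
                  compartments = raw$compartments %||% list(),
                  seed = raw$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

snake_config_from <- function(cfg) {
  do.call(snake_config, cfg$snake)
}

#' Segment one slice
#'
#' Runs the per-slice stages in order: intensity k-means, tissue
#' assignment, morphological cleanup, limb and muscle snakes, bone
#' detection, compartment partition (on the raw clustering, as the
#' IMAT/muscle separation must be), fat fraction and failure heuristics.
#'
#' @param slice numeric intensity matrix.
#' @param config a [pipeline_config()].
#' @param seed seed for this slice's k-means restarts.
#' @return list with `fraction` (NA on failure), `flags`, `tmap_raw`,
#'   `tmap_clean`, `contours`, `bone`, `masks`.
#' @export
segment_slice <- function(slice, config = pipeline_config(),
                          seed = config$seed) {
  tmap_raw <- cluster_slice(slice, n_restarts = config$kmeans$restarts,
                            seed = seed, tol = config$kmeans$tol)
  tmap_clean <- clean_tissue_map(tmap_raw, config$morphology$closing_radius_px)
  sc <- snake_config_from(config)
  fit <- fit_limb_and_muscle_contours(tmap_clean, sc,
                                      density_sigma = config$morphology$density_sigma)
  if (isTRUE(fit$failure) || is.null(fit$limb) || is.null(fit$muscle)) {
    return(list(fraction = NA_real_,
                flags = unique(c("segmentation failure", fit$reasons)),
                tmap_raw = tmap_raw, tmap_clean = tmap_clean,
                contours = fit, bone = NULL, masks = NULL))
  }
  bone <- suppressWarnings(detect_bone(tmap_raw, fit$muscle))
  masks <- tryCatch(
    partition_compartments(tmap_raw, fit$limb, fit$muscle, bone),
    error = function(e) e
  )
  if (inherits(masks, "error")) {
    return(list(fraction = NA_real_,
                flags = c("segmentation failure", conditionMessage(masks)),
                tmap_raw = tmap_raw, tmap_clean = tmap_clean,
                contours = fit, bone = bone, masks = NULL))
  }
  cc <- config$compartments
  fl <- flag_failure(masks, tmap_raw,
                     min_muscle_area_frac = cc$min_muscle_area_frac,
                     touch_dist_px = cc$touch_dist_px,
                     bridge_occupancy = cc$bridge_occupancy,
                     band_depth_px = cc$band_depth_px)
  fraction <- tryCatch(fat_fraction(masks), error = function(e) NA_real_)
  list(fraction = fraction, flags = fl$reasons, tmap_raw = tmap_raw,
       tmap_clean = tmap_clean, contours = fit, bone = bone, masks = masks)
}

#' Run the full segmentation pipeline on a volume
#'
#' Applies [segment_slice()] to every slice (each slice is clustered
#' independently), aggregates the intramuscular fat fraction over the
#' middle slices, and optionally writes artifacts: compartment label maps
#' (NIfTI), contours (CSV), per-slice results (CSV) and a JSON run
#' manifest recording the configuration, seed and package version.
#'
#' @param input an [image_volume()], a 2-D slice matrix, or a path
#'   readable by [read_volume()].
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for artifacts; created if needed.
#'   Existing result files are not overwritten unless `force = TRUE`.
#' @param force overwrite existing artifacts.
#' @return a `fat_fraction_result` with, as attribute `"slices"`, the
#'   per-slice stage outputs.
#' @export
run_pipeline <- function(input, config = pipeline_config(), output_dir = NULL,
                         force = FALSE) {
  vol <- if (is.character(input)) read_volume(input)
         else if (is.matrix(input)) image_volume(input)
         else input
  stopifnot(inherits(vol, "image_volume"))
  ns <- n_slices(vol)
  slices <- vector("list", ns)
  fractions <- rep(NA_real_, ns)
  flags <- vector("list", ns)
  for (z in seq_len(ns)) {
    # decorrelate restart seeds across slices, reproducibly
    s <- segment_slice(get_slice(vol, z), config,
                       seed = (config$seed + 997L * z) %% .Machine$integer.max)
    slices[[z]] <- s
    fractions[z] <- s$fraction
    flags[[z]] <- s$flags
  }
  res <- fat_fraction_result(fractions, flags, source = "automatic")
  res <- tryCatch(aggregate_fraction(res, config$compartments$n_middle),
                  error = function(e) { res$warnings <- conditionMessage(e); res })

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    res_path <- file.path(output_dir, "results.csv")
    if (file.exists(res_path) && !force) {
      stop("output exists (use force = TRUE to overwrite): ", res_path)
    }
    utils::write.csv(
      data.frame(slice = seq_len(ns), fat_fraction = fractions,
                 flagged = vapply(flags, function(f) length(f) > 0, TRUE),
                 flags = vapply(flags, paste, "", collapse = "; "),
                 used = seq_len(ns) %in% res$slices_used),
      res_path, row.names = FALSE)
    cms <- lapply(slices, function(s) {
      if (is.null(s$masks)) matrix(NA_integer_, dim(vol$data)[1], dim(vol$data)[2])
      else matrix(as.integer(s$masks), nrow(s$masks), ncol(s$masks))
    })
    write_volume(array(unlist(cms), dim = dim(vol$data)),
                 file.path(output_dir, "compartments.nii.gz"),
                 pixel_spacing = vol$pixel_spacing)
    conts <- lapply(slices, function(s) {
      if (is.null(s$contours$limb)) list()
      else list(limb = s$contours$limb$points, muscle = s$contours$muscle$points)
    })
    write_contours_csv(conts, file.path(output_dir, "contours.csv"))
    manifest <- list(
      package = "musclefat",
      version = as.character(utils::packageVersion("musclefat")),
      seed = config$seed,
      config = unclass(config),
      n_slices = ns,
      aggregate_fraction = res$aggregate,
      flagged_slices = which(vapply(flags, function(f) length(f) > 0, TRUE))
    )
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  attr(res, "slices") <- slices
  res
}
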