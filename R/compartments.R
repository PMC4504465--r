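#' Compartment codes
#'
#' Per-pixel compartments of a partitioned slice. `outside` collects
#' everything that is not quantified tissue: pixels beyond the limb
#' contour, the skin rim, and unclassified dark pixels between the
#' boundaries.
#'
#' @format named integer vector.
#' @export
compartment_codes <- c(outside = 0L, SAT = 1L, IMAT = 2L, muscle = 3L, bone = 4L)

contour_points <- function(x) {
  if (inherits(x, "snake_contour")) x$points else x
}

#' Detect the femur (cortical bone + marrow) inside the muscle contour
#'
#' Bone shares the dark intensity cluster with the background; it is
#' recovered as a connected dark component lying inside the muscle contour
#' whose filled hull contains a bright marrow core (fat-class pixels). The
#' returned mask is the filled component, i.e. cortical shell plus marrow,
#' so marrow is never counted as intramuscular fat downstream.
#'
#' @param tmap raw `tissue_map` of the slice.
#' @param muscle_contour muscle boundary (`snake_contour` or vertex
#'   matrix).
#' @param min_area smallest candidate component, px.
#' @return logical bone mask; empty (with a warning) when no candidate
#'   dark component with a marrow core exists.
#' @export
detect_bone <- function(tmap, muscle_contour, min_area = 20L) {
  stopifnot(inherits(tmap, "tissue_map"))
  lab <- matrix(as.integer(tmap), nrow(tmap), ncol(tmap))
  inside <- rasterize_polygon(contour_points(muscle_contour), dim(lab))
  dark_in <- (lab == tissue_classes[["background_bone_vessel"]]) & inside
  empty <- matrix(FALSE, nrow(lab), ncol(lab))
  if (!any(dark_in)) {
    warning("no bone candidate inside the muscle contour")
    return(empty)
  }
  comps <- EBImage::bwlabel(dark_in)
  sizes <- tabulate(comps[comps > 0])
  best <- empty
  best_size <- 0
  for (cid in which(sizes >= min_area)) {
    filled <- EBImage::fillHull(comps == cid) > 0
    core <- filled & (lab == tissue_classes[["fat"]])
    if (any(core) && sizes[cid] > best_size) {
      best <- filled
      best_size <- sizes[cid]
    }
  }
  if (best_size == 0) {
    warning("no bone candidate with a marrow core inside the muscle contour")
    return(empty)
  }
  best
}

#' Partition a slice into SAT / IMAT / muscle / bone compartments
#'
#' Uses the two snake boundaries and the raw intensity clustering: SAT is
#' the fat class between the limb and muscle contours; inside the muscle
#' contour the IMAT/muscle separation follows the initial clustering (fat
#' class = IMAT, muscle class = muscle), the bone mask excluded from both.
#' Pixels that are neither fat nor muscle (skin, background) fall into
#' `outside`, so the five compartments always partition the slice exactly.
#'
#' @param tmap raw `tissue_map` of the slice.
#' @param limb limb boundary (`snake_contour` or vertex matrix).
#' @param muscle muscle boundary.
#' @param bone logical bone mask (e.g. from [detect_bone()]); `NULL` for
#'   none.
#' @param source provenance tag, `"automatic"` or `"manual_corrected"`.
#' @return object of class `compartment_masks`: integer matrix of
#'   [compartment_codes] with the contours stored as attributes.
#' @export
partition_compartments <- function(tmap, limb, muscle, bone = NULL,
                                   source = "automatic") {
  stopifnot(inherits(tmap, "tissue_map"))
  lab <- matrix(as.integer(tmap), nrow(tmap), ncol(tmap))
  limb_pts <- contour_points(limb)
  muscle_pts <- contour_points(muscle)
  # nesting check: the muscle contour must lie inside the limb contour
  mus_in <- points_in_polygon(muscle_pts[, 1], muscle_pts[, 2], limb_pts)
  limb_in_mus <- points_in_polygon(limb_pts[, 1], limb_pts[, 2], muscle_pts)
  if (all(limb_in_mus)) {
    stop("geometry error: limb contour lies inside the muscle contour")
  }
  if (mean(mus_in) < 0.5) {
    stop("geometry error: muscle contour is not nested inside the limb contour")
  }
  limb_mask <- rasterize_polygon(limb_pts, dim(lab))
  muscle_mask_poly <- rasterize_polygon(muscle_pts, dim(lab))
  if (is.null(bone)) bone <- matrix(FALSE, nrow(lab), ncol(lab))
  bone <- bone & muscle_mask_poly

  cm <- matrix(compartment_codes[["outside"]], nrow(lab), ncol(lab))
  between <- limb_mask & !muscle_mask_poly
  cm[between & lab == tissue_classes[["fat"]]] <- compartment_codes[["SAT"]]
  in_mus <- muscle_mask_poly & !bone
  cm[in_mus & lab == tissue_classes[["fat"]]] <- compartment_codes[["IMAT"]]
  cm[in_mus & lab == tissue_classes[["muscle"]]] <- compartment_codes[["muscle"]]
  cm[bone] <- compartment_codes[["bone"]]

  structure(cm, class = c("compartment_masks", class(cm)),
            source = source, limb = limb_pts, muscle = muscle_pts)
}

#' @export
print.compartment_masks <- function(x, ...) {
  tab <- table(factor(as.integer(x), levels = compartment_codes,
                      labels = names(compartment_codes)))
  cat("compartment_masks (", attr(x, "source"), "): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Intramuscular fat fraction of one slice
#'
#' The quantitative outcome of the pipeline: the ratio between the IMAT
#' and the IMAT + muscle pixel counts inside the muscle boundary.
#'
#' @param masks a `compartment_masks`.
#' @return fraction in \[0, 1\].
#' @export
fat_fraction <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  n_imat <- sum(masks == compartment_codes[["IMAT"]])
  n_mus <- sum(masks == compartment_codes[["muscle"]])
  if (n_imat + n_mus == 0) {
    stop("undefined fraction: no IMAT or muscle pixels inside the muscle contour")
  }
  n_imat / (n_imat + n_mus)
}

#' Indices of the middle slices of a stack
#'
#' The `n_middle` slices centred on the stack midpoint; when the remainder
#' is odd the window is shifted one slice towards the proximal end.
#'
#' @param n_slices stack size.
#' @param n_middle window size.
#' @return 1-based slice indices.
#' @export
middle_slice_indices <- function(n_slices, n_middle = 20L) {
  if (n_middle >= n_slices) return(seq_len(n_slices))
  start <- floor((n_slices - n_middle) / 2)
  (start + 1L):(start + n_middle)
}

#' Per-volume fat-fraction result
#'
#' Container for per-slice fractions and their aggregate. Mostly produced
#' by [run_pipeline()] / [aggregate_fraction()].
#'
#' @param per_slice numeric vector of per-slice fractions (NA where a
#'   slice failed).
#' @param flags list (one character vector per slice) of failure reasons.
#' @param source `"automatic"` or `"manual_corrected"`.
#' @return object of class `fat_fraction_result`.
#' @export
fat_fraction_result <- function(per_slice, flags = NULL, source = "automatic") {
  if (is.null(flags)) flags <- rep(list(character(0)), length(per_slice))
  stopifnot(length(flags) == length(per_slice))
  structure(list(per_slice = as.numeric(per_slice), flags = flags,
                 aggregate = NA_real_, slices_used = integer(0),
                 warnings = character(0), source = source),
            class = "fat_fraction_result")
}

#' Aggregate the per-slice fat fractions over the middle of the volume
#'
#' The volume summary is the arithmetic mean of the per-slice fractions of
#' the `n_middle` middle slices (default 20). Flagged or missing slices
#' inside the window are dropped; if fewer than `n_middle` valid slices
#' exist in the whole stack, all valid slices are used and a warning flag
#' is set on the result.
#'
#' @param result a `fat_fraction_result` with per-slice values.
#' @param n_middle number of middle slices to average.
#' @return the input with `aggregate`, `slices_used` and `warnings`
#'   filled in.
#' @export
aggregate_fraction <- function(result, n_middle = 20L) {
  stopifnot(inherits(result, "fat_fraction_result"))
  valid <- which(is.finite(result$per_slice) &
                   !vapply(result$flags, function(f) length(f) > 0, TRUE))
  if (length(valid) == 0) {
    stop("aggregation error: no valid slice to aggregate")
  }
  ns <- length(result$per_slice)
  idx <- middle_slice_indices(ns, n_middle)
  used <- intersect(idx, valid)
  if (length(used) < n_middle) {
    result$warnings <- c(result$warnings,
                         sprintf("only %d valid slice(s) available for a %d-slice window",
                                 length(used), n_middle))
    if (length(used) == 0) used <- valid
  }
  result$slices_used <- used
  result$aggregate <- mean(result$per_slice[used])
  result
}

#' @export
print.fat_fraction_result <- function(x, ...) {
  cat(sprintf("fat_fraction_result (%s): %d slice(s)\n", x$source,
              length(x$per_slice)))
  if (is.finite(x$aggregate)) {
    cat(sprintf("  aggregate fraction %.4f over slices %s\n", x$aggregate,
                paste(range(x$slices_used), collapse = "-")))
  }
  nflag <- sum(vapply(x$flags, function(f) length(f) > 0, TRUE))
  if (nflag) cat("  flagged slices:", nflag, "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Heuristic failure detection for one segmented slice
#'
#' Severe fatty infiltration can defeat the automated SAT/IMAT
#' delimitation (infiltrated muscle directly under the subcutaneous ring
#' looks like SAT). A slice is flagged for manual correction when
#' \itemize{
#'   \item the muscle class is (near) empty,
#'   \item the muscle contour encloses less than `min_muscle_area_frac` of
#'     the limb contour area,
#'   \item the SAT ring is non-annular: some muscle-contour vertex lies
#'     within `touch_dist_px` of the limb contour,
#'   \item the inner rim of the muscle compartment (a band of
#'     `band_depth_px` just inside the fascia) is mostly fat
#'     (occupancy `>= bridge_occupancy`): subcutaneous and intramuscular
#'     fat merge across the boundary, so the SAT/IMAT split is
#'     unreliable.
#' }
#'
#' @param masks a `compartment_masks` (carries its contours).
#' @param tmap the raw `tissue_map` of the slice.
#' @param min_muscle_area_frac area-ratio threshold.
#' @param touch_dist_px contact distance, px.
#' @param bridge_occupancy fat-occupancy threshold of the fascia band.
#' @param band_depth_px band depth, px.
#' @return list with `failed` (logical) and `reasons` (character vector,
#'   possibly empty).
#' @export
flag_failure <- function(masks, tmap, min_muscle_area_frac = 0.2,
                         touch_dist_px = 1.5, bridge_occupancy = 0.75,
                         band_depth_px = 3L) {
  stopifnot(inherits(masks, "compartment_masks"), inherits(tmap, "tissue_map"))
  reasons <- character(0)
  lab <- matrix(as.integer(tmap), nrow(tmap), ncol(tmap))
  limb_pts <- attr(masks, "limb")
  muscle_pts <- attr(masks, "muscle")

  if (sum(lab == tissue_classes[["muscle"]]) < 10) {
    reasons <- c(reasons, "empty muscle class")
  }
  a_limb <- polygon_area(limb_pts)
  a_mus <- polygon_area(muscle_pts)
  if (a_mus < min_muscle_area_frac * a_limb) {
    reasons <- c(reasons, "muscle contour area below limb-area threshold")
  }
  d2 <- outer(muscle_pts[, 1], limb_pts[, 1], "-")^2 +
    outer(muscle_pts[, 2], limb_pts[, 2], "-")^2
  if (min(d2) < touch_dist_px^2) {
    reasons <- c(reasons, "SAT ring non-annular (contours touch)")
  }
  # fat occupancy of the band just inside the fascia
  inner <- rasterize_polygon(muscle_pts, dim(lab))
  eroded <- EBImage::erode(inner, disc_brush(band_depth_px)) > 0
  band <- inner & !eroded
  if (any(band)) {
    occ <- mean(lab[band] == tissue_classes[["fat"]])
    if (occ >= bridge_occupancy) {
      reasons <- c(reasons, "SAT/IMAT delimitation")
    }
  }
  list(failed = length(reasons) > 0, reasons = reasons)
}

#' Recompute the fat fraction from manually drawn contours
#'
#' Fallback for slices where the automated segmentation failed: the
#' supplied limb and muscle boundaries replace the snake results, the bone
#' is re-detected inside the manual muscle contour, and the compartments
#' and fat fraction are recomputed for that single slice. The result is a
#' single-slice `fat_fraction_result` with source `"manual_corrected"`.
#'
#' @param tmap raw `tissue_map` of the (mid-portion) slice.
#' @param manual_limb,manual_muscle vertex matrices, `snake_contour`s, or
#'   paths to polygon CSV files (see [read_contour_csv()]).
#' @return list with `result` (a `fat_fraction_result`), `masks` and
#'   `bone`.
#' @export
apply_manual_contours <- function(tmap, manual_limb, manual_muscle) {
  if (is.character(manual_limb)) manual_limb <- read_contour_csv(manual_limb)
  if (is.character(manual_muscle)) manual_muscle <- read_contour_csv(manual_muscle)
  limb_pts <- contour_points(manual_limb)
  muscle_pts <- contour_points(manual_muscle)
  if (nrow(limb_pts) < 3 || nrow(muscle_pts) < 3) {
    stop("geometry error: manual contours need >= 3 vertices")
  }
  bone <- suppressWarnings(detect_bone(tmap, muscle_pts))
  masks <- partition_compartments(tmap, limb_pts, muscle_pts, bone,
                                  source = "manual_corrected")
  ff <- fat_fraction(masks)
  res <- fat_fraction_result(ff, source = "manual_corrected")
  res$aggregate <- ff
  res$slices_used <- 1L
  list(result = res, masks = masks, bone = bone)
}
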