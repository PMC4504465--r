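#' Tissue class codes
#'
#' Semantic classes of a [tissue_map]: cluster 1 (darkest) holds
#' background, cortical bone and vessel walls; cluster 2 is adipose tissue
#' (SAT, IMAT, marrow — all bright on T1); cluster 3 is muscle.
#'
#' @format named integer vector.
#' @export
tissue_classes <- c(background_bone_vessel = 1L, fat = 2L, muscle = 3L)

new_tissue_map <- function(labels, provenance) {
  structure(labels, class = c("tissue_map", class(labels)),
            provenance = provenance)
}

#' @export
print.tissue_map <- function(x, ...) {
  tab <- table(factor(as.integer(x), levels = tissue_classes,
                      labels = names(tissue_classes)))
  cat("tissue_map (", attr(x, "provenance"), "): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Map intensity clusters to tissues
#'
#' Converts a 3-class intensity clustering of a T1-weighted slice into a
#' semantic tissue map using the contrast ordering: the lowest centroid is
#' background/bone/vessel, the middle is muscle, the highest is adipose
#' tissue. The result is invariant to how the clustering happened to number
#' its clusters, since [kmeans_1d()] relabels centroids in ascending order.
#'
#' @param clustering an `intensity_clustering` from [kmeans_1d()] with
#'   `k = 3`, run on a slice (labels retain the slice shape).
#' @return a `tissue_map`: integer matrix of [tissue_classes] codes with
#'   provenance `"raw_kmeans"`.
#' @export
assign_tissues <- function(clustering) {
  stopifnot(inherits(clustering, "intensity_clustering"))
  cen <- clustering$centroids
  if (length(cen) != 3) stop("assign_tissues needs exactly 3 clusters")
  if (anyDuplicated(cen)) {
    stop("ambiguous assignment: cluster centroids are not distinct")
  }
  # centroids ascend, so cluster index 1/2/3 = dark/mid/bright
  map <- c(tissue_classes[["background_bone_vessel"]],
           tissue_classes[["muscle"]],
           tissue_classes[["fat"]])
  labels <- map[clustering$labels]
  dim(labels) <- dim(clustering$labels)
  if (is.null(dim(labels))) stop("clustering does not carry a slice shape")
  new_tissue_map(labels, "raw_kmeans")
}

#' Cluster one slice into a raw tissue map
#'
#' Convenience wrapper: [kmeans_1d()] on the slice intensities followed by
#' [assign_tissues()].
#'
#' @param slice numeric matrix of intensities.
#' @param n_restarts,seed,tol passed to [kmeans_1d()].
#' @return a raw `tissue_map`.
#' @export
cluster_slice <- function(slice, n_restarts = 8L, seed = 1L, tol = 1e-8) {
  assign_tissues(kmeans_1d(slice, k = 3L, n_restarts = n_restarts,
                           seed = seed, tol = tol))
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

# background-class pixels connected to the image border (true exterior)
outside_mask <- function(tmap) {
  bg <- as.integer(tmap) == tissue_classes[["background_bone_vessel"]]
  dim(bg) <- dim(tmap)
  comp <- EBImage::bwlabel(bg)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  border <- border[border > 0]
  m <- matrix(comp %in% border, nrow(comp), ncol(comp))
  m
}

#' Remove vessel and skin signal from a raw tissue map
#'
#' Morphological cleanup between clustering and boundary fitting:
#' \enumerate{
#'   \item Skin: thin muscle-intensity components that touch the exterior
#'     background and vanish under erosion with the closing disc are
#'     reassigned to the background class, so the muscle class keeps only
#'     the fascia-enclosed compartment.
#'   \item Vessels: a morphological closing of the muscle class with a disc
#'     of `closing_radius_px` absorbs small bright lumina (and equally
#'     small fat speckle) back into muscle, leaving a solid muscle support
#'     for the active contour. The raw map is retained upstream for the
#'     IMAT/muscle separation, which the cleanup must not disturb.
#' }
#'
#' @param tmap a raw `tissue_map` from [assign_tissues()].
#' @param closing_radius_px structuring-disc radius in pixels (> 0);
#'   default 3 px.
#' @return a `tissue_map` with provenance `"cleaned"`.
#' @export
clean_tissue_map <- function(tmap, closing_radius_px = 3L) {
  stopifnot(inherits(tmap, "tissue_map"))
  if (closing_radius_px <= 0) stop("invalid parameter: closing_radius_px must be > 0")
  lab <- matrix(as.integer(tmap), nrow(tmap), ncol(tmap))
  brush <- disc_brush(closing_radius_px)
  # exterior of the limb before skin removal: the outer limb boundary
  # (skin surface) is recovered from this, not from the cleaned classes
  outside <- outside_mask(tmap)

  # --- skin removal -------------------------------------------------------
  muscle <- lab == tissue_classes[["muscle"]]
  comps <- EBImage::bwlabel(muscle)
  touching <- unique(as.integer(comps[EBImage::dilate(outside, disc_brush(1)) & muscle]))
  touching <- touching[touching > 0]
  for (cid in touching) {
    cm <- comps == cid
    if (sum(EBImage::erode(cm, brush)) == 0) {
      lab[cm] <- tissue_classes[["background_bone_vessel"]]
    }
  }

  # --- vessel / lumen removal by closing of the muscle class --------------
  muscle <- lab == tissue_classes[["muscle"]]
  closed <- EBImage::closing(muscle, brush) > 0
  gained <- closed & !muscle & (lab == tissue_classes[["fat"]])
  lab[gained] <- tissue_classes[["muscle"]]

  out <- new_tissue_map(lab, "cleaned")
  attr(out, "outside_raw") <- outside
  out
}
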