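# Shared fixtures: all synthetic, generated in code at test time.

# standard small phantom used by several tests
test_phantom <- function(imat = 0.2, n_slices = 1, seed = 42, ...) {
  make_thigh_phantom(phantom_spec(imat_fraction_target = imat,
                                  n_slices = n_slices, seed = seed, ...))
}

# filled-disk binary target and its analytic boundary
disk_target <- function(size = 128, r = 40) {
  c0 <- (size + 1) / 2
  list(mask = outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+") <= r^2,
       center = c0, radius = r)
}

# symmetric Hausdorff distance between a polygon and an analytic circle,
# with dense resampling of the polygon edges
contour_to_circle_hausdorff <- function(pts, cx, cy, r) {
  dense <- resample_closed_curve(pts, 600)
  ref <- circle_polygon(cx, cy, r, 1200)
  hausdorff_distance(dense, ref)
}

# build a tissue_map directly from an integer matrix (bypassing k-means)
as_tissue_map <- function(m, provenance = "raw_kmeans") {
  structure(m, class = c("tissue_map", class(m)), provenance = provenance)
}

# exhaustive minimum inertia over all contiguous 3-partitions of sorted
# 1-D values (the 1-D k-means optimum is contiguous in sorted order)
contiguous_3partition_min <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      g1 <- v[1:i]; g2 <- v[(i + 1):j]; g3 <- v[(j + 1):n]
      ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
      if (ss < best) best <- ss
    }
  }
  best
}
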