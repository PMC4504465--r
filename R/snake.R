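#' Snake (active contour) configuration
#'
#' Parameters of the greedy polygonal active contour used to delineate the
#' outer limb boundary and the deep fascia. `alpha` weights contour
#' tension (continuity), `beta` the rigidity (curvature) and `gamma` the
#' attachment to the binary target image; the defaults (0.1, 0.6, 0.3)
#' with `n_points = 50` are the operating point of the segmentation
#' pipeline.
#'
#' @param alpha continuity weight (>= 0).
#' @param beta curvature weight (>= 0).
#' @param gamma image-attachment weight (>= 0); the three weights must not
#'   all be zero.
#' @param n_points number of contour control points N (>= 4).
#' @param search_window_px odd side (>= 3) of the square greedy search
#'   window around each point.
#' @param max_iter sweep cap.
#' @param move_tol convergence threshold: stop when the fraction of points
#'   moved in a sweep is `<= move_tol`.
#' @param field_sigma Gaussian blur (px) applied to the edge map when
#'   building the image-energy field; sets the attraction range.
#' @param resample redistribute points to equal arc length after each
#'   sweep (recommended; prevents bunching).
#' @return an object of class `snake_config`.
#' @export
snake_config <- function(alpha = 0.1, beta = 0.6, gamma = 0.3,
                         n_points = 50L, search_window_px = 7L,
                         max_iter = 500L, move_tol = 0.02,
                         field_sigma = 3, resample = TRUE) {
  if (alpha < 0 || beta < 0 || gamma < 0 || (alpha + beta + gamma) == 0) {
    stop("invalid snake config: weights must be >= 0 and not all zero")
  }
  if (n_points < 4) stop("invalid snake config: n_points must be >= 4")
  if (search_window_px < 3 || search_window_px %% 2 == 0) {
    stop("invalid snake config: search_window_px must be odd and >= 3")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 n_points = as.integer(n_points),
                 search_window_px = as.integer(search_window_px),
                 max_iter = as.integer(max_iter), move_tol = move_tol,
                 field_sigma = field_sigma, resample = isTRUE(resample)),
            class = "snake_config")
}

#' Image-energy field of a binary target
#'
#' Negative, normalized, Gaussian-smoothed gradient magnitude of the
#' binary target: the field is 0 far from the region boundary and reaches
#' -1 on it, so boundary pixels are energy minima with an attraction range
#' of a few `sigma`.
#'
#' @param target binary (logical or 0/1) matrix.
#' @param sigma blur in pixels.
#' @return numeric matrix in `[-1, 0]`.
#' @export
image_energy_field <- function(target, sigma = 3) {
  t <- matrix(as.numeric(target), nrow(target), ncol(target))
  gx <- t; gy <- t
  gx[] <- 0; gy[] <- 0
  gx[, 2:(ncol(t) - 1)] <- (t[, 3:ncol(t)] - t[, 1:(ncol(t) - 2)]) / 2
  gy[2:(nrow(t) - 1), ] <- (t[3:nrow(t), ] - t[1:(nrow(t) - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  sm <- as.matrix(EBImage::gblur(mag, sigma = sigma))
  mx <- max(sm)
  if (mx <= 0) return(matrix(0, nrow(t), ncol(t)))
  -sm / mx
}

.field_at <- function(field, x, y) {
  xi <- pmin(pmax(round(x), 1), ncol(field))
  yi <- pmin(pmax(round(y), 1), nrow(field))
  field[cbind(yi, xi)]
}

.mean_spacing <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  mean(sqrt(rowSums((nxt - pts)^2)))
}

#' Total snake energy of a contour
#'
#' Sum over the closed contour, with cyclic indexing, of
#' `alpha * ||p_i - p_{i-1}||^2 + beta * ||p_{i-1} - 2 p_i + p_{i+1}||^2 +
#' gamma * E_image(p_i)`, where `E_image` is the [image_energy_field()] of
#' the binary target sampled at the nearest pixel. With
#' `normalized = TRUE` (the form minimized by [evolve_contour()]) the two
#' internal terms are divided by the squared reference spacing `d_ref` so
#' that the three weights act on comparable scales.
#'
#' @param contour two-column (x, y) vertex matrix or a `snake_contour`.
#' @param target binary target image (ignored when `field` is given).
#' @param config a [snake_config()].
#' @param field optional precomputed [image_energy_field()].
#' @param normalized divide internal terms by `d_ref^2`.
#' @param d_ref reference spacing; defaults to the contour's mean point
#'   spacing.
#' @return scalar energy (finite).
#' @export
snake_energy <- function(contour, target = NULL, config = snake_config(),
                         field = NULL, normalized = FALSE, d_ref = NULL) {
  pts <- if (inherits(contour, "snake_contour")) contour$points else contour
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 4)
  if (is.null(field)) {
    if (is.null(target)) stop("either a target image or a field is required")
    field <- image_energy_field(target, config$field_sigma)
  }
  if (any(pts[, 1] < 0.5 | pts[, 1] > ncol(field) + 0.5 |
          pts[, 2] < 0.5 | pts[, 2] > nrow(field) + 0.5)) {
    stop("out of bounds: contour point outside the image frame")
  }
  prv <- rbind(pts[nrow(pts), , drop = FALSE], pts[-nrow(pts), , drop = FALSE])
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  e_cont <- rowSums((pts - prv)^2)
  e_curv <- rowSums((prv - 2 * pts + nxt)^2)
  e_img <- .field_at(field, pts[, 1], pts[, 2])
  d2 <- if (normalized) {
    dr <- if (is.null(d_ref)) .mean_spacing(pts) else d_ref
    max(dr^2, 1e-12)
  } else 1
  sum(config$alpha * e_cont / d2 + config$beta * e_curv / d2 + config$gamma * e_img)
}

# rotate ordering so the lexicographically smallest vertex (y, then x)
# comes first; makes the greedy sweep independent of the input rotation
.canonical_order <- function(pts) {
  i0 <- order(pts[, 2], pts[, 1])[1]
  if (i0 > 1) pts <- pts[c(i0:nrow(pts), 1:(i0 - 1)), , drop = FALSE]
  pts
}

.normalize_ccw <- function(pts) {
  if (polygon_signed_area(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  else pts
}

#' Evolve a polygonal snake on a binary target
#'
#' Greedy local search in the Williams-Shah style. Each sweep evaluates,
#' for every control point, all positions in its square search window
#' with the other points frozen at their sweep-start positions. The
#' point's share of the energy — both continuity terms, the three
#' curvature terms that involve it, and its image term — is computed for
#' every candidate, each term min-max normalized over the window before
#' weighting, which puts the heterogeneous term scales on an equal
#' footing and makes the weights (0.1, 0.6, 0.3) meaningful. All moves
#' are then applied simultaneously. Because the current position competes
#' in its own window under the same normalization, a sweep never
#' increases the summed local energy it minimizes; the per-sweep sums are
#' recorded in `energy_trace` (columns `energy_start`/`energy_end`, both
#' evaluated against the frozen sweep-start neighbours). After each sweep
#' the points are redistributed to equal arc length.
#'
#' The contour is canonicalized (counterclockwise, starting from the
#' lexicographically smallest vertex) before evolution, so the result does
#' not depend on the rotation of the input ordering.
#'
#' @param init initial contour: (n x 2) vertex matrix enclosing (or close
#'   to) the target region.
#' @param target binary target image.
#' @param config a [snake_config()].
#' @param field optional precomputed external-energy field (e.g. from
#'   [image_energy_field()] on a non-binary image); overrides `target`.
#' @return object of class `snake_contour`: `points` (exactly
#'   `config$n_points` rows, counterclockwise), `closed = TRUE`,
#'   `converged`, `n_sweeps`, `energy_trace` (data frame) and `flags`
#'   (character vector; `"max_iter"` when the sweep cap was hit,
#'   `"self_intersection"` if the converged polygon crosses itself).
#' @examples
#' disk <- outer((1:96 - 48.5)^2, (1:96 - 48.5)^2, "+") <= 30^2
#' fit <- evolve_contour(circle_polygon(48.5, 48.5, 40, 50), disk, snake_config())
#' fit$converged
#' @export
evolve_contour <- function(init, target, config = snake_config(),
                           field = NULL) {
  stopifnot(is.matrix(init), ncol(init) == 2, nrow(init) >= 4)
  if (is.null(field)) field <- image_energy_field(target, config$field_sigma)
  nr <- nrow(field); nc <- ncol(field)
  N <- config$n_points
  # canonicalize the raw vertices before resampling so that a cyclic
  # rotation of the input ordering yields the identical point sequence
  pts <- resample_closed_curve(.canonical_order(.normalize_ccw(init)), N)
  pts <- .canonical_order(pts)
  pts[, 1] <- pmin(pmax(pts[, 1], 1), nc)
  pts[, 2] <- pmin(pmax(pts[, 2], 1), nr)

  h <- (config$search_window_px - 1L) / 2L
  off <- expand.grid(dx = -h:h, dy = -h:h)
  a <- config$alpha; b <- config$beta; g <- config$gamma

  # min-max normalize a term over the valid window candidates; a flat
  # term contributes 0 for every candidate
  mmnorm <- function(v, ok) {
    vv <- v[ok]
    rng <- max(vv) - min(vv)
    out <- rep(0, length(v))
    if (rng > 1e-30) out[ok] <- (v[ok] - min(vv)) / rng
    out
  }
  cur <- which(off$dx == 0 & off$dy == 0)

  trace <- matrix(NA_real_, 0, 3)
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(config$max_iter)) {
    sweeps <- sweep
    p0 <- pts  # frozen neighbour positions for this sweep
    moved <- 0L
    e_start <- 0; e_end <- 0
    for (i in seq_len(N)) {
      im1 <- if (i == 1) N else i - 1
      im2 <- if (im1 == 1) N else im1 - 1
      ip1 <- if (i == N) 1 else i + 1
      ip2 <- if (ip1 == N) 1 else ip1 + 1
      pm2 <- p0[im2, ]; pm1 <- p0[im1, ]; pp1 <- p0[ip1, ]; pp2 <- p0[ip2, ]
      cx <- p0[i, 1] + off$dx; cy <- p0[i, 2] + off$dy
      ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
      # all energy terms that involve p_i, neighbours frozen
      e_cont <- (cx - pm1[1])^2 + (cy - pm1[2])^2 +
                (pp1[1] - cx)^2 + (pp1[2] - cy)^2
      e_curv <- (pm2[1] - 2 * pm1[1] + cx)^2 + (pm2[2] - 2 * pm1[2] + cy)^2 +
                (pm1[1] - 2 * cx + pp1[1])^2 + (pm1[2] - 2 * cy + pp1[2])^2 +
                (cx - 2 * pp1[1] + pp2[1])^2 + (cy - 2 * pp1[2] + pp2[2])^2
      e_img <- .field_at(field, cx, cy)
      e <- a * mmnorm(e_cont, ok) + b * mmnorm(e_curv, ok) + g * mmnorm(e_img, ok)
      e[!ok] <- Inf
      best <- which.min(e)
      if (e[cur] <= e[best] + 1e-12) best <- cur
      e_start <- e_start + e[cur]
      e_end <- e_end + e[best]
      if (best != cur) {
        pts[i, ] <- c(cx[best], cy[best])
        moved <- moved + 1L
      }
    }
    trace <- rbind(trace, c(sweep, e_start, e_end))
    if (moved / N <= config$move_tol) { converged <- TRUE; break }
    if (config$resample) pts <- resample_closed_curve(pts, N)
  }

  pts <- .canonical_order(.normalize_ccw(pts))
  flags <- character(0)
  if (!converged) flags <- c(flags, "max_iter")
  if (polygon_self_intersects(pts)) flags <- c(flags, "self_intersection")
  structure(
    list(points = pts, closed = TRUE, converged = converged,
         n_sweeps = sweeps,
         energy_trace = stats::setNames(as.data.frame(trace),
                                        c("sweep", "energy_start", "energy_end")),
         flags = flags),
    class = "snake_contour"
  )
}

#' @export
print.snake_contour <- function(x, ...) {
  cat(sprintf("snake_contour: %d points, %s after %d sweep(s)",
              nrow(x$points),
              if (x$converged) "converged" else "NOT converged", x$n_sweeps))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# convex-hull initial contour around a mask, pushed outward radially
.hull_init <- function(mask, n_points, offset = 5) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(NULL)
  pts <- cbind(idx[, 2], idx[, 1])  # (x, y)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ctr <- colMeans(pts)
  d <- sqrt(rowSums((hull - matrix(ctr, nrow(hull), 2, byrow = TRUE))^2))
  d[d < 1e-9] <- 1e-9
  hull <- hull + offset * (hull - matrix(ctr, nrow(hull), 2, byrow = TRUE)) / d
  hull[, 1] <- pmin(pmax(hull[, 1], 1.5), ncol(mask) - 0.5)
  hull[, 2] <- pmin(pmax(hull[, 2], 1.5), nrow(mask) - 0.5)
  resample_closed_curve(hull, n_points)
}

.largest_component <- function(mask) {
  comps <- EBImage::bwlabel(mask)
  sizes <- tabulate(comps[comps > 0])
  if (!length(sizes)) return(NULL)
  comps == which.max(sizes)
}

# Binary support of the fascia-enclosed muscle region ("muscle plus
# interior fat, filled"). Subcutaneous fat contains essentially no
# muscle-class pixels, so the fascia is the outer envelope of the muscle
# class. The envelope is taken star-convex around the centroid of the
# muscle-density support: per 1-degree angular bin the outermost
# muscle-pixel radius, then a circular running maximum over +/- env_half
# bins, which bridges fat blobs sitting on the boundary (a blob would
# otherwise carve a fat-rich bite out of the compartment and bias the
# fat fraction downward). The density support (local muscle density
# above half its interior level) provides the centroid and a fallback.
.muscle_region_support <- function(muscle_mask, density_sigma = 4,
                                   n_bins = 360L, env_half = 15L) {
  dens <- as.matrix(EBImage::gblur(matrix(as.numeric(muscle_mask),
                                          nrow(muscle_mask), ncol(muscle_mask)),
                                   sigma = density_sigma))
  region <- dens > 0.02
  if (!any(region)) return(NULL)
  core_brush <- disc_brush(max(2L, round(2 * density_sigma)))
  for (it in 1:3) {
    # interior level = median local density over the filled, eroded
    # region: filling keeps sub-threshold interior patches in the sample
    # and the erosion drops the boundary ramp, so the estimate is not
    # biased upward by the thresholding itself
    core <- EBImage::erode(EBImage::fillHull(region), core_brush) > 0
    d_in <- stats::median(dens[if (any(core)) core else region])
    nxt <- dens > d_in / 2
    if (!any(nxt)) break
    region <- nxt
  }
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) < 3) return(region)
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])

  m_idx <- which(muscle_mask, arr.ind = TRUE)
  dx <- m_idx[, 2] - cx; dy <- m_idx[, 1] - cy
  ang <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)
  bin <- as.integer(floor((ang + pi) / (2 * pi) * n_bins)) %% n_bins + 1L
  r_raw <- rep(NA_real_, n_bins)
  agg <- tapply(rad, bin, max)
  r_raw[as.integer(names(agg))] <- agg
  if (anyNA(r_raw)) {
    ok <- which(!is.na(r_raw))
    if (length(ok) < 3) return(region)
    r_raw[is.na(r_raw)] <- stats::approx(
      c(ok, ok[1] + n_bins), c(r_raw[ok], r_raw[ok[1]]),
      xout = which(is.na(r_raw)), rule = 2)$y
  }
  r_env <- vapply(seq_len(n_bins), function(a) {
    w <- ((a - env_half):(a + env_half) - 1L) %% n_bins + 1L
    max(r_raw[w])
  }, numeric(1))
  th <- 2 * pi * ((seq_len(n_bins) - 0.5) / n_bins) - pi
  poly <- cbind(cx + r_env * cos(th), cy + r_env * sin(th))
  poly[, 1] <- pmin(pmax(poly[, 1], 1), ncol(muscle_mask))
  poly[, 2] <- pmin(pmax(poly[, 2], 1), nrow(muscle_mask))
  rasterize_polygon(poly, dim(muscle_mask))
}

#' Fit the limb and muscle boundaries of one slice
#'
#' Builds two binary targets from a cleaned tissue map and evolves a
#' snake on each, initialized from the dilated convex hull of the
#' respective support. The limb target is the filled largest component of
#' everything not connected to the image border as background; the
#' muscle target is the filled muscle-region support (muscle plus
#' interior fat and bone), reconstructed from the local muscle-pixel
#' density at the half-maximum level so that speckled infiltration does
#' not erode the fascia boundary.
#'
#' @param tmap a cleaned `tissue_map` (see [clean_tissue_map()]).
#' @param config a [snake_config()].
#' @param density_sigma Gaussian scale (px) of the muscle-density
#'   estimate used to build the muscle-region support.
#' @return list with `limb` and `muscle` (`snake_contour` or `NULL`),
#'   `failure` (logical) and `reasons` (character). An empty muscle class
#'   raises the failure flag instead of an error so the slice can be
#'   routed to manual correction.
#' @export
fit_limb_and_muscle_contours <- function(tmap, config = snake_config(),
                                         density_sigma = 4) {
  stopifnot(inherits(tmap, "tissue_map"))
  lab <- matrix(as.integer(tmap), nrow(tmap), ncol(tmap))
  # prefer the exterior recorded before skin removal, so the limb contour
  # sits on the skin surface
  outside <- attr(tmap, "outside_raw")
  if (is.null(outside)) outside <- outside_mask(tmap)
  limb_comp <- .largest_component(!outside)
  if (is.null(limb_comp)) {
    return(list(limb = NULL, muscle = NULL, failure = TRUE,
                reasons = "empty limb support"))
  }
  limb_support <- EBImage::fillHull(limb_comp) > 0

  muscle_mask <- lab == tissue_classes[["muscle"]]
  if (!any(muscle_mask)) {
    return(list(limb = NULL, muscle = NULL, failure = TRUE,
                reasons = "empty muscle class"))
  }
  muscle_support <- .muscle_region_support(muscle_mask, density_sigma)
  if (is.null(muscle_support)) {
    return(list(limb = NULL, muscle = NULL, failure = TRUE,
                reasons = "degenerate support"))
  }

  reasons <- character(0)
  limb_init <- .hull_init(limb_support, config$n_points, offset = 5)
  muscle_init <- .hull_init(muscle_support, config$n_points, offset = 5)
  if (is.null(limb_init) || is.null(muscle_init)) {
    return(list(limb = NULL, muscle = NULL, failure = TRUE,
                reasons = "degenerate support"))
  }
  limb <- evolve_contour(limb_init, limb_support, config)
  muscle <- evolve_contour(muscle_init, muscle_support, config)
  if (length(limb$flags)) reasons <- c(reasons, paste0("limb: ", limb$flags))
  if (length(muscle$flags)) reasons <- c(reasons, paste0("muscle: ", muscle$flags))
  inside <- points_in_polygon(muscle$points[, 1], muscle$points[, 2], limb$points)
  if (mean(inside) < 0.95) reasons <- c(reasons, "muscle contour escapes limb contour")
  list(limb = limb, muscle = muscle,
       failure = any(grepl("self_intersection|escapes", reasons)),
       reasons = reasons)
}
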