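#' Polygon and mask geometry utilities
#'
#' Small geometric primitives shared by the phantom generator, the active
#' contour and the compartment partitioning. Coordinates are pixel-centred:
#' pixel (x, y) is column x, row y of the image matrix, both 1-based, so a
#' polygon vertex at (10, 3) sits on the centre of `img[3, 10]`.
#'
#' @name geometry
#' @keywords internal
NULL

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counterclockwise orientation in the image frame
#' (x rightwards, y downwards, angles measured as usual on the stored
#' coordinates).
#'
#' @param pts two-column matrix of (x, y) vertices, implicitly closed.
#' @return signed area in square pixels.
#' @export
polygon_signed_area <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 3)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_signed_area
#' @return area in square pixels.
#' @export
polygon_area <- function(pts) abs(polygon_signed_area(pts))

#' Rasterize a closed polygon to a logical mask
#'
#' Even-odd (crossing-number) scanline fill evaluated at pixel centres;
#' pixels whose centre lies on the boundary are counted as interior. This
#' is the single rasterization rule used throughout the package so that
#' polygon areas and mask pixel counts stay consistent.
#'
#' @param pts two-column (x, y) vertex matrix, implicitly closed.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix of size `dim`.
#' @export
rasterize_polygon <- function(pts, dim) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 3, length(dim) == 2)
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(FALSE, nr, nc)
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  eps <- 1e-9
  ylo <- max(1L, floor(min(y)))
  yhi <- min(nr, ceiling(max(y)))
  if (ylo > yhi) return(mask)
  for (row in ylo:yhi) {
    # edges crossing the horizontal line through this row of pixel centres
    cross <- (y <= row) != (yn <= row)
    if (!any(cross)) next
    xi <- x[cross] + (row - y[cross]) * (xn[cross] - x[cross]) / (yn[cross] - y[cross])
    xi <- sort(xi)
    # fill between successive pairs of crossings (even-odd rule)
    for (j in seq(1, length(xi) - 1, by = 2)) {
      a <- ceiling(xi[j] - eps); b <- floor(xi[j + 1] + eps)
      a <- max(1L, a); b <- min(nc, b)
      if (a <= b) mask[row, a:b] <- TRUE
    }
  }
  mask
}

#' Test points against a closed polygon
#'
#' Even-odd rule; points exactly on an edge count as inside (consistent
#' with [rasterize_polygon()]).
#'
#' @param px,py coordinates of query points.
#' @param pts polygon vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (i in seq_along(px)) {
    cross <- (y <= py[i]) != (yn <= py[i])
    if (!any(cross)) next
    xi <- x[cross] + (py[i] - y[cross]) * (xn[cross] - x[cross]) / (yn[cross] - y[cross])
    inside[i] <- (sum(xi <= px[i] + 1e-9) %% 2) == 1
  }
  inside
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b logical masks of identical dimension.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

#' Symmetric Hausdorff distance between two point sets
#'
#' Used to compare a converged contour with an analytic reference boundary.
#' Polygons should be densely resampled before calling if edge (not just
#' vertex) distance matters; see [resample_closed_curve()].
#'
#' @param a,b two-column (x, y) coordinate matrices.
#' @return largest of the two directed Hausdorff distances, in pixels.
#' @export
hausdorff_distance <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 2, ncol(b) == 2)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

#' Resample a closed curve to equally spaced points
#'
#' Linear interpolation along arc length; the output has exactly `n`
#' points. Used after each snake sweep to keep control points from
#' bunching, and to densify contours before distance computations.
#'
#' @param pts two-column vertex matrix of the closed curve.
#' @param n number of output points.
#' @return an `n` x 2 matrix.
#' @export
resample_closed_curve <- function(pts, n) {
  stopifnot(nrow(pts) >= 3, n >= 3)
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(matrix(rep(pts[1, ], each = n), n, 2))
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(
    stats::approx(s, closed[, 1], xout = target, ties = "ordered")$y,
    stats::approx(s, closed[, 2], xout = target, ties = "ordered")$y
  )
}

#' Regular polygon approximation of a circle
#'
#' @param cx,cy centre in pixel coordinates.
#' @param r radius in pixels.
#' @param n number of vertices.
#' @return an `n` x 2 (x, y) matrix, counterclockwise.
#' @export
circle_polygon <- function(cx, cy, r, n = 100) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Does the closed polygon self-intersect (any non-adjacent edge pair)?
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(TRUE)
    }
  }
  FALSE
}
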