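#' Lloyd's k-means with k-means++ seeding
#'
#' The clustering engine shared by the per-slice intensity clustering and
#' the cohort imaging-pattern clustering. Runs Lloyd's alternating
#' assign/recentre iteration from `n_restarts` k-means++ initializations
#' and keeps the lowest-inertia fixed point. Points equidistant to two
#' centres are assigned to the lower-index centre; a cluster emptied during
#' iteration is re-seeded with the point farthest from its centre. The
#' within-cluster sum of squares is recorded after every update and is
#' non-increasing by construction.
#'
#' @param x numeric matrix, one row per observation.
#' @param k number of clusters.
#' @param n_restarts independent k-means++ starts.
#' @param seed integer seed governing initialization.
#' @param tol convergence threshold on the relative inertia decrease (the
#'   iteration also stops when assignments no longer change).
#' @param max_iter iteration cap per restart.
#' @return list with `cluster` (assignments), `centers` (k x p matrix),
#'   `inertia`, `n_iter`, and `inertia_trace` of the winning restart.
#' @export
lloyd_kmeans <- function(x, k, n_restarts = 8, seed = 1L, tol = 1e-8,
                         max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1")
  if (nrow(unique(x)) < k) {
    stop("degenerate input: fewer than k distinct observations")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- .kmeanspp_init(x, k)
    fit <- .lloyd_run(x, centers, tol, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then
# proportional to squared distance to the nearest chosen centre
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  if (k == 1) return(centers)
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      cand <- which(!duplicated(x))
      pick <- cand[sample.int(length(cand), 1)]
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers <- rbind(centers, x[pick, , drop = FALSE])
    dn <- rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  centers
}

.assign_nearest <- function(x, centers) {
  # ties go to the lower-index centre: max.col on negated distance with
  # ties.method = "first"
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

.lloyd_run <- function(x, centers, tol, max_iter) {
  n <- nrow(x); k <- nrow(centers)
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cl <- .assign_nearest(x, centers)
    # re-seed empty clusters with the point farthest from its centre
    for (j in which(tabulate(cl, k) == 0)) {
      d2 <- rowSums((x - centers[cl, , drop = FALSE])^2)
      far <- which.max(d2)
      centers[j, ] <- x[far, ]
      cl[far] <- j
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[cl == j, , drop = FALSE])
    }
    inertia <- sum(rowSums((x - centers[cl, , drop = FALSE])^2))
    trace <- c(trace, inertia)
    converged <- identical(cl, assign_prev) ||
      (length(trace) > 1 && (trace[length(trace) - 1] - inertia) <= tol * max(inertia, 1)) ||
      iter >= max_iter
    assign_prev <- cl
    if (converged) break
  }
  # final assignment at the converged centres (Lloyd fixed point)
  cl <- .assign_nearest(x, centers)
  inertia <- sum(rowSums((x - centers[cl, , drop = FALSE])^2))
  list(cluster = cl, centers = centers, inertia = inertia, n_iter = iter,
       inertia_trace = trace)
}

#' One-dimensional k-means on pixel intensities
#'
#' Clusters scalar intensities into `k` groups (three for the T1 tissue
#' model: dark background/bone/vessels, mid-grey muscle, bright fat) with
#' [lloyd_kmeans()]. Cluster labels are relabelled so that centroids
#' ascend: cluster 1 is the darkest, cluster `k` the brightest.
#'
#' @param values numeric vector (or matrix, kept as shape attribute) of
#'   intensities.
#' @param k number of clusters (default 3).
#' @param n_restarts independent k-means++ starts.
#' @param seed integer seed.
#' @param tol convergence tolerance passed to [lloyd_kmeans()].
#' @return object of class `intensity_clustering`: `labels` (same shape as
#'   the input when it was a matrix), `centroids` (ascending), `inertia`,
#'   `n_iter`, `inertia_trace`.
#' @examples
#' km <- kmeans_1d(c(0, 0, 0, 100, 100, 200, 200), k = 3, seed = 1)
#' km$centroids  # 0, 100, 200
#' @export
kmeans_1d <- function(values, k = 3L, n_restarts = 8L, seed = 1L, tol = 1e-8) {
  shape <- if (is.matrix(values) || is.array(values)) dim(values) else NULL
  v <- as.numeric(values)
  if (length(unique(v)) < k) {
    stop("degenerate input: fewer than k distinct intensity values")
  }
  fit <- lloyd_kmeans(matrix(v, ncol = 1), k, n_restarts = n_restarts,
                      seed = seed, tol = tol)
  ord <- order(fit$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[fit$cluster]
  if (!is.null(shape)) dim(labels) <- shape
  structure(
    list(labels = labels, centroids = as.numeric(fit$centers[ord, 1]),
         inertia = fit$inertia, n_iter = fit$n_iter,
         inertia_trace = fit$inertia_trace),
    class = "intensity_clustering"
  )
}

#' @export
print.intensity_clustering <- function(x, ...) {
  cat("intensity_clustering:", length(x$centroids), "clusters\n")
  cat("  centroids:", paste(sprintf("%.2f", x$centroids), collapse = ", "), "\n")
  cat(sprintf("  inertia %.4g after %d iteration(s)\n", x$inertia, x$n_iter))
  invisible(x)
}
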