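#' Cluster patients by imaging pattern
#'
#' k-means (Lloyd's iteration, best of `n_restarts` seeded starts) on the
#' per-muscle visual scores, the two sides of each muscle averaged so that
#' a patient is described by one mean grade per muscle. Thigh and leg
#' patterns are clustered separately via `region`. Cluster labels are
#' re-ordered by ascending overall mean score, so cluster 1 is always the
#' mildest pattern.
#'
#' @param table a `visual_score_table` (see [make_cohort_scores()]) or any
#'   data frame with `<muscle>_<L|R>` grade columns.
#' @param k number of clusters (default 3).
#' @param region `"thigh"`, `"leg"` or `"all"`; selects the muscle set.
#' @param n_restarts k-means++ restarts (default 20).
#' @param seed integer seed.
#' @param side_average average left/right grades per muscle (default);
#'   `FALSE` clusters the raw muscle-by-side vectors.
#' @return object of class `cluster_result`: `assignments`, `centers`
#'   (k x muscles), `inertia`, `n_iter`, `features`.
#' @export
cluster_patients <- function(table, k = 3L, region = c("thigh", "leg", "all"),
                             n_restarts = 20L, seed = 1L, side_average = TRUE) {
  region <- match.arg(region)
  muscles <- switch(region, thigh = thigh_muscles, leg = leg_muscles,
                    all = c(thigh_muscles, leg_muscles))
  g <- score_matrix(table, muscles)
  if (k > nrow(g)) stop("invalid k: more clusters than patients")
  feats <- if (side_average) {
    f <- (g[, paste0(muscles, "_L"), drop = FALSE] +
            g[, paste0(muscles, "_R"), drop = FALSE]) / 2
    colnames(f) <- muscles
    f
  } else g
  fit <- lloyd_kmeans(feats, k, n_restarts = n_restarts, seed = seed)
  ord <- order(rowMeans(fit$centers))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(
    list(assignments = relabel[fit$cluster],
         centers = fit$centers[ord, , drop = FALSE],
         inertia = fit$inertia, n_iter = fit$n_iter, features = feats),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$centers), "clusters,",
      length(x$assignments), "patients\n")
  cat("  sizes:", paste(tabulate(x$assignments, nrow(x$centers)), collapse = ", "),
      "; inertia", signif(x$inertia, 5), "\n")
  invisible(x)
}

#' Bilateral asymmetry summary of a visual-score table
#'
#' A muscle pair is asymmetric when the left and right grades differ by at
#' least one point; a patient is asymmetric for a region when any muscle
#' pair of that region is.
#'
#' @param table a `visual_score_table`.
#' @return list with `per_muscle` (data frame: muscle, region, per-cohort
#'   asymmetry percentage), `per_patient` (data frame with logical
#'   `thigh_asymmetric` / `leg_asymmetric`), and cohort frequencies
#'   `pct_patients_thigh` / `pct_patients_leg` in percent.
#' @export
asymmetry_summary <- function(table) {
  all_m <- c(thigh_muscles, leg_muscles)
  region <- rep(c("thigh", "leg"), c(length(thigh_muscles), length(leg_muscles)))
  g <- score_matrix(table, all_m)
  asym <- abs(g[, paste0(all_m, "_L"), drop = FALSE] -
                g[, paste0(all_m, "_R"), drop = FALSE]) >= 1
  colnames(asym) <- all_m
  per_muscle <- data.frame(muscle = all_m, region = region,
                           pct_asymmetric = 100 * colMeans(asym))
  thigh_any <- apply(asym[, thigh_muscles, drop = FALSE], 1, any)
  leg_any <- apply(asym[, leg_muscles, drop = FALSE], 1, any)
  per_patient <- data.frame(thigh_asymmetric = thigh_any, leg_asymmetric = leg_any)
  if ("patient_id" %in% names(table)) per_patient <- cbind(
    patient_id = table$patient_id, per_patient)
  list(per_muscle = per_muscle, per_patient = per_patient,
       pct_patients_thigh = 100 * mean(thigh_any),
       pct_patients_leg = 100 * mean(leg_any))
}

#' Intraclass correlation and coefficient of variation of repeated ratings
#'
#' Agreement between repeated measurements (e.g. two observers' manual
#' fat-fraction measurements on the same subjects). The ICC is the
#' two-way random-effects, absolute-agreement, single-measure form
#' ICC(2,1), computed from the mean squares of the subject x rater
#' decomposition:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects, `k` raters, `MS_R` the between-subject, `MS_C` the
#' between-rater and `MS_E` the residual mean square. The coefficient of
#' variation is computed per subject as sd/mean of that subject's ratings
#' (in percent) and reported as mean +/- sd over subjects.
#'
#' @param ratings numeric matrix, subjects x raters, complete.
#' @param form `"absolute"` for ICC(2,1) (default) or `"consistency"` for
#'   ICC(3,1).
#' @return list with `icc`, `cv_mean`, `cv_sd`, `cv_per_subject` and the
#'   mean squares (`msr`, `msc`, `mse`).
#' @export
icc_agreement <- function(ratings, form = c("absolute", "consistency")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stop("ratings matrix must be complete")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- if (form == "absolute") {
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  } else {
    msr + (k - 1) * mse
  }
  if (abs(denom) < 1e-30) {
    stop("degenerate ratings: no variance, ICC undefined")
  }
  icc <- (msr - mse) / denom
  cv <- apply(ratings, 1, function(r) {
    if (abs(mean(r)) < 1e-30) return(NA_real_)
    100 * stats::sd(r) / mean(r)
  })
  list(icc = icc, cv_mean = mean(cv, na.rm = TRUE),
       cv_sd = stats::sd(cv[is.finite(cv)]),
       cv_per_subject = cv, msr = msr, msc = msc, mse = mse)
}

# all permutations of 1..n as a matrix (n! rows); n is kept small by the
# exactness cutoff in spearman_bonferroni
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation with Bonferroni correction
#'
#' The rank correlation is the Pearson correlation of mid-ranks (average
#' ranks on ties). For `n <= exact_max` (default 10) the two-sided p-value
#' is exact, by full enumeration of all `n!` permutations of one ranking;
#' above that the usual t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' is used. The Bonferroni-adjusted p-value is `min(1, m_tests * p_raw)`.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param m_tests number of tests in the family (default 1 = no
#'   correction).
#' @param exact_max largest n for which the permutation-exact p is
#'   computed.
#' @return list with `rho`, `p_raw`, `p_adjusted`, `method`.
#' @export
spearman_bonferroni <- function(x, y, m_tests = 1L, exact_max = 10L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- .permutations(n)
    # rho is affine in the permuted cross-products, so enumerate those
    rp <- matrix(ry[perms], nrow(perms), n)
    rho_perm <- as.numeric(stats::cor(rx, t(rp)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_raw = p, p_adjusted = min(1, m_tests * p),
       method = method)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE`,
#' returning the pooled-variance t statistic, its degrees of freedom and
#' the two-sided p-value.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 in each sample")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  }
  if (stats::var(x) + stats::var(y) == 0) {
    stop("degenerate samples: zero pooled variance with distinct means")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Linear versus logarithmic fit of fat fraction on visual score
#'
#' Compares the explanatory power of the mean visual score for the
#' intramuscular fat fraction on the raw and on the log scale: `r2_linear`
#' is the R-squared of `fraction ~ score`, `r2_log` that of
#' `log(fraction) ~ score`. Zero fractions are offset by half the smallest
#' positive observed fraction before the log (with a warning).
#'
#' @param mean_score per-patient mean visual score.
#' @param fat_fraction per-patient intramuscular fat fraction.
#' @return list with `r2_linear` and `r2_log`.
#' @export
linear_vs_log_r2 <- function(mean_score, fat_fraction) {
  stopifnot(length(mean_score) == length(fat_fraction))
  if (stats::sd(mean_score) == 0) stop("undefined fit: all scores equal")
  ff <- fat_fraction
  if (any(ff < 0)) stop("fat fractions must be >= 0")
  if (any(ff == 0)) {
    pos <- ff[ff > 0]
    if (!length(pos)) stop("all fat fractions are zero")
    warning("zero fat fractions offset by half the smallest positive value for the log fit")
    ff[ff == 0] <- min(pos) / 2
  }
  # simple regression R-squared = squared Pearson correlation
  r2 <- function(yy) stats::cor(yy, mean_score)^2
  list(r2_linear = r2(fat_fraction), r2_log = r2(log(ff)))
}

#' STIR hyperintensity frequencies
#'
#' @param table a `visual_score_table` with `stir_*` 0/1 columns.
#' @return list with `pct_muscles` (percentage of all muscle entries
#'   flagged) and `pct_patients` (percentage of patients with at least one
#'   flag).
#' @export
stir_frequency <- function(table) {
  stir_cols <- grep("^stir_", names(table), value = TRUE)
  if (!length(stir_cols)) stop("score table has no stir_* columns")
  s <- as.matrix(table[, stir_cols, drop = FALSE])
  list(pct_muscles = 100 * mean(s == 1),
       pct_patients = 100 * mean(apply(s == 1, 1, any)))
}
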