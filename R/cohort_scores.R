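#' Muscle name sets used in visual scoring
#'
#' Ten thigh muscles (vastus medialis/lateralis/intermediaris, rectus
#' femoris, adductors, gracilis, sartorius, semimembranosus,
#' semitendinosus, biceps femoris) and six lower-leg muscles (tibialis
#' anterior/posterior, soleus, gastrocnemius lateralis/medialis,
#' peroneus), each graded bilaterally on the four-point fatty-infiltration
#' scale (1 normal ... 4 severe).
#'
#' @format character vectors.
#' @export
thigh_muscles <- c("VM", "VL", "VI", "RF", "Add", "G", "S", "SM", "ST", "BF")

#' @rdname thigh_muscles
#' @export
leg_muscles <- c("TA", "TP", "Sol", "GL", "GM", "P")

posterior_thigh <- c("Add", "SM", "ST", "BF")

#' Archetype mean visual scores of the three thigh imaging patterns
#'
#' Row 1: near-normal imaging (mean grade 1.7 in every muscle). Row 2:
#' posterior-dominant involvement (3.7 in the posterior compartment, 2.5
#' anteriorly). Row 3: diffuse severe infiltration (3.4 throughout).
#'
#' @return 3 x 10 matrix (clusters x thigh muscles).
#' @export
thigh_archetypes <- function() {
  a <- rbind(
    rep(1.7, length(thigh_muscles)),
    ifelse(thigh_muscles %in% posterior_thigh, 3.7, 2.5),
    rep(3.4, length(thigh_muscles))
  )
  dimnames(a) <- list(paste0("T", 1:3), thigh_muscles)
  a
}

#' Archetype mean visual scores of the three lower-leg imaging patterns
#'
#' Row 1: near-normal (1.2). Row 2: selective gastrocnemius medialis
#' involvement (3.0, other muscles below 2.2). Row 3: diffuse involvement
#' (2.8) sparing the tibialis posterior (1.5).
#'
#' @return 3 x 6 matrix (clusters x leg muscles).
#' @export
leg_archetypes <- function() {
  a <- rbind(
    rep(1.2, length(leg_muscles)),
    ifelse(leg_muscles == "GM", 3.0, 1.8),
    ifelse(leg_muscles == "TP", 1.5, 2.8)
  )
  dimnames(a) <- list(paste0("L", 1:3), leg_muscles)
  a
}

#' Generate a synthetic cohort visual-score table
#'
#' Simulates a cohort whose per-muscle T1 visual grades follow known
#' cluster archetypes: each patient's grade for a muscle side is the
#' archetype mean plus Gaussian noise, rounded to the nearest integer and
#' clipped to the 1-4 scale. Left and right sides are drawn independently,
#' so bilateral asymmetry arises naturally from the noise. STIR
#' hyperintensity flags are independent Bernoulli draws per muscle entry.
#'
#' @param n_per_cluster integer vector: patients per archetype (length =
#'   rows of `archetype_means`).
#' @param archetype_means clusters x muscles matrix of mean grades in
#'   \[1, 4\] with muscle column names; defaults to the three combined
#'   thigh + leg patterns (`cbind(thigh_archetypes(), leg_archetypes())`).
#' @param score_noise_sd grade noise standard deviation.
#' @param stir_rate probability of a STIR flag per muscle entry.
#' @param seed integer seed.
#' @return a `visual_score_table` data frame: `patient_id`,
#'   `true_cluster`, one `<muscle>_<L|R>` integer grade column per muscle
#'   side, and matching `stir_<muscle>_<L|R>` 0/1 columns.
#' @examples
#' tab <- make_cohort_scores(c(16, 10, 9), seed = 1)
#' dim(tab)
#' @export
make_cohort_scores <- function(n_per_cluster,
                               archetype_means = NULL,
                               score_noise_sd = 0.4,
                               stir_rate = 0.031,
                               seed = 1L) {
  if (is.null(archetype_means)) {
    archetype_means <- cbind(thigh_archetypes(), leg_archetypes())
  }
  archetype_means <- as.matrix(archetype_means)
  if (is.null(colnames(archetype_means))) {
    stop("archetype_means must have muscle column names")
  }
  if (any(archetype_means < 1 | archetype_means > 4)) {
    stop("invalid archetype: mean grades must lie in [1, 4]")
  }
  if (length(n_per_cluster) != nrow(archetype_means) || any(n_per_cluster < 1)) {
    stop("n_per_cluster must give >= 1 patient for each archetype row")
  }
  muscles <- colnames(archetype_means)
  sides <- c("L", "R")
  grade_cols <- as.vector(t(outer(muscles, sides, paste, sep = "_")))

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_total <- sum(n_per_cluster)
  cluster <- rep(seq_along(n_per_cluster), n_per_cluster)
  grades <- matrix(NA_integer_, n_total, length(grade_cols),
                   dimnames = list(NULL, grade_cols))
  for (p in seq_len(n_total)) {
    mu <- rep(archetype_means[cluster[p], ], each = length(sides))
    g <- round(mu + stats::rnorm(length(mu), sd = score_noise_sd))
    grades[p, ] <- pmin(pmax(as.integer(g), 1L), 4L)
  }
  stir <- matrix(stats::rbinom(n_total * length(grade_cols), 1, stir_rate),
                 n_total, length(grade_cols),
                 dimnames = list(NULL, paste0("stir_", grade_cols)))

  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n_total)),
                    true_cluster = cluster,
                    grades, stir, check.names = FALSE)
  class(out) <- c("visual_score_table", class(out))
  out
}

# split a score table into grade and stir matrices for one muscle set
score_matrix <- function(table, muscles = NULL) {
  if (is.null(muscles)) {
    nm <- names(table)
    grade_cols <- nm[grepl("^[A-Za-z]+_[LR]$", nm) & !startsWith(nm, "stir_")]
  } else {
    grade_cols <- as.vector(t(outer(muscles, c("L", "R"), paste, sep = "_")))
  }
  missing <- setdiff(grade_cols, names(table))
  if (length(missing)) stop("score table lacks columns: ", paste(missing, collapse = ", "))
  as.matrix(table[, grade_cols, drop = FALSE])
}
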