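#' Ground-truth compartment label codes used by the thigh phantom
#'
#' Integer codes of the per-pixel ground-truth label volume emitted by
#' [make_thigh_phantom()]. The codes are mutually exclusive and cover every
#' pixel of a slice.
#'
#' @format named integer vector.
#' @export
phantom_labels <- c(
  outside = 0L, skin = 1L, SAT = 2L, muscle = 3L, IMAT = 4L,
  cortical_bone = 5L, marrow = 6L, vessel = 7L
)

#' Specification of a synthetic thigh MR phantom
#'
#' Describes a single-femur thigh cross-section rendered with T1-weighted
#' contrast: adipose tissue and bone marrow bright, muscle and skin
#' mid-grey, cortical bone and background dark. The muscle compartment is
#' speckled with "moth-eaten" intramuscular fat (IMAT) blobs at a
#' controllable pixel fraction, a subcutaneous fat (SAT) ring separates
#' muscle from skin, and the rendered image is degraded by a smooth
#' multiplicative bias field and Rician noise.
#'
#' @param image_size pixels per side of the square slice.
#' @param limb_radius outer limb (skin) radius, px.
#' @param sat_thickness SAT ring thickness, px.
#' @param skin_thickness skin rim thickness, px.
#' @param bone_center femur centre `c(x, y)`; default slice centre.
#' @param bone_outer_radius outer cortical bone radius, px.
#' @param marrow_radius marrow radius, px (inside the cortical ring).
#' @param imat_fraction_target fraction in \[0, 0.95\] of the muscle
#'   compartment converted to IMAT speckle.
#' @param speckle_grain characteristic IMAT blob size, px (Gaussian
#'   correlation length of the thresholded random field).
#' @param n_slices number of axial slices in the volume.
#' @param gradient optional `c(proximal, distal)` pair; when given, the
#'   per-slice IMAT target is linearly interpolated between the two
#'   endpoints (slice 1 = most proximal). Default endpoints of
#'   `c(0.116, 0.272)` emulate the proximal-to-distal infiltration
#'   gradient typical of dystrophic thighs.
#' @param intensity_means named mean signal per tissue; must be strictly
#'   ordered fat > marrow > muscle > skin > cortical_bone >= background.
#' @param noise_sigma Rician noise scale (per-channel Gaussian sd). The
#'   default gives a muscle signal-to-noise ratio of about 15.
#' @param bias_field_amplitude relative amplitude (<= 0.2) of the smooth
#'   multiplicative intensity inhomogeneity.
#' @param n_vessels number of bright vessel lumina placed inside muscle.
#' @param vessel_radius vessel radius, px.
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @param seed integer seed; the same spec and seed reproduce the volume
#'   bit for bit.
#' @return an object of class `phantom_spec`.
#' @seealso [make_thigh_phantom()]
#' @export
phantom_spec <- function(image_size = 128,
                         limb_radius = 56,
                         sat_thickness = 8,
                         skin_thickness = 2,
                         bone_center = NULL,
                         bone_outer_radius = 10,
                         marrow_radius = 6,
                         imat_fraction_target = 0.2,
                         speckle_grain = 3,
                         n_slices = 1,
                         gradient = NULL,
                         intensity_means = c(fat = 240, marrow = 220, muscle = 110,
                                             skin = 90, cortical_bone = 25, background = 20),
                         noise_sigma = 7.3,
                         bias_field_amplitude = 0.05,
                         n_vessels = 0,
                         vessel_radius = 2,
                         pixel_spacing = 2.5,
                         seed = 1L) {
  if (is.null(bone_center)) bone_center <- rep((image_size + 1) / 2, 2)
  spec <- structure(
    list(image_size = as.integer(image_size), limb_radius = limb_radius,
         sat_thickness = sat_thickness, skin_thickness = skin_thickness,
         bone_center = bone_center, bone_outer_radius = bone_outer_radius,
         marrow_radius = marrow_radius,
         imat_fraction_target = imat_fraction_target,
         speckle_grain = speckle_grain, n_slices = as.integer(n_slices),
         gradient = gradient, intensity_means = intensity_means,
         noise_sigma = noise_sigma,
         bias_field_amplitude = bias_field_amplitude,
         n_vessels = as.integer(n_vessels), vessel_radius = vessel_radius,
         pixel_spacing = pixel_spacing, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  m <- spec$intensity_means
  need <- c("fat", "marrow", "muscle", "skin", "cortical_bone", "background")
  if (!all(need %in% names(m))) {
    stop("invalid phantom spec: intensity_means must name ", paste(need, collapse = ", "))
  }
  if (spec$sat_thickness + spec$bone_outer_radius >= spec$limb_radius) {
    stop("invalid phantom spec: sat_thickness + bone_outer_radius must be < limb_radius")
  }
  if (spec$skin_thickness + spec$sat_thickness + spec$bone_outer_radius >= spec$limb_radius) {
    stop("invalid phantom spec: skin + SAT + bone must nest inside limb_radius")
  }
  if (spec$marrow_radius >= spec$bone_outer_radius) {
    stop("invalid phantom spec: marrow_radius must be < bone_outer_radius")
  }
  if (spec$imat_fraction_target < 0 || spec$imat_fraction_target > 0.95) {
    stop("invalid phantom spec: imat_fraction_target must lie in [0, 0.95]")
  }
  if (!is.null(spec$gradient)) {
    if (length(spec$gradient) != 2 || any(spec$gradient < 0) || any(spec$gradient > 0.95)) {
      stop("invalid phantom spec: gradient must be two fractions in [0, 0.95]")
    }
  }
  ord <- m[c("fat", "marrow", "muscle", "skin", "cortical_bone")]
  if (any(diff(ord) >= 0)) {
    stop("invalid phantom spec: intensity means must be strictly ordered fat > marrow > muscle > skin > cortical_bone")
  }
  if (m["background"] > m["cortical_bone"]) {
    stop("invalid phantom spec: background intensity must not exceed cortical bone")
  }
  if (spec$bias_field_amplitude < 0 || spec$bias_field_amplitude > 0.2) {
    stop("invalid phantom spec: bias_field_amplitude must lie in [0, 0.2]")
  }
  if (spec$limb_radius >= spec$image_size / 2) {
    stop("invalid phantom spec: limb_radius must fit inside the image")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Thigh phantom spec:", x$image_size, "x", x$image_size, "px,",
      x$n_slices, "slice(s)\n")
  cat("  limb radius", x$limb_radius, "px; SAT", x$sat_thickness,
      "px; skin", x$skin_thickness, "px\n")
  tgt <- if (is.null(x$gradient)) sprintf("%.3f (constant)", x$imat_fraction_target)
         else sprintf("%.3f -> %.3f (proximal -> distal)", x$gradient[1], x$gradient[2])
  cat("  IMAT target", tgt, "; speckle grain", x$speckle_grain, "px\n")
  cat("  noise sigma", x$noise_sigma, "; bias amplitude", x$bias_field_amplitude,
      "; seed", x$seed, "\n")
  invisible(x)
}

# squared distance of every pixel centre to (cx, cy)
.dist2_grid <- function(size, cx, cy) {
  outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, "+")
}

# smooth multiplicative bias field in [1 - a, 1 + a]; bump centre drawn
# from the current RNG stream
.bias_field <- function(size, amplitude) {
  if (amplitude <= 0) return(matrix(1, size, size))
  cx <- stats::runif(1, size * 0.25, size * 0.75)
  cy <- stats::runif(1, size * 0.25, size * 0.75)
  w <- size * 0.6
  bump <- exp(-.dist2_grid(size, cx, cy) / (2 * w^2))
  bump <- (bump - min(bump)) / (max(bump) - min(bump))
  1 + amplitude * (2 * bump - 1)
}

#' Generate a synthetic thigh MR volume with known ground truth
#'
#' Renders each axial slice from concentric geometry (skin rim, SAT ring,
#' fascia-enclosed muscle, cortical bone ring with bright marrow), converts
#' a controlled fraction of muscle pixels to IMAT speckle by thresholding a
#' Gaussian-smoothed random field at the quantile matching the per-slice
#' target, applies a multiplicative bias field, and adds Rician noise
#' (magnitude of a complex Gaussian perturbation).
#'
#' The realized IMAT fraction is exact up to one-pixel quantization: the
#' top `round(target * n_muscle)` field values inside the muscle mask are
#' converted.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `thigh_phantom` with elements
#'   \describe{
#'     \item{volume}{`image_volume`: the noisy rendered volume.}
#'     \item{truth}{`phantom_truth`: `label_volume` (codes of
#'       [phantom_labels]), `true_fat_fraction` per slice (IMAT pixel count
#'       over IMAT + muscle), `limb_contour` and `muscle_contour` polygons,
#'       `clean_volume` (pre-bias, pre-noise intensities), and the per-slice
#'       IMAT targets.}
#'   }
#' @examples
#' ph <- make_thigh_phantom(phantom_spec(imat_fraction_target = 0.3, seed = 7))
#' ph$truth$true_fat_fraction
#' @export
make_thigh_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  S <- spec$image_size
  ns <- spec$n_slices
  m <- spec$intensity_means
  cx <- (S + 1) / 2; cy <- (S + 1) / 2
  bx <- spec$bone_center[1]; by <- spec$bone_center[2]

  d2_limb <- .dist2_grid(S, cx, cy)
  d2_bone <- .dist2_grid(S, bx, by)
  r_skin_in <- spec$limb_radius - spec$skin_thickness
  r_fascia <- r_skin_in - spec$sat_thickness

  limb_mask <- d2_limb <= spec$limb_radius^2
  skin_mask <- limb_mask & d2_limb > r_skin_in^2
  sat_mask <- d2_limb <= r_skin_in^2 & d2_limb > r_fascia^2
  fascia_mask <- d2_limb <= r_fascia^2
  bone_mask <- d2_bone <= spec$bone_outer_radius^2
  marrow_mask <- d2_bone <= spec$marrow_radius^2
  cortical_mask <- bone_mask & !marrow_mask
  muscle_base <- fascia_mask & !bone_mask

  # fixed per-spec vessel positions: evenly spaced on a mid-muscle circle
  vessel_mask <- matrix(FALSE, S, S)
  if (spec$n_vessels > 0) {
    rv <- (r_fascia + spec$bone_outer_radius) / 2
    th <- 2 * pi * (seq_len(spec$n_vessels) - 1) / spec$n_vessels + 0.4
    for (k in seq_len(spec$n_vessels)) {
      vm <- .dist2_grid(S, bx + rv * cos(th[k]), by + rv * sin(th[k])) <=
        spec$vessel_radius^2
      vessel_mask <- vessel_mask | (vm & muscle_base)
    }
  }
  muscle_base <- muscle_base & !vessel_mask

  targets <- if (is.null(spec$gradient)) {
    rep(spec$imat_fraction_target, ns)
  } else if (ns == 1) {
    mean(spec$gradient)
  } else {
    seq(spec$gradient[1], spec$gradient[2], length.out = ns)
  }

  labels <- array(phantom_labels[["outside"]], dim = c(S, S, ns))
  clean <- array(m[["background"]], dim = c(S, S, ns))
  noisy <- array(0, dim = c(S, S, ns))
  truefrac <- numeric(ns)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n_muscle_base <- sum(muscle_base)
  for (z in seq_len(ns)) {
    lab <- matrix(phantom_labels[["outside"]], S, S)
    lab[skin_mask] <- phantom_labels[["skin"]]
    lab[sat_mask] <- phantom_labels[["SAT"]]
    lab[muscle_base] <- phantom_labels[["muscle"]]
    lab[cortical_mask] <- phantom_labels[["cortical_bone"]]
    lab[marrow_mask] <- phantom_labels[["marrow"]]
    lab[vessel_mask] <- phantom_labels[["vessel"]]

    # moth-eaten IMAT speckle: smoothed random field, exact top-k threshold
    k <- round(targets[z] * n_muscle_base)
    if (k > 0) {
      field <- matrix(stats::rnorm(S * S), S, S)
      field <- as.matrix(EBImage::gblur(field, sigma = spec$speckle_grain))
      fv <- field[muscle_base]
      idx <- which(muscle_base)
      imat_idx <- idx[order(fv, decreasing = TRUE)[seq_len(k)]]
      lab[imat_idx] <- phantom_labels[["IMAT"]]
    }

    n_imat <- sum(lab == phantom_labels[["IMAT"]])
    n_mus <- sum(lab == phantom_labels[["muscle"]])
    truefrac[z] <- if (n_imat + n_mus > 0) n_imat / (n_imat + n_mus) else NA_real_

    img <- matrix(m[["background"]], S, S)
    img[lab == phantom_labels[["skin"]]] <- m[["skin"]]
    img[lab == phantom_labels[["SAT"]]] <- m[["fat"]]
    img[lab == phantom_labels[["muscle"]]] <- m[["muscle"]]
    img[lab == phantom_labels[["IMAT"]]] <- m[["fat"]]
    img[lab == phantom_labels[["cortical_bone"]]] <- m[["cortical_bone"]]
    img[lab == phantom_labels[["marrow"]]] <- m[["marrow"]]
    img[lab == phantom_labels[["vessel"]]] <- m[["fat"]]

    bias <- .bias_field(S, spec$bias_field_amplitude)
    biased <- img * bias
    if (spec$noise_sigma > 0) {
      g1 <- matrix(stats::rnorm(S * S, sd = spec$noise_sigma), S, S)
      g2 <- matrix(stats::rnorm(S * S, sd = spec$noise_sigma), S, S)
      out <- sqrt((biased + g1)^2 + g2^2)
    } else {
      out <- biased
    }

    labels[, , z] <- lab
    clean[, , z] <- img
    noisy[, , z] <- out
  }

  vol <- image_volume(noisy, pixel_spacing = spec$pixel_spacing)
  truth <- structure(
    list(label_volume = labels,
         true_fat_fraction = truefrac,
         imat_target_per_slice = targets,
         limb_contour = circle_polygon(cx, cy, spec$limb_radius, 120),
         muscle_contour = circle_polygon(cx, cy, r_fascia, 120),
         clean_volume = clean,
         spec = spec),
    class = "phantom_truth"
  )
  structure(list(volume = vol, truth = truth), class = "thigh_phantom")
}

#' @export
print.thigh_phantom <- function(x, ...) {
  print(x$truth$spec)
  cat(sprintf("  true fat fraction: %s\n",
              paste(sprintf("%.3f", x$truth$true_fat_fraction), collapse = " ")))
  invisible(x)
}
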