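#' Construct an image volume
#'
#' An ordered stack of 2-D axial slices (slice 1 = most proximal) with an
#' in-plane pixel spacing. The pixel array is stored `[row, col, slice]`.
#'
#' @param data 2-D matrix (single slice) or 3-D array.
#' @param pixel_spacing in-plane pixel spacing in mm.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, pixel_spacing = 2.5) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = data, pixel_spacing = pixel_spacing),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_volume: %d x %d px, %d slice(s), %.3g mm/px\n",
              d[1], d[2], d[3], x$pixel_spacing))
  invisible(x)
}

#' Number of slices in a volume
#' @param vol an `image_volume`.
#' @export
n_slices <- function(vol) dim(vol$data)[3]

#' Extract one slice as a matrix
#' @param vol an `image_volume`.
#' @param z slice index (1 = most proximal).
#' @export
get_slice <- function(vol, z) {
  stopifnot(z >= 1, z <= n_slices(vol))
  vol$data[, , z]
}

#' Read an MR volume from disk
#'
#' NIfTI (`.nii`, `.nii.gz`) volumes are read with their header pixel
#' spacing; single-slice PNG or TIFF images are accepted for fixtures and
#' read as one-slice volumes with a default spacing of 2.5 mm/px (with a
#' warning, since raster formats carry no spacing).
#'
#' @param path file path.
#' @return an [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop("format error reading NIfTI '", path,
                                             "': ", conditionMessage(e)))
    arr <- as.array(img)
    arr <- array(as.vector(arr), dim = dim(arr))  # strip NIfTI attributes
    if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
    if (length(dim(arr)) != 3) stop("format error: expected a 2-D or 3-D NIfTI, got ",
                                    length(dim(arr)), " dimensions")
    spacing <- RNifti::pixdim(img)[1]
    if (!is.finite(spacing) || spacing <= 0) {
      warning("missing pixel spacing in NIfTI header; assuming 2.5 mm/px")
      spacing <- 2.5
    }
    return(image_volume(arr, pixel_spacing = spacing))
  }
  if (grepl("\\.png$", lower)) {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stop("format error reading PNG '", path,
                                             "': ", conditionMessage(e)))
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    warning("PNG carries no pixel spacing; assuming 2.5 mm/px")
    return(image_volume(arr * 65535, pixel_spacing = 2.5))
  }
  if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    arr <- tiff::readTIFF(path)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    warning("TIFF carries no pixel spacing; assuming 2.5 mm/px")
    return(image_volume(arr * 65535, pixel_spacing = 2.5))
  }
  stop("format error: unsupported volume format: ", path)
}

#' Write a volume (or integer label volume) as NIfTI
#'
#' @param vol an [image_volume()] or a 3-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixel_spacing spacing written to the header when `vol` is a bare
#'   array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, pixel_spacing = 2.5) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data
    pixel_spacing <- vol$pixel_spacing
  } else {
    arr <- vol
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(pixel_spacing, length(dim(arr)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a single slice as 16-bit PNG
#'
#' Intensities are clipped to `[0, 65535]` and scaled to the PNG range.
#'
#' @param slice numeric matrix.
#' @param path output path.
#' @export
write_slice_png <- function(slice, path) {
  x <- pmin(pmax(slice, 0), 65535) / 65535
  png::writePNG(x, path)
  invisible(path)
}

#' Write contours to CSV
#'
#' Long format: `slice_index, contour, point_index, x, y` — one row per
#' control point.
#'
#' @param contours named list (e.g. `list(limb = ..., muscle = ...)`) or a
#'   list of such lists, one per slice.
#' @param path output CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  if (!is.null(names(contours)) && all(vapply(contours, is.matrix, TRUE))) {
    contours <- list(contours)
  }
  rows <- list()
  for (z in seq_along(contours)) {
    for (nm in names(contours[[z]])) {
      pts <- contours[[z]][[nm]]
      if (is.null(pts)) next
      rows[[length(rows) + 1]] <- data.frame(
        slice_index = z, contour = nm, point_index = seq_len(nrow(pts)),
        x = pts[, 1], y = pts[, 2])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a manual contour from a polygon-vertex CSV
#'
#' The file must contain `x` and `y` columns (optionally `point_index`,
#' used for ordering). Fewer than three vertices is a geometry error.
#'
#' @param path CSV path.
#' @return an (n x 2) vertex matrix.
#' @export
read_contour_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read contour: no such file: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("parse error reading contour '", path,
                                          "': ", conditionMessage(e)))
  if (!all(c("x", "y") %in% names(df))) {
    stop("parse error: contour CSV must have 'x' and 'y' columns")
  }
  if ("point_index" %in% names(df)) df <- df[order(df$point_index), ]
  pts <- unname(as.matrix(df[, c("x", "y")]))
  if (nrow(pts) < 3 || any(!is.finite(pts))) {
    stop("geometry error: contour must be a closed polygon with >= 3 finite vertices")
  }
  # tolerate an explicitly closed ring
  if (nrow(pts) > 3 && all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), ]
  pts
}
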