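# build a compartment_masks object directly for the arithmetic tests
fake_masks <- function(n_imat, n_muscle, size = 40) {
  m <- matrix(compartment_codes[["outside"]], size, size)
  if (n_imat > 0) m[seq_len(n_imat)] <- compartment_codes[["IMAT"]]
  if (n_muscle > 0) m[size * size - seq_len(n_muscle) + 1] <- compartment_codes[["muscle"]]
  structure(m, class = c("compartment_masks", class(m)), source = "automatic",
            limb = circle_polygon(20, 20, 18, 30),
            muscle = circle_polygon(20, 20, 10, 30))
}

test_that("bone detection recovers the femur and never leaks marrow into IMAT", {
  ph <- test_phantom(imat = 0.2, seed = 19)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  truth <- ph$truth
  bone <- detect_bone(tmap, truth$muscle_contour)
  true_bone <- matrix(truth$label_volume[, , 1] %in%
                        phantom_labels[c("cortical_bone", "marrow")],
                      128, 128)
  expect_gte(dice_coefficient(bone, true_bone), 0.9)
  masks <- partition_compartments(tmap, truth$limb_contour, truth$muscle_contour, bone)
  imat <- masks == compartment_codes[["IMAT"]]
  expect_equal(sum(imat & true_bone), 0)
})

test_that("a slice without a dark marrow-cored component yields an empty bone mask", {
  m <- matrix(tissue_classes[["background_bone_vessel"]], 64, 64)
  d2 <- outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+")
  m[d2 <= 25^2] <- tissue_classes[["muscle"]]
  tm <- as_tissue_map(m)
  expect_warning(bone <- detect_bone(tm, circle_polygon(32.5, 32.5, 20, 40)),
                 "bone")
  expect_equal(sum(bone), 0)
})

test_that("oracle contours reproduce the ground-truth compartments", {
  ph <- test_phantom(imat = 0.2, seed = 25)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  truth <- ph$truth
  bone <- detect_bone(tmap, truth$muscle_contour)
  masks <- partition_compartments(tmap, truth$limb_contour, truth$muscle_contour, bone)
  lab <- truth$label_volume[, , 1]
  pairs <- list(SAT = "SAT", IMAT = "IMAT", muscle = "muscle",
                bone = c("cortical_bone", "marrow"))
  for (nm in names(pairs)) {
    got <- masks == compartment_codes[[nm]]
    want <- matrix(lab %in% phantom_labels[pairs[[nm]]], 128, 128)
    expect_gte(dice_coefficient(got, want), 0.97)
  }
  # conservation: the five compartments partition the slice exactly
  counts <- table(factor(as.integer(masks), levels = compartment_codes))
  expect_equal(sum(counts), 128 * 128)
})

test_that("a zero-infiltration phantom yields an empty IMAT compartment", {
  ph <- test_phantom(imat = 0, seed = 26, noise_sigma = 0, bias_field_amplitude = 0)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  truth <- ph$truth
  masks <- partition_compartments(tmap, truth$limb_contour, truth$muscle_contour,
                                  detect_bone(tmap, truth$muscle_contour))
  expect_equal(sum(masks == compartment_codes[["IMAT"]]), 0)
  expect_equal(fat_fraction(masks), 0)
})

test_that("fat fraction follows the pixel-count definition", {
  expect_equal(fat_fraction(fake_masks(0, 1000)), 0)
  expect_equal(fat_fraction(fake_masks(500, 500)), 0.5)
  expect_error(fat_fraction(fake_masks(0, 0)), "undefined fraction")
})

test_that("middle-slice selection centres the window with proximal tie-break", {
  expect_equal(middle_slice_indices(50, 20), 16:35)  # 0-based 15..34
  expect_equal(middle_slice_indices(41, 20), 11:30)  # tie resolved proximally
  expect_equal(middle_slice_indices(10, 20), 1:10)
})

test_that("aggregation averages the middle slices and warns when short", {
  r <- fat_fraction_result(rep(0.25, 50))
  agg <- aggregate_fraction(r, 20)
  expect_equal(agg$aggregate, 0.25)
  expect_equal(agg$slices_used, 16:35)

  series <- seq(0.116, 0.272, length.out = 40)
  agg2 <- aggregate_fraction(fat_fraction_result(series), 20)
  expect_equal(agg2$aggregate, mean(series[middle_slice_indices(40, 20)]))
  expect_lt(abs(agg2$aggregate - mean(c(0.116, 0.272))), 0.02)

  short <- aggregate_fraction(fat_fraction_result(c(0.1, 0.2, 0.3)), 20)
  expect_equal(short$aggregate, 0.2)
  expect_match(short$warnings, "valid slice")

  flagged <- fat_fraction_result(c(0.1, NA, 0.3),
                                 flags = list(character(0), "fail", character(0)))
  expect_error(aggregate_fraction(fat_fraction_result(c(NA, NA)), 2), "aggregation error")
  # window {1, 2} loses its flagged slice; the surviving one is used, warned
  agg_f <- aggregate_fraction(flagged, 2)
  expect_equal(agg_f$aggregate, 0.1)
  expect_match(agg_f$warnings, "valid slice")
})

test_that("failure heuristics pass a clean slice and catch severe infiltration", {
  ph <- test_phantom(imat = 0.2, seed = 27)
  res <- run_pipeline(ph$volume, pipeline_config(seed = 2))
  expect_length(attr(res, "slices")[[1]]$flags, 0)

  severe <- test_phantom(imat = 0.85, seed = 27)
  res2 <- run_pipeline(severe$volume, pipeline_config(seed = 2))
  fl <- unlist(attr(res2, "slices")[[1]]$flags)
  expect_gt(length(fl), 0)
  expect_true(any(grepl("SAT/IMAT delimitation", fl)))
})

test_that("an empty muscle class is flagged by the failure predicate", {
  m <- matrix(tissue_classes[["fat"]], 64, 64)
  tm <- as_tissue_map(m)
  masks <- structure(matrix(compartment_codes[["IMAT"]], 64, 64),
                     class = c("compartment_masks", "matrix", "array"),
                     source = "automatic",
                     limb = circle_polygon(32, 32, 30, 40),
                     muscle = circle_polygon(32, 32, 20, 40))
  fl <- flag_failure(masks, tm)
  expect_true(fl$failed)
  expect_true(any(grepl("empty muscle class", fl$reasons)))
})

test_that("manual contours reproduce ground truth and are deterministic", {
  ph <- test_phantom(imat = 0.3, seed = 29)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  truth <- ph$truth
  out1 <- apply_manual_contours(tmap, truth$limb_contour, truth$muscle_contour)
  expect_equal(out1$result$source, "manual_corrected")
  expect_lt(abs(out1$result$aggregate - truth$true_fat_fraction[1]), 0.02)
  # identical inputs give identical results (ICC of a repeat would be 1)
  out2 <- apply_manual_contours(tmap, truth$limb_contour, truth$muscle_contour)
  expect_identical(out1$result$aggregate, out2$result$aggregate)
  expect_identical(as.integer(out1$masks), as.integer(out2$masks))
})

test_that("a limb contour nested inside the muscle contour is a geometry error", {
  ph <- test_phantom(imat = 0.2, seed = 30)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  truth <- ph$truth
  expect_error(apply_manual_contours(tmap, truth$muscle_contour, truth$limb_contour),
               "geometry error")
})

test_that("manual contours can be read from polygon CSV files", {
  ph <- test_phantom(imat = 0.2, seed = 31)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  truth <- ph$truth
  limb_csv <- tempfile(fileext = ".csv")
  mus_csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = truth$limb_contour[, 1], y = truth$limb_contour[, 2]),
            limb_csv, row.names = FALSE)
  write.csv(data.frame(x = truth$muscle_contour[, 1], y = truth$muscle_contour[, 2]),
            mus_csv, row.names = FALSE)
  out <- apply_manual_contours(tmap, limb_csv, mus_csv)
  expect_lt(abs(out$result$aggregate - truth$true_fat_fraction[1]), 0.02)

  bad <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(apply_manual_contours(tmap, bad, mus_csv), "parse error")
  open_poly <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(1, 2), y = c(1, 2)), open_poly, row.names = FALSE)
  expect_error(apply_manual_contours(tmap, open_poly, mus_csv), "geometry error")
})

test_that("pipeline fat fraction rises monotonically with infiltration", {
  fr <- vapply(c(0.05, 0.2, 0.4), function(t) {
    ph <- test_phantom(imat = t, seed = 33)
    run_pipeline(ph$volume, pipeline_config(seed = 2))$per_slice[1]
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
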