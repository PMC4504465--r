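test_that("snake configuration is validated", {
  expect_error(snake_config(alpha = -1), "weights")
  expect_error(snake_config(alpha = 0, beta = 0, gamma = 0), "weights")
  expect_error(snake_config(n_points = 3), "n_points")
  expect_error(snake_config(search_window_px = 4), "search_window")
})

test_that("snake energy has its closed form on a regular polygon", {
  d <- disk_target()
  N <- 50
  pts <- circle_polygon(d$center, d$center, 30, N)
  s <- sqrt(sum((pts[2, ] - pts[1, ])^2))  # chord length
  cfg <- snake_config(alpha = 1, beta = 0, gamma = 0)
  expect_equal(snake_energy(pts, d$mask, cfg), N * s^2, tolerance = 1e-10)
})

test_that("snake energy matches an independent term-by-term computation", {
  d <- disk_target()
  field <- image_energy_field(d$mask, 3)
  set.seed(14)
  pts <- cbind(runif(8, 30, 90), runif(8, 30, 90))
  cfg <- snake_config(alpha = 0.1, beta = 0.6, gamma = 0.3, n_points = 8)
  # brute-force oracle: loop the three quoted formulas with cyclic indexing
  oracle <- 0
  n <- nrow(pts)
  for (i in seq_len(n)) {
    pm <- pts[if (i == 1) n else i - 1, ]
    pp <- pts[if (i == n) 1 else i + 1, ]
    e_cont <- sum((pts[i, ] - pm)^2)
    e_curv <- sum((pm - 2 * pts[i, ] + pp)^2)
    e_img <- field[round(pts[i, 2]), round(pts[i, 1])]
    oracle <- oracle + 0.1 * e_cont + 0.6 * e_curv + 0.3 * e_img
  }
  expect_equal(snake_energy(pts, d$mask, cfg), oracle, tolerance = 1e-10)
})

test_that("collinear equally spaced points contribute zero curvature energy", {
  # rectangle-ish contour with a long straight run; compare beta-only energy
  # to the same contour with the straight run removed from the sum by hand
  pts <- rbind(c(10, 10), c(20, 10), c(30, 10), c(40, 10),
               c(40, 40), c(10, 40))
  d <- disk_target()
  cfg <- snake_config(alpha = 0, beta = 1, gamma = 0, n_points = 6)
  e <- snake_energy(pts, d$mask, cfg)
  # interior points of the straight run (indices 2 and 3) are collinear and
  # equally spaced: their curvature terms vanish, so the energy equals the
  # sum over the four corner points only
  corner_terms <- 0
  n <- nrow(pts)
  for (i in c(1, 4, 5, 6)) {
    pm <- pts[if (i == 1) n else i - 1, ]
    pp <- pts[if (i == n) 1 else i + 1, ]
    corner_terms <- corner_terms + sum((pm - 2 * pts[i, ] + pp)^2)
  }
  expect_equal(e, corner_terms, tolerance = 1e-12)
})

test_that("a contour point outside the image frame is an error", {
  d <- disk_target()
  pts <- circle_polygon(d$center, d$center, 80, 20)  # exceeds the 128 px frame
  expect_error(snake_energy(pts, d$mask, snake_config()), "out of bounds")
})

test_that("the snake converges onto a disk boundary from outside", {
  d <- disk_target()
  init <- circle_polygon(d$center, d$center, d$radius + 10, 50)
  fit <- evolve_contour(init, d$mask, snake_config())
  expect_true(fit$converged)
  expect_equal(nrow(fit$points), 50)
  expect_lt(contour_to_circle_hausdorff(fit$points, d$center, d$center, d$radius), 2)
  # greedy sweeps never increase the frozen-neighbour local energy
  expect_true(all(fit$energy_trace$energy_end <=
                    fit$energy_trace$energy_start + 1e-9))
})

test_that("an initialization on the boundary of a convex target stays put", {
  d <- disk_target()
  init <- circle_polygon(d$center, d$center, d$radius, 50)
  fit <- evolve_contour(init, d$mask, snake_config())
  expect_lt(contour_to_circle_hausdorff(fit$points, d$center, d$center, d$radius), 1)
})

test_that("with gamma = 0 an irregular contour regularizes without energy increase", {
  d <- disk_target()
  set.seed(3)
  th <- seq(0, 2 * pi, length.out = 41)[1:40]
  r <- 35 + 8 * sin(5 * th) + rnorm(40, 0, 2)
  init <- cbind(d$center + r * cos(th), d$center + r * sin(th))
  fit <- evolve_contour(init, d$mask,
                        snake_config(alpha = 0.3, beta = 0.7, gamma = 0,
                                     n_points = 40, max_iter = 60))
  expect_true(all(fit$energy_trace$energy_end <=
                    fit$energy_trace$energy_start + 1e-9))
  # shape is more regular: spread of the radius profile shrinks
  r_out <- sqrt((fit$points[, 1] - d$center)^2 + (fit$points[, 2] - d$center)^2)
  expect_lt(stats::sd(r_out), stats::sd(r))
  expect_lte(polygon_area(fit$points), polygon_area(init) + 1e-9)
})

test_that("the result is invariant to cyclic rotation of the initial ordering", {
  d <- disk_target()
  init <- circle_polygon(d$center, d$center, d$radius + 8, 50)
  f1 <- evolve_contour(init, d$mask, snake_config())
  rot <- init[c(18:50, 1:17), ]
  f2 <- evolve_contour(rot, d$mask, snake_config())
  expect_equal(f1$points, f2$points)
})

test_that("limb and muscle contours fit a clean phantom accurately", {
  ph <- test_phantom(imat = 0, seed = 21)
  tmap <- cluster_slice(get_slice(ph$volume, 1), seed = 2)
  fit <- fit_limb_and_muscle_contours(clean_tissue_map(tmap))
  expect_false(fit$failure)
  lab <- ph$truth$label_volume[, , 1]
  true_limb_area <- sum(lab != phantom_labels[["outside"]])
  true_fascia <- matrix(lab %in% phantom_labels[c("muscle", "IMAT", "cortical_bone",
                                                  "marrow", "vessel")],
                        nrow(lab), ncol(lab))
  expect_lt(abs(polygon_area(fit$limb$points) - true_limb_area) / true_limb_area, 0.02)
  expect_lt(abs(polygon_area(fit$muscle$points) - sum(true_fascia)) / sum(true_fascia),
            0.03)
  mc <- rasterize_polygon(fit$muscle$points, dim(lab))
  expect_gte(dice_coefficient(mc, true_fascia), 0.98)
  # muscle contour nested in limb contour
  expect_true(all(points_in_polygon(fit$muscle$points[, 1], fit$muscle$points[, 2],
                                    fit$limb$points)))
})

test_that("an empty muscle class raises the failure flag, not an error", {
  m <- matrix(tissue_classes[["background_bone_vessel"]], 64, 64)
  d2 <- outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+")
  m[d2 <= 25^2] <- tissue_classes[["fat"]]
  fit <- fit_limb_and_muscle_contours(as_tissue_map(m, "cleaned"))
  expect_true(fit$failure)
  expect_match(fit$reasons, "empty muscle class")
})
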