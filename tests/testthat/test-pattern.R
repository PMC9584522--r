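# Primordia detection and pattern-attribute statistics.

test_that("row spacing variability matches hand-computed values", {
  expect_equal(row_spacing_variability(
    data.frame(x_um = c(0, 100, 200, 300), y_um = 0))$spacing_variability, 0)

  st <- row_spacing_variability(data.frame(x_um = c(0, 90, 200, 330),
                                           y_um = 0))
  expect_equal(st$distances_um, c(90, 110, 130))
  expect_equal(st$sd_um, 20)         # sample sd, n - 1 denominator
  expect_equal(st$mean_um, 110)
  expect_equal(st$spacing_variability, 20 / 110)

  expect_error(row_spacing_variability(data.frame(x_um = c(0, 1), y_um = 0)),
               class = "insufficient_points")
})

test_that("spacing statistics are scale equivariant (dimensionless)", {
  set.seed(5)
  pts <- data.frame(x_um = cumsum(runif(20, 80, 120)), y_um = rnorm(20, sd = 4))
  a <- row_spacing_variability(pts)$spacing_variability
  b <- row_spacing_variability(pts * 3.7)$spacing_variability
  expect_equal(a, b)

  arr <- generate_point_pattern(pattern_spec("hex_array", 40, 100, 0.15,
                                             seed = 2))$centers
  a2 <- delaunay_spacing_variability(arr)$spacing_variability
  b2 <- delaunay_spacing_variability(arr * 0.25)$spacing_variability
  expect_equal(a2, b2)
})

test_that("Delaunay statistic excludes hull-boundary edges and degenerates", {
  # co-circular square: every vertex is on the hull, nothing remains
  sq <- data.frame(x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 1))
  expect_error(delaunay_spacing_variability(sq),
               class = "no_interior_edges")
  expect_error(delaunay_spacing_variability(sq[1:3, ]),
               class = "degenerate_geometry")
  expect_error(delaunay_spacing_variability(
    data.frame(x_um = 1:10, y_um = 2 * (1:10))),
    class = "degenerate_geometry")

  # audit trail: used edges never touch the hull
  set.seed(9)
  pts <- data.frame(x_um = runif(30) * 100, y_um = runif(30) * 100)
  st <- delaunay_spacing_variability(pts)
  hull <- grDevices::chull(pts$x_um, pts$y_um)
  expect_false(any(st$edges_used %in% hull))
  expect_equal(st$n_edges_used + st$n_edges_excluded,
               nrow(delaunay_triangulate(pts)$edges))
})

test_that("density counts centers per mm^2 with half-open boundary rule", {
  cen <- data.frame(x_um = seq(50, 950, length.out = 14),
                    y_um = rep(500, 14))
  expect_equal(primordia_density(cen, c(0, 0, 1, 1)), 14)

  cen2 <- data.frame(x_um = seq(25, 275, length.out = 6), y_um = rep(100, 6))
  expect_equal(primordia_density(cen2, c(0, 0, 0.3, 1)), 20)  # 6 / 0.3

  expect_equal(primordia_density(data.frame(x_um = numeric(0),
                                            y_um = numeric(0)),
                                 c(0, 0, 1, 1)), 0)
  # low-coordinate edge counts, high-coordinate edge does not
  edge <- data.frame(x_um = c(0, 1000), y_um = c(0, 0))
  expect_equal(primordia_density(edge, c(0, 0, 1, 1)), 1)
  expect_error(primordia_density(cen, c(0, 0, 0, 1)), class = "invalid_roi")
})

test_that("component areas convert px -> mm^2 and unknown labels error", {
  # rasterized disc of radius 50 at (75, 75); the disc covers ~34.9% of
  # the frame, so a 0.34 quantile retains exactly the disc pixels
  m <- matrix(10, 150, 150)
  d2 <- (row(m) - 75)^2 + (col(m) - 75)^2
  m[d2 <= 50^2] <- 1000
  f <- image_frame(m, 1)
  det <- detect_primordia(f, threshold_quantile = 0.34,
                          gaussian_sigma_px = 0, min_area_px = 100)
  expect_equal(nrow(det$table), 1)
  expect_equal(det$table$area_px, sum(d2 <= 50^2))
  expect_equal(unname(primordium_areas(det, 1)),
               sum(d2 <= 50^2) * 1e-6)
  expect_equal(det$table$area_mm2, pi * 50^2 * 1e-6, tolerance = 0.01)
  expect_error(primordium_areas(det, 99), class = "unknown_label")

  # unit conversion at 2 um/px: single pixel = 4 um^2 = 4e-6 mm^2
  one <- matrix(c(rep(1, 99), 1000), 10, 10)
  d1 <- detect_primordia(image_frame(one, 2), 0.005, 0, 1)
  expect_equal(d1$table$area_mm2, 4e-6)
})

test_that("detector handles blank frames and respects the smoothing order", {
  expect_warning(empty <- detect_primordia(image_frame(matrix(0, 64, 64), 1)),
                 class = "constant_frame")
  expect_equal(nrow(empty$table), 0)
  expect_error(detect_primordia(image_frame(matrix(1:100, 10, 10), 1),
                                threshold_quantile = 1.2),
               class = "invalid_spec")
  # min_area_um2 is converted by pixel size (2 um/px: 1 px = 4 um^2)
  m <- matrix(10, 64, 64); m[20:29, 20:29] <- 1000  # 100 px component
  keep <- detect_primordia(image_frame(m, 2), 0.3, 0, min_area_um2 = 400)
  expect_equal(nrow(keep$table), 1)
  drop <- detect_primordia(image_frame(m, 2), 0.3, 0, min_area_um2 = 404)
  expect_equal(nrow(drop$table), 0)
})

test_that("detected components are 8-connected", {
  m <- matrix(10, 64, 64)
  for (k in 0:9) m[20 + k, 20 + k] <- 1000   # diagonal chain
  det <- detect_primordia(image_frame(m, 1), 9.5 / 64^2, 0, min_area_px = 10)
  expect_equal(nrow(det$table), 1)
  expect_equal(det$table$area_px, 10)
})

test_that("polygon areas and retractation follow the shoelace formula", {
  sq <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  tri <- data.frame(x = c(0, 4, 0), y = c(0, 0, 3))
  r <- polygon_area_retractation(sq, tri)
  expect_equal(r$area_t0_mm2, 100)
  expect_equal(r$area_t1_mm2, 6)

  shrunk <- data.frame(x = c(0, 10, 10, 0) * sqrt(0.9),
                       y = c(0, 0, 10, 10) * sqrt(0.9))
  expect_equal(polygon_area_retractation(sq, shrunk)$retractation_percent,
               10)

  bow <- data.frame(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(polygon_area_retractation(sq, bow), class = "invalid_polygon")
  expect_error(polygon_area_retractation(sq[1:2, ], tri),
               class = "invalid_polygon")
})
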