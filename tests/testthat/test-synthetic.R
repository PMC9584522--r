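# Synthetic-data generators: determinism, planted ground truth, flow models.

test_that("generators are pure functions of their spec (determinism)", {
  sp <- scene_spec(96, 96, noise_sd = 5, seed = 7)
  expect_identical(generate_texture(sp)$pixels, generate_texture(sp)$pixels)

  pat <- pattern_spec("row", 20, 100, 0.2, seed = 3)
  expect_identical(generate_point_pattern(pat), generate_point_pattern(pat))

  fl <- flow_spec("random_walk", random_step_sd_um = 2, n_frames = 3,
                  seed = 5)
  a <- generate_timelapse(scene_spec(64, 64, seed = 1), fl)
  b <- generate_timelapse(scene_spec(64, 64, seed = 1), fl)
  expect_identical(lapply(a$frames, `[[`, "pixels"),
                   lapply(b$frames, `[[`, "pixels"))
  # RNG state of the session is untouched
  set.seed(42); x <- rnorm(1)
  set.seed(42); invisible(generate_texture(sp)); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("invalid specs are rejected with typed conditions", {
  expect_error(scene_spec(0, 10), class = "invalid_spec")
  expect_error(scene_spec(10, 10, pixel_size_um = -1), class = "invalid_spec")
  expect_error(scene_spec(10, 10, texture_stretch_ratio = 0.5),
               class = "invalid_spec")
  expect_error(pattern_spec(spacing_cv = -0.1), class = "invalid_spec")
  expect_error(flow_spec("vortex"), class = "invalid_spec")
  expect_error(flow_spec("none", n_frames = 1), class = "invalid_spec")
  expect_error(flow_spec("sink"), class = "invalid_spec")
})

test_that("row patterns: zero jitter is exactly regular, gaps stay positive", {
  pp <- generate_point_pattern(pattern_spec("row", 5, 100, 0))
  expect_equal(pp$centers$x_um, c(0, 100, 200, 300, 400))
  expect_equal(pp$centers$y_um, rep(0, 5))
  expect_identical(pp$realized_cv, 0)

  # truncation: no gap below 10% of the mean even at large CV
  pp2 <- generate_point_pattern(pattern_spec("row", 200, 50, 0.5, seed = 11))
  gaps <- diff(pp2$centers$x_um)
  expect_true(all(gaps >= 0.1 * 50))
  expect_equal(pp2$realized_cv, sd(gaps) / mean(gaps))
})

test_that("hex lattice with zero jitter has zero interior edge-length CV", {
  pp <- generate_point_pattern(pattern_spec("hex_array", 36, 100, 0))
  st <- delaunay_spacing_variability(pp$centers)
  expect_lt(st$spacing_variability, 1e-10)
  expect_gt(st$n_edges_excluded, 0)  # border edges were dropped
})

test_that("planted blobs carry ground-truth areas and sub-threshold flags", {
  scene <- scene_spec(256, 256, noise_sd = 0, seed = 11)
  centers <- data.frame(x_um = c(60, 128, 200), y_um = c(60, 190, 120))
  gpi <- generate_primordia_image(scene,
                                  pattern_spec(blob_radius_um = 30,
                                               blob_peak_intensity = 300),
                                  centers = centers, min_area_px = 1000)
  expect_equal(nrow(gpi$truth), 3)
  expect_true(all(!gpi$truth$sub_threshold))
  det <- detect_primordia(gpi$frame, 0.30, gaussian_sigma_px = 5,
                          min_area_px = 1000)
  expect_equal(nrow(det$table), 3)
  # truth areas approximate the detected component areas
  expect_equal(sort(det$table$area_px), sort(gpi$truth$area_px),
               tolerance = 0.15)

  # a tiny blob is flagged sub_threshold and not detected
  gpi2 <- generate_primordia_image(scene,
                                   pattern_spec(blob_radius_um = 8,
                                                blob_peak_intensity = 300),
                                   centers = centers[1, , drop = FALSE],
                                   min_area_px = 1000)
  expect_true(gpi2$truth$sub_threshold[1])

  expect_error(generate_primordia_image(scene, centers =
                                          data.frame(x_um = -5, y_um = 10)),
               class = "invalid_spec")
})

test_that("model=none time lapse is static; timestamps follow the interval", {
  sc <- scene_spec(64, 64, noise_sd = 0, seed = 2)
  tl <- generate_timelapse(sc, flow_spec("none", n_frames = 4,
                                         frame_interval_min = 5))
  expect_identical(tl$frames[[1]]$pixels, tl$frames[[4]]$pixels)
  expect_equal(vapply(tl$frames, `[[`, numeric(1), "timestamp_min"),
               c(0, 5, 10, 15))
})

test_that("uniform flow advects blobs and preserves their count", {
  sc <- scene_spec(256, 256, noise_sd = 0, seed = 9)
  pat <- pattern_spec("row", 2, 120, 0, blob_radius_um = 30,
                      blob_peak_intensity = 300)
  tl <- generate_timelapse(sc, flow_spec("uniform", c(24, 0), n_frames = 5),
                           pattern = pat)
  counts <- vapply(tl$frames, function(f)
    nrow(detect_primordia(f, 0.3, 5, 1000)$table), integer(1))
  expect_true(all(counts == 2))
  # ground-truth track moves at 24 um/h * (1/12) h = 2 um per frame
  t1 <- subset(tl$truth_tracks, track_id == 1)
  expect_equal(diff(t1$x_um), rep(2, 4))
  expect_equal(diff(t1$y_um), rep(0, 4))
})

test_that("calibration: measured amplitude grows with the planted stretch", {
  mean_amp <- function(rho) {
    v <- vapply(1:3, function(s) {
      f <- generate_texture(scene_spec(192, 192, texture_stretch_ratio = rho,
                                       correlation_length_um = 1.5,
                                       seed = s))
      average_anisotropy(anisotropy_map(f, make_grid(f, 64, 0.5)))$mean_amplitude
    }, numeric(1))
    mean(v)
  }
  amps <- vapply(c(1, 1.5, 2, 3), mean_amp, numeric(1))
  expect_true(all(diff(amps) > 0))
})
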