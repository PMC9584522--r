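# Drift registration, region auto-detection, series alignment, motility,
# divergence and tracking.

test_that("drift registration recovers planted integer shifts", {
  f <- generate_texture(scene_spec(128, 128, correlation_length_um = 1.5,
                                   seed = 3))
  r0 <- register_drift(list(f, f, f))
  expect_true(all(r0$shifts$shift_row_px == 0))
  expect_true(all(r0$shifts$shift_col_px == 0))
  expect_false(any(r0$shifts$low_confidence))

  shifted <- circshift_frame(f, 5, -3)
  r <- register_drift(list(f, shifted))
  expect_equal(r$shifts$shift_row_px[2], 5)
  expect_equal(r$shifts$shift_col_px[2], -3)
  expect_false(r$shifts$low_confidence[2])
  # aligned frame matches the original away from the replicated border
  expect_equal(r$frames[[2]]$pixels[10:119, 10:119],
               f$pixels[10:119, 10:119])

  # unrelated pure-noise frames cannot be registered confidently
  set.seed(1)
  n1 <- image_frame(matrix(rexp(128^2), 128), 1)
  n2 <- image_frame(matrix(rexp(128^2), 128), 1)
  rn <- register_drift(list(n1, n2))
  expect_true(rn$shifts$low_confidence[2])

  expect_error(register_drift(list(f, image_frame(matrix(1, 64, 64), 1))),
               class = "frame_mismatch")
})

test_that("region detection picks the hottest 3-column window and extrema", {
  amp <- matrix(0.05, 6, 9)
  amp[, 4:6] <- 0.4
  amp[2, 4] <- 0.9; amp[3, 5] <- 0.8; amp[4, 6] <- 0.7; amp[2, 6] <- 0.65
  amp[5, 4] <- 0.01; amp[5, 5] <- 0.02; amp[6, 4] <- 0.03; amp[6, 6] <- 0.04
  rg <- detect_regions(amp)
  expect_equal(rg$segment_cols, 4:6)
  expect_setequal(paste(rg$ip_boxes_4[, 1], rg$ip_boxes_4[, 2]),
                  c("2 4", "3 5", "4 6", "2 6"))
  expect_setequal(paste(rg$p_boxes_4[, 1], rg$p_boxes_4[, 2]),
                  c("5 4", "5 5", "6 4", "6 6"))
  # 9-box blocks: 3x3, central column = middle segment column
  expect_equal(sort(unique(rg$ip_boxes_9[, 2])), 4:6)
  expect_equal(nrow(rg$ip_boxes_9), 9)
  # disjointness of the 4-box sets
  expect_equal(nrow(merge(as.data.frame(rg$ip_boxes_4),
                          as.data.frame(rg$p_boxes_4))), 0)

  # uniform map: leftmost window wins (documented tie-break)
  expect_equal(detect_regions(matrix(0.2, 5, 8))$segment_cols, 1:3)
  expect_error(detect_regions(matrix(0.2, 5, 2)), class = "grid_too_small")
})

test_that("smoothing preserves constants, ramps and series length", {
  s <- smooth_and_align(rep(3.5, 40), window_frames = 30, t_ref_frame = 10)
  expect_equal(s$values, rep(3.5, 40))
  expect_equal(s$time_min, ((1:40) - 10) * 5)

  ramp <- seq(0, 39)
  sr <- smooth_and_align(ramp, 30, 1)
  expect_equal(sr$values, ramp)  # symmetric windows leave linear trends

  # missing values are interpolated before smoothing
  v <- c(1, 2, NA, 4, 5)
  sv <- smooth_and_align(v, window_frames = 1, t_ref_frame = 1)
  expect_equal(sv$raw[3], 3)

  expect_error(smooth_and_align(1:10, 30, 11), class = "invalid_tref")
})

test_that("aggregation averages aligned series over their common support", {
  a <- smooth_and_align(c(1, 2, 3, 4, 5), 1, t_ref_frame = 2)
  b <- smooth_and_align(c(10, 20, 30, 40, 50), 1, t_ref_frame = 4)
  ag <- aggregate_aligned(list(a, b))
  # offsets: a covers -1..3, b covers -3..1 -> common -1..1
  expect_equal(ag$offset_frames, -1:1)
  expect_equal(ag$mean_values, c((1 + 30) / 2, (2 + 40) / 2, (3 + 50) / 2))
  expect_equal(ag$time_min, (-1:1) * 5)
  expect_error(aggregate_aligned(list(a, smooth_and_align(1:5, 1, 3,
                                                          frame_interval_min = 10))),
               class = "invalid_spec")
})

test_that("t_ref heuristic flags the onset of an amplitude drop", {
  set.seed(2)
  base <- 0.4 + rnorm(40, sd = 0.005)
  drop <- 0.4 - 0.015 * (1:20) + rnorm(20, sd = 0.005)
  t_ref <- estimate_t_ref(c(base, drop), window_frames = 6)
  expect_true(!is.na(t_ref))
  # centered smoothing can anticipate the change point by up to half a
  # window (3 frames here); the drop starts at frame 41
  expect_gte(t_ref, 37)
  expect_lt(t_ref, 50)
  # flat series: no condensation, no reference point
  expect_true(is.na(estimate_t_ref(rep(0.4, 50) + rnorm(50, sd = 1e-3),
                                   window_frames = 6)))
  expect_error(estimate_t_ref(1:5), class = "invalid_spec")
})

test_that("region motility averages the 9 speed norms", {
  u <- matrix(0, 5, 5)
  u[2:4, 2:4] <- 1:9
  fld <- manual_field(u, matrix(0, 5, 5), stride_um = 16)
  b9 <- cbind(rep(2:4, 3), rep(2:4, each = 3))
  expect_equal(region_motility(fld, b9)$mean_speed_um_h, 5)
  expect_equal(region_motility(fld, b9)$n_replaced, 0)
  expect_error(region_motility(fld, cbind(5:7, 2)),
               class = "region_out_of_bounds")
})

test_that("divergence is a linear operator, exact on linear fields", {
  h <- 16
  x <- matrix(rep((0:5) * h, each = 6), 6, 6)
  y <- matrix(rep((0:5) * h, 6), 6, 6)
  c1 <- 0.3
  f1 <- manual_field(c1 * x, c1 * y, h)
  d1 <- field_divergence(f1)
  expect_equal(d1, matrix(2 * c1, 6, 6), tolerance = 1e-12)

  # linearity: div(f1 + f2) = div f1 + div f2
  set.seed(3)
  u2 <- matrix(rnorm(36), 6); v2 <- matrix(rnorm(36), 6)
  f2 <- manual_field(u2, v2, h)
  fsum <- manual_field(f1$u + u2, f1$v + v2, h)
  expect_equal(field_divergence(fsum), d1 + field_divergence(f2),
               tolerance = 1e-10)

  expect_error(field_divergence(manual_field(matrix(0, 2, 5),
                                             matrix(0, 2, 5), h)),
               class = "field_too_small")
})

test_that("tracking follows static and moving primordia along the AP axis", {
  # static blob
  fr <- lapply(1:6, function(k)
    blob_frame(data.frame(x_um = 128, y_um = 100), seed = 5))
  tr <- track_primordia(fr, 0.3, gaussian_sigma_px = 10, min_area_px = 2000)
  expect_equal(length(tr), 1)
  pos <- tr[[1]]$positions[1:6]
  expect_lt(max(pos) - min(pos), 0.5)
  expect_lt(abs(mean(pos) - 101), 2)

  # advected blob: +2 px/frame along AP (rows)
  fr2 <- lapply(0:5, function(k)
    blob_frame(data.frame(x_um = 128, y_um = 90 + 2 * k), seed = 5))
  tr2 <- track_primordia(fr2, 0.3, gaussian_sigma_px = 10, min_area_px = 2000)
  expect_equal(length(tr2), 1)
  slopes <- diff(tr2[[1]]$positions[1:6])
  expect_equal(mean(slopes), 2, tolerance = 0.1)
  expect_true(all(abs(slopes - 2) < 0.5))
})

test_that("open-track count drops by exactly one at each fusion", {
  frames <- lapply(0:11, function(k)
    blob_frame(data.frame(x_um = c(128, 128),
                          y_um = c(min(60 + 6 * k, 124),
                                   max(196 - 6 * k, 132))), seed = 7))
  tr <- track_primordia(frames, 0.3, gaussian_sigma_px = 10,
                        min_area_px = 2000)
  tab <- tracks_table(tr)
  open_per_frame <- vapply(1:12, function(k)
    sum(tab$frame == k), integer(1))
  drops <- which(diff(open_per_frame) == -1)
  fus <- do.call(rbind, lapply(tr, `[[`, "fusion_events"))
  expect_equal(nrow(fus), length(drops))
  expect_true(all(diff(open_per_frame) %in% c(0, -1)))
})
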