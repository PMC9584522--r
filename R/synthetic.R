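#' Scene specification for synthetic skin texture
#'
#' Describes one synthetic "dermis" image: an anisotropically filtered
#' Gaussian noise texture standing in for the cell-scale actin/nuclei
#' texture of embryonic skin. The texture is white noise convolved with an
#' anisotropic Gaussian kernel whose long axis (stretched by
#' `texture_stretch_ratio`, written rho below) lies along
#' `texture_angle_deg`, measured from the antero-posterior (row) axis.
#' This construction has a closed-form expectation for the downstream
#' Fourier anisotropy readout: amplitude (1/2) ln rho at the planted
#' angle, and 0 when rho = 1 (statistically isotropic).
#'
#' @param width_px,height_px frame size in pixels (columns, rows).
#' @param pixel_size_um micrometres per pixel.
#' @param texture_stretch_ratio rho >= 1; 1 gives an isotropic texture.
#' @param texture_angle_deg elongation axis in degrees in `[0, 180)`,
#'   counter-clockwise from the AP (row) axis.
#' @param correlation_length_um texture grain (Gaussian kernel sd along the
#'   short axis) in micrometres.
#' @param noise_sd additive sensor-noise standard deviation (intensity
#'   units), applied after texture synthesis.
#' @param mean_intensity,contrast_sd intensity scaling of the standardized
#'   texture (arbitrary units, clipped at 0).
#' @param seed integer RNG seed; identical specs give identical images.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width_px = 256L, height_px = 256L, pixel_size_um = 1,
                       texture_stretch_ratio = 1, texture_angle_deg = 0,
                       correlation_length_um = 3, noise_sd = 0,
                       mean_intensity = 100, contrast_sd = 30, seed = 1L) {
  if (width_px < 1 || height_px < 1)
    pf_stop("invalid_spec", "frame dimensions must be positive")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(correlation_length_um, "correlation_length_um")
  if (texture_stretch_ratio < 1)
    pf_stop("invalid_spec", "texture_stretch_ratio must be >= 1")
  if (texture_angle_deg < 0 || texture_angle_deg >= 180)
    pf_stop("invalid_spec", "texture_angle_deg must lie in [0, 180)")
  if (noise_sd < 0) pf_stop("invalid_spec", "noise_sd must be >= 0")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um,
                 texture_stretch_ratio = texture_stretch_ratio,
                 texture_angle_deg = texture_angle_deg,
                 correlation_length_um = correlation_length_um,
                 noise_sd = noise_sd, mean_intensity = mean_intensity,
                 contrast_sd = contrast_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Primordia point-pattern specification
#'
#' Describes planted primordia: bright condensations either along a single
#' row (the first-formed row of chicken/quail/finch-like patterns) or on a
#' 2D hexagonal array (emu/ostrich/penguin-like patterns), with tunable
#' spacing jitter expressed as a target coefficient of variation (CV) of
#' neighbour spacings.
#'
#' @param mode `"row"` or `"hex_array"`.
#' @param n_primordia number of centers (>= 0).
#' @param mean_spacing_um mean neighbour spacing in micrometres.
#' @param spacing_cv target CV (sd/mean) of neighbour spacings, >= 0.
#' @param blob_radius_um apparent primordium radius in micrometres; blobs
#'   are rendered as Gaussians of sd `blob_radius_um / 2`.
#' @param blob_peak_intensity peak intensity added at a blob center.
#' @param seed integer RNG seed.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(mode = c("row", "hex_array"), n_primordia = 5L,
                         mean_spacing_um = 100, spacing_cv = 0,
                         blob_radius_um = 20, blob_peak_intensity = 300,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (n_primordia < 0) pf_stop("invalid_spec", "n_primordia must be >= 0")
  check_positive(mean_spacing_um, "mean_spacing_um")
  if (spacing_cv < 0) pf_stop("invalid_spec", "spacing_cv must be >= 0")
  check_positive(blob_radius_um, "blob_radius_um")
  structure(list(mode = mode, n_primordia = as.integer(n_primordia),
                 mean_spacing_um = mean_spacing_um, spacing_cv = spacing_cv,
                 blob_radius_um = blob_radius_um,
                 blob_peak_intensity = blob_peak_intensity,
                 seed = as.integer(seed)),
            class = "pattern_spec")
}

#' Flow specification for synthetic time-lapse stacks
#'
#' Kinematic flow models used to advect synthetic frames: `none` (static),
#' `uniform` (constant drift), `random_walk` (whole-field Gaussian steps,
#' emulating slow undirected tissue motion), and `sink` (radial inflow
#' toward one or more condensation centers, speed = `sink_strength` x
#' distance). These are stand-ins for tissue flow kinematics, not
#' mechanistic models of primordium self-organization.
#'
#' @param model one of `"none"`, `"uniform"`, `"random_walk"`, `"sink"`.
#' @param uniform_velocity_um_per_h length-2 vector (vx, vy) in um/h.
#' @param sink_centers matrix or data.frame of sink positions (x_um, y_um).
#' @param sink_strength inflow rate in 1/h.
#' @param random_step_sd_um per-axis sd of the per-frame global step, um.
#' @param frame_interval_min acquisition interval in minutes (default 5).
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed.
#' @return A `flow_spec` list.
#' @export
flow_spec <- function(model = c("none", "uniform", "random_walk", "sink"),
                      uniform_velocity_um_per_h = c(0, 0),
                      sink_centers = NULL, sink_strength = 0.5,
                      random_step_sd_um = 1, frame_interval_min = 5,
                      n_frames = 2L, seed = 1L) {
  model <- tryCatch(match.arg(model),
                    error = function(e) pf_stop("invalid_spec",
                                                "unknown flow model"))
  check_positive(frame_interval_min, "frame_interval_min")
  if (n_frames < 2) pf_stop("invalid_spec", "n_frames must be >= 2")
  if (model == "sink") {
    if (is.null(sink_centers)) pf_stop("invalid_spec",
                                       "sink model needs sink_centers")
    sink_centers <- as.matrix(sink_centers)
    if (ncol(sink_centers) != 2) pf_stop("invalid_spec",
                                         "sink_centers must be n x 2 (x, y) um")
  }
  structure(list(model = model,
                 uniform_velocity_um_per_h = uniform_velocity_um_per_h,
                 sink_centers = sink_centers, sink_strength = sink_strength,
                 random_step_sd_um = random_step_sd_um,
                 frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "flow_spec")
}

# Torus-wrapped centered offsets 0, 1, ..., -1 for periodic kernels.
torus_offsets <- function(n) {
  h <- floor(n / 2)
  ((seq_len(n) - 1 + h) %% n) - h
}

# FFT-based circular convolution of a matrix with a kernel given on the
# same (wrapped) grid.
fft_convolve <- function(x, k) {
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / length(x)
}

#' Generate a synthetic anisotropic texture
#'
#' White Gaussian noise convolved (circularly) with an anisotropic Gaussian
#' kernel of aspect `texture_stretch_ratio` elongated along
#' `texture_angle_deg`, then standardized to the scene's mean/contrast and
#' degraded by additive sensor noise. Deterministic given the spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return An [image_frame()].
#' @export
generate_texture <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$height_px
  nc <- spec$width_px
  s0 <- spec$correlation_length_um / spec$pixel_size_um
  s1 <- spec$texture_stretch_ratio * s0   # along elongation axis
  a <- spec$texture_angle_deg * pi / 180  # from row (AP) axis
  dr <- torus_offsets(nr)
  dc <- torus_offsets(nc)
  # coordinates rotated into the kernel frame; axis direction in (row, col)
  p1 <- outer(dr * cos(a), dc * sin(a), `+`)
  p2 <- outer(-dr * sin(a), dc * cos(a), `+`)
  kern <- exp(-0.5 * ((p1 / s1)^2 + (p2 / s0)^2))
  with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    tex <- fft_convolve(noise, kern)
    z <- (tex - mean(tex)) / stats::sd(tex)
    px <- spec$mean_intensity + spec$contrast_sd * z
    if (spec$noise_sd > 0)
      px <- px + matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    px[px < 0] <- 0
    image_frame(px, spec$pixel_size_um, timestamp_min = 0)
  })
}

#' Replace a column band of one frame with another frame's pixels
#'
#' Utility to plant a dorso-ventral stripe of contrasting texture (e.g., an
#' anisotropic competent segment inside isotropic surroundings) for region
#' auto-detection fixtures.
#'
#' @param base,stripe two [image_frame()]s of identical geometry.
#' @param col_start,col_end 1-based inclusive pixel-column range.
#' @return An [image_frame()].
#' @export
plant_stripe <- function(base, stripe, col_start, col_end) {
  if (!identical(dim(base$pixels), dim(stripe$pixels)))
    pf_stop("frame_mismatch", "frames must have identical geometry")
  if (col_start < 1 || col_end > ncol(base$pixels) || col_start > col_end)
    pf_stop("invalid_spec", "column range outside frame")
  px <- base$pixels
  px[, col_start:col_end] <- stripe$pixels[, col_start:col_end]
  as_frame_like(px, base)
}

#' Generate a planted primordia point pattern
#'
#' `mode = "row"` places centers along the x axis with consecutive gaps
#' drawn from a normal law (mean `mean_spacing_um`, sd `spacing_cv` x
#' mean) truncated below at 10% of the mean, keeping gaps positive while
#' leaving the CV as the single fidelity knob. `mode = "hex_array"` builds
#' a hexagonal lattice with isotropic Gaussian positional jitter of
#' per-axis sd `spacing_cv * mean_spacing_um / sqrt(2)`, the first-order
#' calibration making the Delaunay edge-length CV match the target.
#'
#' @param spec a [pattern_spec()].
#' @return A list with `centers` (data.frame `x_um`, `y_um`),
#'   `realized_cv` (ground-truth CV of the realized neighbour spacings) and
#'   the input `spec`.
#' @export
generate_point_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  n <- spec$n_primordia
  m <- spec$mean_spacing_um
  cv <- spec$spacing_cv
  if (n == 0)
    return(list(centers = data.frame(x_um = numeric(0), y_um = numeric(0)),
                realized_cv = NA_real_, spec = spec))
  if (spec$mode == "row") {
    if (n == 1) {
      centers <- data.frame(x_um = 0, y_um = 0)
      realized <- NA_real_
    } else if (cv == 0) {
      centers <- data.frame(x_um = m * (seq_len(n) - 1), y_um = 0)
      realized <- 0
    } else {
      gaps <- with_seed(spec$seed, {
        g <- stats::rnorm(n - 1, mean = m, sd = cv * m)
        lo <- 0.1 * m
        while (any(g < lo))  # truncated normal by rejection
          g[g < lo] <- stats::rnorm(sum(g < lo), mean = m, sd = cv * m)
        g
      })
      centers <- data.frame(x_um = cumsum(c(0, gaps)), y_um = 0)
      realized <- if (n >= 3) stats::sd(gaps) / mean(gaps) else NA_real_
    }
    list(centers = centers, realized_cv = realized, spec = spec)
  } else {
    ncols <- ceiling(sqrt(n / (sqrt(3) / 2)))
    nrows <- ceiling(n / ncols)
    ij <- expand.grid(i = seq_len(ncols) - 1, j = seq_len(nrows) - 1)
    ij <- ij[seq_len(n), , drop = FALSE]
    x <- (ij$i + 0.5 * (ij$j %% 2)) * m
    y <- ij$j * m * sqrt(3) / 2
    if (cv > 0) {
      jit <- with_seed(spec$seed,
                       matrix(stats::rnorm(2 * n, sd = cv * m / sqrt(2)),
                              ncol = 2))
      x <- x + jit[, 1]
      y <- y + jit[, 2]
    }
    centers <- data.frame(x_um = x, y_um = y)
    realized <- if (cv == 0) 0 else if (n >= 5) {
      st <- tryCatch(delaunay_spacing_variability(centers),
                     error = function(e) NULL)
      if (is.null(st)) NA_real_ else st$spacing_variability
    } else NA_real_
    list(centers = centers, realized_cv = realized, spec = spec)
  }
}

# Additively render Gaussian blobs (sd = radius/2) at centers given in um.
render_blobs <- function(nr, nc, pixel_size_um, centers, radius_um, peak) {
  acc <- matrix(0, nr, nc)
  if (nrow(centers) == 0) return(acc)
  sig <- radius_um / 2 / pixel_size_um
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers$y_um[i] / pixel_size_um + 1
    c0 <- centers$x_um[i] / pixel_size_um + 1
    g <- peak * outer(exp(-(rows - r0)^2 / (2 * sig^2)),
                      exp(-(cols - c0)^2 / (2 * sig^2)))
    acc <- acc + g
  }
  acc
}

#' Render primordia blobs on a textured background, with ground truth
#'
#' Each center becomes an isotropic Gaussian condensation (sd =
#' `blob_radius_um / 2`) added to the scene texture. Ground truth records,
#' per blob, the pixel area that would exceed the brightest-pixel detection
#' threshold in the absence of noise; blobs whose area falls below
#' `min_area_px` are flagged `sub_threshold` (they should not be reported
#' by [detect_primordia()]).
#'
#' @param scene a [scene_spec()] for the background texture.
#' @param pattern a [pattern_spec()]; ignored when `centers` is given.
#' @param centers optional data.frame (`x_um`, `y_um`) of planted centers;
#'   by default the pattern from [generate_point_pattern()] is centered in
#'   the frame.
#' @param threshold_quantile brightest-pixel fraction used to define the
#'   ground-truth detection threshold (default 0.30 as in detection).
#' @param min_area_px detection minimum area used for the `sub_threshold`
#'   flag (NA disables the flag).
#' @return A list: `frame` ([image_frame()]), `truth` (data.frame `x_um`,
#'   `y_um`, `area_px`, `sub_threshold`) and `threshold` (intensity).
#' @export
generate_primordia_image <- function(scene, pattern = NULL, centers = NULL,
                                     threshold_quantile = 0.30,
                                     min_area_px = NA) {
  stopifnot(inherits(scene, "scene_spec"))
  nr <- scene$height_px
  nc <- scene$width_px
  psz <- scene$pixel_size_um
  if (is.null(centers)) {
    stopifnot(inherits(pattern, "pattern_spec"))
    pp <- generate_point_pattern(pattern)
    centers <- pp$centers
    if (nrow(centers) > 0) {  # center the pattern's bounding box in frame
      centers$x_um <- centers$x_um - mean(range(centers$x_um)) +
        (nc - 1) / 2 * psz
      centers$y_um <- centers$y_um - mean(range(centers$y_um)) +
        (nr - 1) / 2 * psz
    }
  } else centers <- as.data.frame(centers)
  radius_um <- if (!is.null(pattern)) pattern$blob_radius_um else 20
  peak <- if (!is.null(pattern)) pattern$blob_peak_intensity else 300
  if (nrow(centers) > 0 &&
      (any(centers$x_um < 0) || any(centers$x_um > (nc - 1) * psz) ||
       any(centers$y_um < 0) || any(centers$y_um > (nr - 1) * psz)))
    pf_stop("invalid_spec", "all blob centers must lie inside the frame")

  noiseless <- scene
  noiseless$noise_sd <- 0
  tex <- generate_texture(noiseless)
  blobs <- render_blobs(nr, nc, psz, centers, radius_um, peak)
  clean <- tex$pixels + blobs
  thr <- nearest_rank_quantile(clean, 1 - threshold_quantile)
  eff <- thr - stats::median(tex$pixels)  # blob excess needed over texture
  sig_px <- radius_um / 2 / psz
  area <- vapply(seq_len(nrow(centers)), function(i) {
    if (eff <= 0) return(nr * nc)
    if (eff >= peak) return(0L)
    rows <- seq_len(nr)
    cols <- seq_len(nc)
    r0 <- centers$y_um[i] / psz + 1
    c0 <- centers$x_um[i] / psz + 1
    g <- peak * outer(exp(-(rows - r0)^2 / (2 * sig_px^2)),
                      exp(-(cols - c0)^2 / (2 * sig_px^2)))
    sum(g >= eff)
  }, numeric(1))
  px <- clean
  if (scene$noise_sd > 0)
    px <- px + with_seed(scene$seed + 1L,
                         matrix(stats::rnorm(nr * nc, sd = scene$noise_sd),
                                nr, nc))
  px[px < 0] <- 0
  truth <- data.frame(x_um = centers$x_um, y_um = centers$y_um,
                      area_px = area,
                      sub_threshold = if (is.na(min_area_px)) NA else
                        area < min_area_px)
  list(frame = image_frame(px, psz, timestamp_min = 0), truth = truth,
       threshold = thr)
}

# Reflective index mapping for out-of-range coordinates on 1..n.
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1, length(i)))
  p <- 2 * (n - 1)
  j <- (i - 1) %% p
  j[j < 0] <- j[j < 0] + p
  j <- ifelse(j >= (n - 1), p - j, j)
  j + 1
}

# Backward bilinear warp: out(r, c) = in(r - dr(r,c), c - dc(r,c)), with
# reflective padding; dr/dc are displacements of the content in pixels.
warp_bilinear <- function(mat, dr, dc) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  rr <- matrix(seq_len(nr), nr, nc) - dr
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dc
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0;   fc <- cc - c0
  idx <- function(r, c) {
    r <- reflect_index(r, nr)
    c <- reflect_index(c, nc)
    mat[cbind(as.vector(r), as.vector(c))]
  }
  v00 <- idx(r0,     c0)
  v10 <- idx(r0 + 1, c0)
  v01 <- idx(r0,     c0 + 1)
  v11 <- idx(r0 + 1, c0 + 1)
  out <- (1 - as.vector(fr)) * (1 - as.vector(fc)) * v00 +
    as.vector(fr) * (1 - as.vector(fc)) * v10 +
    (1 - as.vector(fr)) * as.vector(fc) * v01 +
    as.vector(fr) * as.vector(fc) * v11
  matrix(out, nr, nc)
}

# Analytic flow velocity (um/h) at points (x_um, y_um) for frame step k
# (1-based step index between frames k and k+1). steps_um is used by the
# random_walk model.
flow_velocity <- function(flow, x_um, y_um, k, steps_um = NULL) {
  dt_h <- flow$frame_interval_min / 60
  switch(flow$model,
         none = cbind(u = 0 * x_um, v = 0 * y_um),
         uniform = cbind(u = rep(flow$uniform_velocity_um_per_h[1],
                                 length(x_um)),
                         v = rep(flow$uniform_velocity_um_per_h[2],
                                 length(x_um))),
         random_walk = cbind(u = rep(steps_um[k, 1] / dt_h, length(x_um)),
                             v = rep(steps_um[k, 2] / dt_h, length(x_um))),
         sink = {
           u <- 0 * x_um
           v <- 0 * y_um
           for (s in seq_len(nrow(flow$sink_centers))) {
             u <- u - flow$sink_strength * (x_um - flow$sink_centers[s, 1])
             v <- v - flow$sink_strength * (y_um - flow$sink_centers[s, 2])
           }
           cbind(u = u, v = v)
         })
}

#' Generate a synthetic time-lapse stack with planted flow
#'
#' Frame k+1 is frame k advected by the flow model (backward bilinear warp
#' with reflective padding), plus fresh additive sensor noise. Optional
#' primordia blobs are advected with the flow (forward Euler at the frame
#' interval) and reported as ground-truth tracks.
#'
#' @param scene a [scene_spec()] (its `noise_sd` is the per-frame sensor
#'   noise; the advected clean image accumulates no noise).
#' @param flow a [flow_spec()].
#' @param pattern optional [pattern_spec()] for planted blobs.
#' @param centers optional explicit blob centers (data.frame x_um, y_um),
#'   overriding `pattern` placement as in [generate_primordia_image()].
#' @return A list: `frames` (list of [image_frame()], timestamps k x
#'   `frame_interval_min`), `truth_tracks` (data.frame `track_id`, `frame`,
#'   `x_um`, `y_um`), `velocity_fun(x_um, y_um, k)` returning the analytic
#'   flow in um/h for step k, and `steps_um` (random-walk steps, or NULL).
#' @export
generate_timelapse <- function(scene, flow, pattern = NULL, centers = NULL) {
  stopifnot(inherits(scene, "scene_spec"), inherits(flow, "flow_spec"))
  nr <- scene$height_px
  nc <- scene$width_px
  psz <- scene$pixel_size_um
  nfr <- flow$n_frames
  dt_h <- flow$frame_interval_min / 60

  if (is.null(centers) && !is.null(pattern)) {
    pp <- generate_point_pattern(pattern)
    centers <- pp$centers
    if (nrow(centers) > 0) {
      centers$x_um <- centers$x_um - mean(range(centers$x_um)) +
        (nc - 1) / 2 * psz
      centers$y_um <- centers$y_um - mean(range(centers$y_um)) +
        (nr - 1) / 2 * psz
    }
  }
  if (is.null(centers)) centers <- data.frame(x_um = numeric(0),
                                              y_um = numeric(0))

  steps_um <- NULL
  if (flow$model == "random_walk")
    steps_um <- with_seed(flow$seed,
                          matrix(stats::rnorm(2 * (nfr - 1),
                                              sd = flow$random_step_sd_um),
                                 ncol = 2))

  noiseless <- scene
  noiseless$noise_sd <- 0
  tex <- generate_texture(noiseless)
  clean <- tex$pixels
  if (nrow(centers) > 0 && !is.null(pattern))
    clean <- clean + render_blobs(nr, nc, psz, centers,
                                  pattern$blob_radius_um,
                                  pattern$blob_peak_intensity)

  # per-frame sensor noise, seeded once for the whole stack
  noise_stack <- if (scene$noise_sd > 0)
    with_seed(scene$seed + 1000L,
              lapply(seq_len(nfr), function(k)
                matrix(stats::rnorm(nr * nc, sd = scene$noise_sd), nr, nc)))
  else NULL

  # pixel-center physical coordinates for spatially varying flows
  xg <- matrix(rep((seq_len(nc) - 1) * psz, each = nr), nr, nc)
  yg <- matrix((seq_len(nr) - 1) * psz, nr, nc)

  frames <- vector("list", nfr)
  tracks <- list()
  cur_centers <- centers
  add_noise <- function(m, k) {
    out <- if (is.null(noise_stack)) m else m + noise_stack[[k]]
    out[out < 0] <- 0
    out
  }
  frames[[1]] <- image_frame(add_noise(clean, 1), psz, timestamp_min = 0)
  if (nrow(cur_centers) > 0)
    tracks[[1]] <- data.frame(track_id = seq_len(nrow(cur_centers)),
                              frame = 1L, x_um = cur_centers$x_um,
                              y_um = cur_centers$y_um)
  for (k in seq_len(nfr - 1)) {
    vel <- flow_velocity(flow, as.vector(xg), as.vector(yg), k, steps_um)
    dc_px <- matrix(vel[, "u"] * dt_h / psz, nr, nc)
    dr_px <- matrix(vel[, "v"] * dt_h / psz, nr, nc)
    clean <- warp_bilinear(clean, dr_px, dc_px)
    if (nrow(cur_centers) > 0) {
      cv <- flow_velocity(flow, cur_centers$x_um, cur_centers$y_um, k,
                          steps_um)
      cur_centers$x_um <- cur_centers$x_um + cv[, "u"] * dt_h
      cur_centers$y_um <- cur_centers$y_um + cv[, "v"] * dt_h
      tracks[[k + 1]] <- data.frame(track_id = seq_len(nrow(cur_centers)),
                                    frame = k + 1L,
                                    x_um = cur_centers$x_um,
                                    y_um = cur_centers$y_um)
    }
    frames[[k + 1]] <- image_frame(add_noise(clean, k + 1), psz,
                                   timestamp_min = k * flow$frame_interval_min)
  }
  list(frames = frames,
       truth_tracks = if (length(tracks)) do.call(rbind, tracks) else
         data.frame(track_id = integer(0), frame = integer(0),
                    x_um = numeric(0), y_um = numeric(0)),
       velocity_fun = function(x_um, y_um, k = 1)
         flow_velocity(flow, x_um, y_um, k, steps_um),
       steps_um = steps_um)
}
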