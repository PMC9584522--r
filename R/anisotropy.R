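#' Build an interrogation-box grid over a frame
#'
#' Deterministic square tiling anchored at the top-left pixel. The default
#' geometry (25 x 25 um boxes, 50% overlap) is the standard coarse-graining
#' used for cell-shape anisotropy in embryonic skin. Boxes that would
#' overrun the frame are dropped; no partial boxes are produced.
#'
#' @param frame an [image_frame()].
#' @param box_size_um box side in micrometres (default 25).
#' @param overlap_fraction fractional overlap between neighbouring boxes in
#'   `[0, 1)` (default 0.5).
#' @return An `interrogation_grid`: `box_size_px`, `stride_px`,
#'   `stride_um`, `row_origins`/`col_origins` (1-based pixel offsets of box
#'   top-left corners), `n_rows_boxes`, `n_cols_boxes`, and per-box center
#'   coordinates in micrometres.
#' @export
make_grid <- function(frame, box_size_um = 25, overlap_fraction = 0.5) {
  stopifnot(inherits(frame, "image_frame"))
  check_positive(box_size_um, "box_size_um")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    pf_stop("invalid_spec", "overlap_fraction must lie in [0, 1)")
  box_px <- round(box_size_um / frame$pixel_size_um)
  if (box_px < 8)
    pf_stop("invalid_spec", "box size must be at least 8 px after conversion")
  nr <- nrow(frame$pixels)
  nc <- ncol(frame$pixels)
  if (nr < box_px || nc < box_px)
    pf_stop("frame_too_small", "frame is smaller than one interrogation box")
  stride <- max(1L, as.integer(round(box_px * (1 - overlap_fraction))))
  n_rows <- (nr - box_px) %/% stride + 1L
  n_cols <- (nc - box_px) %/% stride + 1L
  row_origins <- 1L + stride * (seq_len(n_rows) - 1L)
  col_origins <- 1L + stride * (seq_len(n_cols) - 1L)
  ctr <- function(o) (o - 1 + (box_px - 1) / 2) * frame$pixel_size_um
  structure(list(box_size_um = box_px * frame$pixel_size_um,
                 overlap_fraction = overlap_fraction,
                 box_size_px = as.integer(box_px),
                 stride_px = stride,
                 stride_um = stride * frame$pixel_size_um,
                 row_origins = row_origins, col_origins = col_origins,
                 n_rows_boxes = n_rows, n_cols_boxes = n_cols,
                 center_y_um = ctr(row_origins),
                 center_x_um = ctr(col_origins),
                 frame_dim = c(nr, nc),
                 pixel_size_um = frame$pixel_size_um),
            class = "interrogation_grid")
}

# 2D Hann window of side n (apodization before the FT, avoiding boundary
# singularities in the spectrum).
hann2d <- function(n) {
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  outer(w, w)
}

#' Fourier-transform anisotropy of one interrogation box
#'
#' Segmentation-free readout of the average elongation of the texture in a
#' square block: (1) subtract the block mean; (2) multiply by a 2D Hann
#' window; (3) 2D DFT, modulus, zero frequency centered; (4) binarize by
#' retaining the 5% brightest spectrum pixels (nearest-rank 95th
#' percentile, ties retained); (5) second-moment (inertia) matrix of the
#' retained pixel coordinates about the zero-frequency origin, uniform
#' weights; (6) diagonalize; with eigenvalues l1 >= l2 the Fourier ellipse
#' has axis ratio `L_maj / L_min = sqrt(l1 / l2)`, so the anisotropy
#' amplitude is `(1/2) ln(L_maj / L_min) = (1/4) ln(l1 / l2)` —
#' dimensionless, zero for isotropic texture; (7) the real-space elongation
#' angle is the orientation of the eigenvector of l2 (the spectrum ellipse
#' is elongated perpendicular to the texture), reported as a nematic angle
#' in `[0, pi)` measured from the AP (row) axis.
#'
#' @param box_pixels square numeric matrix, side >= 8 px.
#' @param retain_fraction fraction of brightest spectrum pixels kept
#'   (default 0.05).
#' @param statistic `"modulus"` (default) or `"power"` spectrum.
#' @return list `amplitude`, `angle_rad` (NA when degenerate),
#'   `degenerate`.
#' @export
box_anisotropy <- function(box_pixels, retain_fraction = 0.05,
                           statistic = c("modulus", "power")) {
  statistic <- match.arg(statistic)
  n <- nrow(box_pixels)
  if (!is.matrix(box_pixels) || n != ncol(box_pixels) || n < 8)
    pf_stop("invalid_spec", "box must be square with side >= 8 px")
  degen <- list(amplitude = 0, angle_rad = NA_real_, degenerate = TRUE)
  x <- box_pixels - mean(box_pixels)
  if (all(x == 0)) return(degen)
  x <- x * hann2d(n)
  sp <- Mod(stats::fft(x))
  if (statistic == "power") sp <- sp^2
  # center zero frequency
  h <- floor(n / 2)
  ord <- c((n - h + 1):n, 1:(n - h))  # so that origin lands at index h + 1
  sp <- sp[ord, ord, drop = FALSE]
  thr <- nearest_rank_quantile(sp, 1 - retain_fraction)
  keep <- which(sp >= thr, arr.ind = TRUE)
  org <- h + 1
  dr <- keep[, 1] - org
  dc <- keep[, 2] - org
  m <- nrow(keep)
  if (m < 3) return(degen)
  inertia <- matrix(c(sum(dr * dr), sum(dr * dc),
                      sum(dr * dc), sum(dc * dc)), 2, 2) / m
  eg <- eigen(inertia, symmetric = TRUE)
  l1 <- eg$values[1]
  l2 <- eg$values[2]
  if (l2 <= 1e-12 * max(l1, 1)) return(degen)  # retained pixels collinear
  amp <- 0.25 * log(l1 / l2)
  v2 <- eg$vectors[, 2]  # minor axis of the spectrum ellipse
  ang <- wrap_nematic(atan2(v2[2], v2[1]))
  list(amplitude = amp, angle_rad = ang, degenerate = FALSE)
}

#' Map anisotropy over an interrogation grid
#'
#' Applies [box_anisotropy()] to every box of the grid, producing per-box
#' amplitude and nematic orientation matrices (a heat map of coarse-grained
#' cell-shape anisotropy).
#'
#' @param frame an [image_frame()].
#' @param grid an `interrogation_grid` built from this frame's geometry.
#' @param ... passed to [box_anisotropy()].
#' @return An `anisotropy_map`: matrices `amplitude`, `angle_rad`,
#'   `degenerate` indexed `[box_row, box_col]`, plus the `grid`.
#' @export
anisotropy_map <- function(frame, grid, ...) {
  stopifnot(inherits(frame, "image_frame"),
            inherits(grid, "interrogation_grid"))
  if (!identical(grid$frame_dim, dim(frame$pixels)) ||
      grid$pixel_size_um != frame$pixel_size_um)
    pf_stop("grid_mismatch", "grid was not built from this frame's geometry")
  nb <- grid$box_size_px
  amp <- matrix(0, grid$n_rows_boxes, grid$n_cols_boxes)
  ang <- matrix(NA_real_, grid$n_rows_boxes, grid$n_cols_boxes)
  dgn <- matrix(FALSE, grid$n_rows_boxes, grid$n_cols_boxes)
  for (i in seq_len(grid$n_rows_boxes)) {
    r0 <- grid$row_origins[i]
    for (j in seq_len(grid$n_cols_boxes)) {
      c0 <- grid$col_origins[j]
      b <- box_anisotropy(frame$pixels[r0:(r0 + nb - 1), c0:(c0 + nb - 1)],
                          ...)
      amp[i, j] <- b$amplitude
      ang[i, j] <- b$angle_rad
      dgn[i, j] <- b$degenerate
    }
  }
  structure(list(amplitude = amp, angle_rad = ang, degenerate = dgn,
                 grid = grid), class = "anisotropy_map")
}

#' Average anisotropy over a set of boxes
#'
#' The mean amplitude is the arithmetic mean of the per-box bar lengths.
#' The mean direction is the orientation of the mean nematic tensor
#' `sum(a_i * (cos 2 theta_i, sin 2 theta_i))`; when opposing orientations
#' cancel (tensor norm below 1e-9 of the amplitude sum) the direction is
#' undefined (NA). Degenerate boxes are excluded.
#'
#' @param map an `anisotropy_map`.
#' @param box_subset optional 2-column matrix of (box_row, box_col)
#'   indices; default all boxes.
#' @return list `mean_amplitude`, `mean_angle_rad` (NA if undefined),
#'   `n_boxes_used`.
#' @export
average_anisotropy <- function(map, box_subset = NULL) {
  stopifnot(inherits(map, "anisotropy_map"))
  if (is.null(box_subset)) {
    sel <- which(!map$degenerate)
  } else {
    box_subset <- as.matrix(box_subset)
    sel <- box_subset[!map$degenerate[box_subset], , drop = FALSE]
    if (nrow(sel) == 0)
      pf_stop("no_valid_boxes", "no non-degenerate boxes in subset")
  }
  a <- map$amplitude[sel]
  th <- map$angle_rad[sel]
  if (length(a) == 0)
    pf_stop("no_valid_boxes", "no non-degenerate boxes in subset")
  sx <- sum(a * cos(2 * th))
  sy <- sum(a * sin(2 * th))
  dir <- if (sqrt(sx^2 + sy^2) < 1e-9 * sum(a)) NA_real_ else
    wrap_nematic(0.5 * atan2(sy, sx))
  list(mean_amplitude = mean(a), mean_angle_rad = dir,
       n_boxes_used = length(a))
}

#' Export an anisotropy map as a tidy table
#'
#' One row per interrogation box with physical box-center coordinates,
#' suitable for CSV export or plotting.
#'
#' @param map an `anisotropy_map`.
#' @return data.frame with columns `box_row`, `box_col`, `center_x_um`,
#'   `center_y_um`, `amplitude`, `angle_deg`, `degenerate`.
#' @export
anisotropy_table <- function(map) {
  g <- map$grid
  idx <- expand.grid(box_row = seq_len(g$n_rows_boxes),
                     box_col = seq_len(g$n_cols_boxes))
  data.frame(box_row = idx$box_row, box_col = idx$box_col,
             center_x_um = g$center_x_um[idx$box_col],
             center_y_um = g$center_y_um[idx$box_row],
             amplitude = map$amplitude[as.matrix(idx)],
             angle_deg = map$angle_rad[as.matrix(idx)] * 180 / pi,
             degenerate = map$degenerate[as.matrix(idx)])
}

#' Render an anisotropy bar overlay to PNG
#'
#' Draws the classic bar representation — one bar per box, length
#' proportional to amplitude, oriented along the measured elongation axis —
#' over the image.
#'
#' @param frame an [image_frame()].
#' @param map an `anisotropy_map` computed on `frame`.
#' @param path output PNG path.
#' @param bar_scale bar half-length in pixels per unit amplitude.
#' @return `path`, invisibly.
#' @export
plot_anisotropy_overlay <- function(frame, map, path, bar_scale = 40) {
  g <- map$grid
  grDevices::png(path, width = ncol(frame$pixels), height = nrow(frame$pixels))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(t(frame$pixels)[, nrow(frame$pixels):1],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  useRaster = TRUE)
  nr <- nrow(frame$pixels)
  nc <- ncol(frame$pixels)
  for (i in seq_len(g$n_rows_boxes)) for (j in seq_len(g$n_cols_boxes)) {
    if (map$degenerate[i, j]) next
    a <- map$amplitude[i, j]
    th <- map$angle_rad[i, j]
    cr <- g$row_origins[i] + (g$box_size_px - 1) / 2
    cc <- g$col_origins[j] + (g$box_size_px - 1) / 2
    # device coords: x in [0,1] along cols, y flipped
    dx <- bar_scale * a * sin(th) / nc
    dy <- bar_scale * a * cos(th) / nr
    x0 <- (cc - 1) / (nc - 1)
    y0 <- 1 - (cr - 1) / (nr - 1)
    graphics::segments(x0 - dx, y0 + dy, x0 + dx, y0 - dy, col = "red",
                       lwd = 2)
  }
  invisible(path)
}
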