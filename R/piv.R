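# Particle image velocimetry on interrogation windows.

# Circular cross-correlation of two mean-subtracted windows via FFT;
# returns the correlation surface whose peak at wrapped offset d means
# "window b equals window a displaced by d pixels".
cross_correlate <- function(a, b) {
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / length(a)
  # unbias: at wrapped lag s only (n - |s|) pixel pairs genuinely overlap,
  # which tilts wide correlation peaks toward zero displacement; divide by
  # the triangular overlap fraction per axis
  n <- nrow(cc)
  tri <- (n - abs(wrap_offset(seq_len(n), n))) / n
  cc / outer(tri, tri)
}

wrap_offset <- function(idx, n) ((idx - 1 + n %/% 2) %% n) - n %/% 2

# 3-point subpixel refinement along one axis: Gaussian fit on the log of
# the three correlation values when they are all positive, parabolic fit
# otherwise. Returns an offset in (-1, 1).
subpixel_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den < 0) {
      d <- (log(cm) - log(cp)) / den
      if (is.finite(d)) return(max(-1, min(1, d)))
    }
  }
  den <- cm - 2 * c0 + cp
  if (den < 0) {
    d <- 0.5 * (cm - cp) / den
    if (is.finite(d)) return(max(-1, min(1, d)))
  }
  0
}

#' Particle image velocimetry between two frames
#'
#' Estimates the per-box tissue velocity field from one frame to the next:
#' (1) both frames are median-filtered (radius `median_radius_px`, the
#' standard pre-treatment eliminating aberrant vectors); (2) for each
#' interrogation window (default 32 px, 50% overlap) the displacement is
#' the peak of the FFT-based cross-correlation of the mean-subtracted,
#' intensity-normalized windows; (3) subpixel refinement by a 3-point
#' Gaussian fit per axis; (4) outlier rejection by a local 3x3 median
#' test: a vector deviating from its neighbourhood median by more than
#' `outlier_px` pixels is replaced by that median and flagged invalid;
#' (5) conversion px/frame -> um/h via the pixel size and frame interval
#' (at the default 5-min interval, 1 px/frame = 12 x pixel size um/h).
#'
#' The correlation surface is normalized by the per-lag pixel-overlap
#' fraction before peak search, removing the systematic pull of wide
#' correlation peaks toward zero displacement.
#'
#' @param frame_a,frame_b two [image_frame()]s of identical geometry.
#' @param window_px interrogation-window side in pixels (>= 16).
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param frame_interval_min time between the frames, minutes.
#' @param median_radius_px pre-filter radius (0 disables).
#' @param outlier_px median-test rejection threshold in pixels.
#' @param subpixel logical; disable for pure integer-pixel displacement
#'   estimates.
#' @return A `velocity_field`: matrices `u`, `v` (um/h; u along columns =
#'   x, v along rows = y), `speed`, `valid` (FALSE where the raw vector
#'   was replaced or unmeasurable), grid geometry (`stride_um`, box
#'   centers) and the conversion metadata.
#' @export
compute_piv <- function(frame_a, frame_b, window_px = 32,
                        overlap_fraction = 0.5, frame_interval_min = 5,
                        median_radius_px = 2, outlier_px = 2,
                        subpixel = TRUE) {
  stopifnot(inherits(frame_a, "image_frame"), inherits(frame_b, "image_frame"))
  if (!identical(dim(frame_a$pixels), dim(frame_b$pixels)) ||
      frame_a$pixel_size_um != frame_b$pixel_size_um)
    pf_stop("frame_mismatch", "frames must share geometry and pixel size")
  if (window_px < 16) pf_stop("invalid_spec", "window_px must be >= 16")
  med <- function(m) {
    if (median_radius_px <= 0) return(m)
    sc <- max(m, 1)
    EBImage::medianFilter(m / sc, size = median_radius_px) * sc
  }
  A <- med(frame_a$pixels)
  B <- med(frame_b$pixels)
  psz <- frame_a$pixel_size_um
  stride <- max(1L, as.integer(round(window_px * (1 - overlap_fraction))))
  nrb <- (nrow(A) - window_px) %/% stride + 1L
  ncb <- (ncol(A) - window_px) %/% stride + 1L
  if (nrb < 1 || ncb < 1)
    pf_stop("frame_too_small", "frame smaller than one PIV window")
  dr_px <- matrix(0, nrb, ncb)
  dc_px <- matrix(0, nrb, ncb)
  valid <- matrix(TRUE, nrb, ncb)
  n <- window_px
  wrap1 <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(nrb)) for (j in seq_len(ncb)) {
    r0 <- 1 + (i - 1) * stride
    c0 <- 1 + (j - 1) * stride
    a <- A[r0:(r0 + n - 1), c0:(c0 + n - 1)]
    b <- B[r0:(r0 + n - 1), c0:(c0 + n - 1)]
    sa <- stats::sd(a)
    sb <- stats::sd(b)
    if (sa == 0 || sb == 0) { valid[i, j] <- FALSE; next }
    cc <- cross_correlate((a - mean(a)) / sa, (b - mean(b)) / sb)
    # restrict the peak search to |lag| <= window/4 (usual PIV validity
    # range; beyond it the overlap is too small to trust)
    lag <- wrap_offset(seq_len(n), n)
    search <- cc
    search[abs(lag) > n / 4, ] <- -Inf
    search[, abs(lag) > n / 4] <- -Inf
    pk <- arrayInd(which.max(search), dim(cc))
    pr <- pk[1]; pc <- pk[2]
    dr <- wrap_offset(pr, n)
    dc <- wrap_offset(pc, n)
    if (subpixel) {
      dr <- dr + subpixel_offset(cc[wrap1(pr - 1), pc], cc[pr, pc],
                                 cc[wrap1(pr + 1), pc])
      dc <- dc + subpixel_offset(cc[pr, wrap1(pc - 1)], cc[pr, pc],
                                 cc[pr, wrap1(pc + 1)])
    }
    dr_px[i, j] <- dr
    dc_px[i, j] <- dc
  }
  # local 3x3 median test; invalid windows are infilled the same way
  med_u <- dr_px
  med_v <- dc_px
  for (i in seq_len(nrb)) for (j in seq_len(ncb)) {
    ri <- max(1, i - 1):min(nrb, i + 1)
    cj <- max(1, j - 1):min(ncb, j + 1)
    sel <- as.matrix(expand.grid(ri, cj))
    sel <- sel[!(sel[, 1] == i & sel[, 2] == j), , drop = FALSE]
    ok <- valid[sel]
    if (!any(ok)) next
    mr <- stats::median(dr_px[sel[ok, , drop = FALSE]])
    mc <- stats::median(dc_px[sel[ok, , drop = FALSE]])
    if (!valid[i, j]) {
      med_u[i, j] <- mr; med_v[i, j] <- mc
    } else if (sqrt((dr_px[i, j] - mr)^2 + (dc_px[i, j] - mc)^2) >
               outlier_px) {
      med_u[i, j] <- mr; med_v[i, j] <- mc
      valid[i, j] <- FALSE
    }
  }
  conv <- psz * 60 / frame_interval_min  # px/frame -> um/h
  u <- med_v * conv  # columns = x
  v <- med_u * conv  # rows = y
  ctr <- function(o) (o - 1 + (n - 1) / 2) * psz
  structure(list(u = u, v = v, speed = sqrt(u^2 + v^2), valid = valid,
                 stride_um = stride * psz, window_px = as.integer(n),
                 stride_px = stride,
                 center_x_um = ctr(1 + (seq_len(ncb) - 1) * stride),
                 center_y_um = ctr(1 + (seq_len(nrb) - 1) * stride),
                 frame_interval_min = frame_interval_min,
                 pixel_size_um = psz),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d boxes, mean speed %.2f um/h, %d replaced vector(s)\n",
              nrow(x$u), ncol(x$u), mean(x$speed), sum(!x$valid)))
  invisible(x)
}
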