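#' Create an image frame
#'
#' The atom consumed by every pipeline stage: one grayscale image together
#' with its physical pixel size and an optional acquisition timestamp.
#' Pixels are stored as a numeric matrix; rows run along the
#' antero-posterior (AP) axis by convention and columns along the
#' dorso-ventral (DV) axis. Pixel centers sit at integer coordinates, with
#' pixel `[1, 1]` at physical position (0, 0) um and the physical x axis
#' along columns, y along rows.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param timestamp_min optional acquisition time in minutes (>= 0).
#'
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size_um, timestamp_min = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    pf_stop("invalid_spec", "pixels must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    pf_stop("invalid_spec", "intensities must be finite and non-negative")
  check_positive(pixel_size_um, "pixel_size_um")
  if (!is.na(timestamp_min) && timestamp_min < 0)
    pf_stop("invalid_spec", "timestamp_min must be >= 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 timestamp_min = timestamp_min),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.3g um/px", nrow(x$pixels),
              ncol(x$pixels), x$pixel_size_um))
  if (!is.na(x$timestamp_min)) cat(sprintf(", t = %g min", x$timestamp_min))
  cat("\n")
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

as_frame_like <- function(pixels, template) {
  pixels[pixels < 0] <- 0
  image_frame(pixels, template$pixel_size_um, template$timestamp_min)
}

# Convert a (row, col) 1-based pixel position to physical um coordinates.
px_to_um <- function(row, col, pixel_size_um) {
  list(x_um = (col - 1) * pixel_size_um, y_um = (row - 1) * pixel_size_um)
}
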