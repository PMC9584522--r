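#' Detect primordia as bright connected components
#'
#' Threshold-based detector for primordia (condensations of cells appearing
#' as bright areas): (1) keep the brightest `threshold_quantile` fraction
#' of pixels (nearest-rank quantile; 0.30 keeps the 30% brightest), zeroing
#' the rest; (2) Gaussian smoothing with sd `gaussian_sigma_px` (0 skips
#' smoothing); (3) binarize the smoothed image at half the mean of the
#' retained intensities; (4) 8-connected component labelling; (5) discard
#' components smaller than `min_area_px` (inclusive: a component of exactly
#' `min_area_px` pixels is retained).
#'
#' @param frame an [image_frame()].
#' @param threshold_quantile fraction of brightest pixels retained, in
#'   (0, 1); default 0.30.
#' @param gaussian_sigma_px smoothing sd in pixels (default 10).
#' @param min_area_px minimum component area in pixels (default 10000).
#' @param min_area_um2 alternative minimum area in um^2, converted via the
#'   frame's pixel size (overrides `min_area_px` when given).
#' @return A `primordium_set`: `labels` (integer matrix, 0 = background),
#'   `table` (data.frame `label`, `area_px`, `area_mm2`, `row`, `col`,
#'   `x_um`, `y_um`) and `pixel_size_um`. Centers are intensity-weighted
#'   centroids (weight = intensity above the frame median).
#' @export
detect_primordia <- function(frame, threshold_quantile = 0.30,
                             gaussian_sigma_px = 10, min_area_px = 10000,
                             min_area_um2 = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    pf_stop("invalid_spec", "threshold_quantile must lie in (0, 1)")
  if (!is.null(min_area_um2))
    min_area_px <- round(min_area_um2 / frame$pixel_size_um^2)
  if (min_area_px < 1) pf_stop("invalid_spec", "min_area_px must be >= 1")
  px <- frame$pixels
  if (max(px) == min(px)) {
    pf_warn("constant_frame", "constant frame: no primordia detectable")
    return(empty_primordium_set(dim(px), frame$pixel_size_um))
  }
  thr <- nearest_rank_quantile(px, 1 - threshold_quantile)
  retained <- px
  retained[px < thr] <- 0
  m_ret <- mean(retained[retained > 0])
  sm <- if (gaussian_sigma_px > 0) {
    sc <- max(retained)
    EBImage::gblur(retained / sc, sigma = gaussian_sigma_px) * sc
  } else retained
  mask <- sm > m_ret / 2
  lab <- label_components8(mask)
  if (max(lab) == 0)
    return(empty_primordium_set(dim(px), frame$pixel_size_um))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0)
    return(empty_primordium_set(dim(px), frame$pixel_size_um))
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out_lab[nz] <- relab[lab[nz]]  # non-kept labels map to 0
  # centers: intensity-weighted centroids (weight = intensity above the
  # frame median), so the bright condensation dominates over any dimmer
  # texture attached to the component; falls back to the binary centroid
  # for flat components
  wts <- pmax(px - stats::median(px), 0)
  cen_row <- numeric(length(keep))
  cen_col <- numeric(length(keep))
  for (i in seq_along(keep)) {
    sel <- lab == keep[i]
    w <- wts[sel]
    if (sum(w) > 0) {
      cen_row[i] <- sum(row(lab)[sel] * w) / sum(w)
      cen_col[i] <- sum(col(lab)[sel] * w) / sum(w)
    } else {
      cen_row[i] <- mean(row(lab)[sel])
      cen_col[i] <- mean(col(lab)[sel])
    }
  }
  psz <- frame$pixel_size_um
  tab <- data.frame(label = seq_along(keep), area_px = areas[keep],
                    area_mm2 = areas[keep] * psz^2 * 1e-6,
                    row = cen_row, col = cen_col,
                    x_um = (cen_col - 1) * psz, y_um = (cen_row - 1) * psz)
  structure(list(labels = out_lab, table = tab, pixel_size_um = psz),
            class = "primordium_set")
}

empty_primordium_set <- function(dims, pixel_size_um) {
  structure(list(labels = matrix(0L, dims[1], dims[2]),
                 table = data.frame(label = integer(0), area_px = integer(0),
                                    area_mm2 = numeric(0), row = numeric(0),
                                    col = numeric(0), x_um = numeric(0),
                                    y_um = numeric(0)),
                 pixel_size_um = pixel_size_um),
            class = "primordium_set")
}

#' @export
print.primordium_set <- function(x, ...) {
  cat(sprintf("<primordium_set> %d components\n", nrow(x$table)))
  invisible(x)
}

spacing_stats <- function(distances, n_excluded = 0) {
  m <- mean(distances)
  s <- stats::sd(distances)  # sample sd, n - 1 denominator
  structure(list(distances_um = distances, mean_um = m, sd_um = s,
                 spacing_variability = s / m,
                 n_edges_used = length(distances),
                 n_edges_excluded = n_excluded),
            class = "spacing_stats")
}

#' @export
print.spacing_stats <- function(x, ...) {
  cat(sprintf("<spacing_stats> n = %d edges, mean = %.2f um, sd = %.2f um, spacing variability = %.4f\n",
              x$n_edges_used, x$mean_um, x$sd_um, x$spacing_variability))
  invisible(x)
}

#' Spacing variability along the first-formed row
#'
#' Pattern-fidelity statistic for species whose primordia arise in
#' longitudinal lines: the sample standard deviation of Euclidean distances
#' between consecutive primordium centers, normalized to the mean distance
#' (dimensionless; lower = more regular pattern).
#'
#' @param ordered_centers data.frame or matrix (`x_um`, `y_um`), already
#'   ordered along the row axis; at least 3 centers.
#' @return A `spacing_stats` object.
#' @export
row_spacing_variability <- function(ordered_centers) {
  pts <- as.matrix(as.data.frame(ordered_centers)[, 1:2])
  if (nrow(pts) < 3)
    pf_stop("insufficient_points", "need at least 3 centers in the row")
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  spacing_stats(d)
}

#' Spacing variability from the Delaunay triangulation
#'
#' Pattern-fidelity statistic for array-forming species: neighbouring
#' primordia are pairs joined by a Delaunay edge; edges with a vertex on
#' the convex-hull boundary of the point set are excluded (they connect to
#' artificially under-constrained border primordia), and the statistic is
#' the sample sd of the remaining edge lengths normalized to their mean.
#'
#' @param centers data.frame or matrix (`x_um`, `y_um`); at least 4
#'   non-collinear points.
#' @return A `spacing_stats` object (also carries `edges_used`, an index
#'   matrix, for audit).
#' @export
delaunay_spacing_variability <- function(centers) {
  pts <- as.matrix(as.data.frame(centers)[, 1:2])
  tri <- delaunay_triangulate(pts)
  boundary <- hull_boundary_points(pts)
  interior_edge <- !(tri$edges[, 1] %in% boundary |
                       tri$edges[, 2] %in% boundary)
  used <- tri$edges[interior_edge, , drop = FALSE]
  n_excl <- sum(!interior_edge)
  if (nrow(used) == 0)
    pf_stop("no_interior_edges",
            "every triangulation edge touches the boundary")
  if (nrow(used) < 2)
    pf_stop("insufficient_points",
            "fewer than 2 interior edges; sd undefined")
  d <- sqrt((pts[used[, 1], 1] - pts[used[, 2], 1])^2 +
              (pts[used[, 1], 2] - pts[used[, 2], 2])^2)
  out <- spacing_stats(d, n_excl)
  out$edges_used <- used
  out
}

#' Primordia density in a rectangular region of interest
#'
#' Count of primordium centers per unit area (primordia per mm^2, whether
#' counted in 1 mm^2 squares for arrays or 0.3 x 1 mm first-row
#' rectangles). The rectangle is half-open: a center on a low-coordinate
#' edge counts, one on a high-coordinate edge does not.
#'
#' @param set a `primordium_set` or a data.frame of centers (`x_um`,
#'   `y_um`).
#' @param roi_mm numeric length-4: `xmin`, `ymin`, `xmax`, `ymax` in mm.
#' @return density in primordia per mm^2.
#' @export
primordia_density <- function(set, roi_mm) {
  centers <- if (inherits(set, "primordium_set")) set$table else
    as.data.frame(set)
  if (length(roi_mm) != 4) pf_stop("invalid_roi", "roi_mm must be length 4")
  w <- roi_mm[3] - roi_mm[1]
  h <- roi_mm[4] - roi_mm[2]
  if (w <= 0 || h <= 0) pf_stop("invalid_roi", "roi must have positive area")
  if (nrow(centers) == 0) return(0)
  x <- centers$x_um / 1000
  y <- centers$y_um / 1000
  inside <- x >= roi_mm[1] & x < roi_mm[3] & y >= roi_mm[2] & y < roi_mm[4]
  sum(inside) / (w * h)
}

#' Primordium areas in mm^2
#'
#' Component pixel areas converted to physical units:
#' `area_px * pixel_size_um^2 * 1e-6`.
#'
#' @param set a `primordium_set`.
#' @param labels component labels to query (default all).
#' @return named numeric vector of areas in mm^2.
#' @export
primordium_areas <- function(set, labels = NULL) {
  stopifnot(inherits(set, "primordium_set"))
  if (is.null(labels)) labels <- set$table$label
  miss <- setdiff(labels, set$table$label)
  if (length(miss) > 0)
    pf_stop("unknown_label", paste("unknown label(s):",
                                   paste(miss, collapse = ", ")))
  out <- set$table$area_mm2[match(labels, set$table$label)]
  names(out) <- labels
  out
}

# Shoelace area of a simple polygon; vertices as n x 2 matrix.
shoelace_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

segments_properly_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

check_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3) pf_stop("invalid_polygon", "polygon needs at least 3 vertices")
  seg <- function(i) list(a = v[i, ], b = v[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j == i || j == i %% n + 1 || i == j %% n + 1) next  # adjacent
    si <- seg(i); sj <- seg(j)
    if (segments_properly_intersect(si$a, si$b, sj$a, sj$b))
      pf_stop("invalid_polygon", "polygon is self-intersecting")
  }
  invisible(v)
}

#' Explant surface-area retractation from two outlines
#'
#' Cultured skin explants shrink between preparation and differentiation;
#' the readout is the percentage of surface area lost between the outline
#' at t0 and at t1, areas computed by the shoelace formula.
#'
#' @param outline_t0,outline_t1 data.frames or matrices of polygon vertices
#'   (x, y) in mm; each a simple polygon with >= 3 vertices.
#' @return list `area_t0_mm2`, `area_t1_mm2`, `retractation_percent`
#'   (`100 * (1 - area_t1 / area_t0)`).
#' @export
polygon_area_retractation <- function(outline_t0, outline_t1) {
  v0 <- as.matrix(as.data.frame(outline_t0)[, 1:2])
  v1 <- as.matrix(as.data.frame(outline_t1)[, 1:2])
  check_simple_polygon(v0)
  check_simple_polygon(v1)
  a0 <- shoelace_area(v0)
  a1 <- shoelace_area(v1)
  list(area_t0_mm2 = a0, area_t1_mm2 = a1,
       retractation_percent = 100 * (1 - a1 / a0))
}
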