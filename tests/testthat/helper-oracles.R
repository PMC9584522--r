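# Independent oracles and fixture builders shared across test files.

# Brute-force Delaunay: a triangle belongs to the triangulation iff its
# circumcircle contains no other point (O(n^4) triple test). Independent of
# the package's incremental-flip construction.
oracle_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  tris <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
    ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all((pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2 >=
            r2 * (1 - 1e-12)))
      tris <- rbind(tris, c(i, j, k))
  }
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(1, 3)])
  unique(t(apply(e, 1, sort)))
}

edge_key <- function(m) sort(paste(m[, 1], m[, 2]))

# Circularly shift frame content by (dr, dc) pixels (content moves down /
# rightwards for positive shifts) — an exact planted translation.
circshift_frame <- function(frame, dr, dc) {
  m <- frame$pixels
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 - dr) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dc) %% nc) + 1
  image_frame(m[ri, ci], frame$pixel_size_um, frame$timestamp_min)
}

# Frame with Gaussian blobs added to a seeded dim texture (noise-free;
# condensations are much brighter than the background, as in DAPI views).
blob_frame <- function(centers, side = 256, radius_um = 30, peak = 300,
                       seed = 7, contrast_sd = 15) {
  tex <- generate_texture(scene_spec(side, side, noise_sd = 0,
                                     contrast_sd = contrast_sd, seed = seed))
  px <- tex$pixels
  sig <- radius_um / 2
  rows <- seq_len(side); cols <- seq_len(side)
  for (i in seq_len(nrow(centers))) {
    px <- px + peak * outer(exp(-(rows - 1 - centers$y_um[i])^2 / (2 * sig^2)),
                            exp(-(cols - 1 - centers$x_um[i])^2 / (2 * sig^2)))
  }
  image_frame(px, 1)
}

# Hand-built velocity field on an n x n box grid with stride h (um).
manual_field <- function(u, v, stride_um, frame_interval_min = 5) {
  structure(list(u = u, v = v, speed = sqrt(u^2 + v^2),
                 valid = matrix(TRUE, nrow(u), ncol(u)),
                 stride_um = stride_um, window_px = 32L,
                 stride_px = as.integer(stride_um),
                 center_x_um = (seq_len(ncol(u)) - 1) * stride_um,
                 center_y_um = (seq_len(nrow(u)) - 1) * stride_um,
                 frame_interval_min = frame_interval_min,
                 pixel_size_um = 1),
            class = "velocity_field")
}
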