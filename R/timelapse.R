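# Dynamic analysis of time-lapse stacks: drift registration, automatic
# region detection from anisotropy, series smoothing/alignment, divergence
# and antero-posterior primordia tracking.

translate_replicate <- function(mat, dr, dc) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  mat[ri, ci, drop = FALSE]
}

#' Correct x/y drift of a movie by translation-only registration
#'
#' Consecutive frames are registered by integer-pixel phase correlation;
#' cumulative shifts are removed so every frame is aligned to the first,
#' borders filled by edge replication. Pairs whose phase-correlation peak
#' is not clearly dominant — peak below `peak_snr_min` standard deviations
#' of the correlation surface — are flagged low confidence; for unrelated
#' (pure-noise) frame pairs the peak stays near the Gaussian-maximum
#' ceiling `sqrt(2 log N)` (about 5 for typical frames), while a genuine
#' translation scores orders of magnitude higher.
#'
#' @param frames list of [image_frame()]s with identical geometry.
#' @param peak_snr_min dominance threshold for the confidence flag.
#' @return list `frames` (aligned), `shifts` (data.frame `frame`,
#'   `shift_row_px`, `shift_col_px` — cumulative drift of each frame
#'   relative to the first — and `low_confidence`).
#' @export
register_drift <- function(frames, peak_snr_min = 8) {
  if (length(frames) < 2) pf_stop("invalid_spec", "need at least 2 frames")
  dims <- dim(frames[[1]]$pixels)
  for (f in frames) if (!identical(dim(f$pixels), dims))
    pf_stop("frame_mismatch", "all frames must share geometry")
  nr <- dims[1]; nc <- dims[2]
  cum <- matrix(0L, length(frames), 2)
  lowc <- logical(length(frames))
  for (k in 2:length(frames)) {
    fa <- stats::fft(frames[[k - 1]]$pixels - mean(frames[[k - 1]]$pixels))
    fb <- stats::fft(frames[[k]]$pixels - mean(frames[[k]]$pixels))
    cp <- Conj(fa) * fb
    r <- Re(stats::fft(cp / (Mod(cp) + 1e-12), inverse = TRUE)) / (nr * nc)
    pk <- arrayInd(which.max(r), dims)
    lowc[k] <- max(r) < peak_snr_min * stats::sd(r)
    cum[k, ] <- cum[k - 1, ] + c(wrap_offset(pk[1], nr),
                                 wrap_offset(pk[2], nc))
  }
  aligned <- vector("list", length(frames))
  aligned[[1]] <- frames[[1]]
  for (k in 2:length(frames))
    aligned[[k]] <- as_frame_like(translate_replicate(frames[[k]]$pixels,
                                                      cum[k, 1], cum[k, 2]),
                                  frames[[k]])
  list(frames = aligned,
       shifts = data.frame(frame = seq_along(frames),
                           shift_row_px = cum[, 1], shift_col_px = cum[, 2],
                           low_confidence = lowc))
}

#' Auto-detect competent segment and primordium regions from anisotropy
#'
#' From a grid of per-box temporal-mean anisotropy amplitudes, the
#' competent segment is the window of 3 adjacent grid columns
#' (dorso-ventral positions) with maximal mean amplitude; within it, the
#' putative inter-primordium region is the 4 boxes of maximal mean
#' amplitude and the primordium region the 4 boxes of minimal mean
#' amplitude. For velocimetry each region is enlarged to a 3x3 block
#' centered on the 4-box region's centroid row, with its central column
#' forced to the middle segment column and rows clamped into the grid.
#' Ties are broken toward the smallest column index (windows) and
#' row-major order (boxes); the two 4-box sets are kept disjoint.
#'
#' @param per_box_mean_amplitude numeric matrix `[box_row, box_col]` of
#'   temporal-mean anisotropy amplitude.
#' @return A `region_assignment`: `segment_cols` (3 consecutive column
#'   indices), `ip_boxes_4`, `p_boxes_4`, `ip_boxes_9`, `p_boxes_9` (each
#'   a 2-column matrix of box_row, box_col).
#' @export
detect_regions <- function(per_box_mean_amplitude) {
  m <- as.matrix(per_box_mean_amplitude)
  if (ncol(m) < 3) pf_stop("grid_too_small", "need at least 3 grid columns")
  if (nrow(m) < 3) pf_stop("grid_too_small", "need at least 3 grid rows")
  if (any(!is.finite(m))) pf_stop("invalid_spec", "amplitudes must be finite")
  nwin <- ncol(m) - 2
  wmean <- vapply(seq_len(nwin), function(j) mean(m[, j:(j + 2)]),
                  numeric(1))
  j0 <- which.max(wmean)  # ties -> smallest start
  segment_cols <- j0:(j0 + 2)
  sub <- expand.grid(box_row = seq_len(nrow(m)), box_col = segment_cols)
  sub$amp <- m[as.matrix(sub[, 1:2])]
  ord_hi <- order(-sub$amp, sub$box_row, sub$box_col)
  ip4 <- as.matrix(sub[ord_hi[1:4], 1:2])
  rest <- setdiff(seq_len(nrow(sub)), ord_hi[1:4])
  ord_lo <- rest[order(sub$amp[rest], sub$box_row[rest], sub$box_col[rest])]
  p4 <- as.matrix(sub[ord_lo[1:4], 1:2])
  block9 <- function(four) {
    cr <- round(mean(four[, 1]))
    cr <- min(max(cr, 2), nrow(m) - 1)
    cbind(box_row = rep((cr - 1):(cr + 1), times = 3),
          box_col = rep(segment_cols, each = 3))
  }
  structure(list(segment_cols = segment_cols,
                 ip_boxes_4 = unname(ip4), p_boxes_4 = unname(p4),
                 ip_boxes_9 = block9(ip4), p_boxes_9 = block9(p4)),
            class = "region_assignment")
}

#' Smooth a per-frame series and align it on a reference time point
#'
#' Centered moving average of nominal width `window_frames` (at the series
#' ends the window shrinks symmetrically, preserving length and leaving
#' linear trends untouched), with the time axis re-zeroed at `t_ref_frame`
#' — the frame of the first visible condensation when aligning real
#' movies. Missing values are linearly interpolated before smoothing.
#'
#' @param values numeric per-frame series (length >= 2).
#' @param window_frames nominal smoothing window (default 30 frames, i.e.,
#'   2 h 30 min at 5-min intervals).
#' @param t_ref_frame reference frame index within the series.
#' @param frame_interval_min frame interval, minutes.
#' @return An `aligned_series`: `values` (smoothed), `raw`, `time_min`
#'   (`(frame - t_ref_frame) * frame_interval_min`), `t_ref_frame`,
#'   `window_frames`, `frame_interval_min`.
#' @export
smooth_and_align <- function(values, window_frames = 30, t_ref_frame,
                             frame_interval_min = 5) {
  n <- length(values)
  if (n < 2) pf_stop("invalid_spec", "series must have length >= 2")
  if (t_ref_frame < 1 || t_ref_frame > n)
    pf_stop("invalid_tref", "t_ref_frame outside the series")
  if (anyNA(values)) {
    ok <- which(!is.na(values))
    if (length(ok) < 2) pf_stop("invalid_spec", "too few non-missing values")
    values <- stats::approx(ok, values[ok], xout = seq_len(n),
                            rule = 2)$y
  }
  h <- window_frames %/% 2
  sm <- vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(values[(i - k):(i + k)])
  }, numeric(1))
  structure(list(values = sm, raw = values,
                 time_min = (seq_len(n) - t_ref_frame) * frame_interval_min,
                 t_ref_frame = as.integer(t_ref_frame),
                 window_frames = as.integer(window_frames),
                 frame_interval_min = frame_interval_min, smoothed = TRUE),
            class = "aligned_series")
}

#' Average several aligned series over their common support
#'
#' Cross-movie compilation: series aligned on their own reference frames
#' are averaged pointwise over the intersection of their aligned frame
#' offsets.
#'
#' @param series_list list of `aligned_series` with equal frame intervals.
#' @return list `offset_frames`, `time_min`, `mean_values`, `n_series`.
#' @export
aggregate_aligned <- function(series_list) {
  if (length(series_list) == 0) pf_stop("invalid_spec", "empty series list")
  iv <- vapply(series_list, function(s) s$frame_interval_min, numeric(1))
  if (length(unique(iv)) != 1)
    pf_stop("invalid_spec", "series have differing frame intervals")
  offs <- lapply(series_list, function(s)
    seq_along(s$values) - s$t_ref_frame)
  common <- Reduce(intersect, offs)
  if (length(common) == 0)
    pf_stop("invalid_spec", "aligned supports do not overlap")
  common <- sort(common)
  vals <- vapply(seq_along(series_list), function(i)
    series_list[[i]]$values[match(common, offs[[i]])],
    numeric(length(common)))
  vals <- matrix(vals, nrow = length(common))
  list(offset_frames = common, time_min = common * iv[1],
       mean_values = rowMeans(vals), n_series = length(series_list))
}

#' Heuristic reference-frame estimate from a primordium-region series
#'
#' The reference time point t_ref marks the first visible condensation of
#' cells into a primordium and is normally identified by eye and supplied
#' by the user (or taken from synthetic ground truth). This optional
#' heuristic instead flags the first frame at which the primordium-region
#' mean anisotropy amplitude drops more than 2 standard deviations below
#' its pre-drop baseline (estimated over the leading
#' `baseline_fraction` of the smoothed series).
#'
#' @param values per-frame primordium-region mean amplitude.
#' @param window_frames smoothing window passed to [smooth_and_align()].
#' @param baseline_fraction leading fraction of frames treated as
#'   pre-condensation baseline.
#' @return integer frame index, or `NA` if no drop is found.
#' @export
estimate_t_ref <- function(values, window_frames = 30,
                           baseline_fraction = 0.25) {
  n <- length(values)
  if (n < 8) pf_stop("invalid_spec", "series too short for t_ref heuristic")
  sm <- smooth_and_align(values, window_frames, t_ref_frame = 1)$values
  nb <- max(3, floor(baseline_fraction * n))
  mu <- mean(sm[1:nb])
  sdv <- stats::sd(sm[1:nb])
  hit <- which(sm < mu - 2 * sdv)
  hit <- hit[hit > nb]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

check_region <- function(field_dim, boxes) {
  boxes <- as.matrix(boxes)
  if (any(boxes[, 1] < 1) || any(boxes[, 1] > field_dim[1]) ||
      any(boxes[, 2] < 1) || any(boxes[, 2] > field_dim[2]))
    pf_stop("region_out_of_bounds", "region boxes fall outside the field")
  boxes
}

#' Mean cell motility over a 9-box region
#'
#' Arithmetic mean of the speed norms of the region's vectors (replaced
#' outlier vectors contribute their infilled values; their count is
#' reported).
#'
#' @param field a `velocity_field`.
#' @param region_boxes_9 2-column matrix of (box_row, box_col), typically
#'   a 3x3 block from [detect_regions()].
#' @return list `mean_speed_um_h`, `n_replaced`.
#' @export
region_motility <- function(field, region_boxes_9) {
  stopifnot(inherits(field, "velocity_field"))
  b <- check_region(dim(field$speed), region_boxes_9)
  list(mean_speed_um_h = mean(field$speed[b]),
       n_replaced = sum(!field$valid[b]))
}

#' Divergence of a velocity field
#'
#' `du/dx + dv/dy` on the box grid by central differences (one-sided at the
#' edges), grid spacing equal to the box stride in micrometres. Negative
#' divergence indicates tissue contraction/convergence (condensation);
#' zero means no contraction or extension.
#'
#' @param field a `velocity_field` of at least 3 x 3 boxes.
#' @return matrix of per-box divergence in 1/h.
#' @export
field_divergence <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  u <- field$u
  v <- field$v
  if (nrow(u) < 3 || ncol(u) < 3)
    pf_stop("field_too_small", "divergence needs at least 3 x 3 boxes")
  h <- field$stride_um
  ddx <- function(m) {  # along columns (x)
    out <- m
    nc <- ncol(m)
    out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / (2 * h)
    out[, 1] <- (m[, 2] - m[, 1]) / h
    out[, nc] <- (m[, nc] - m[, nc - 1]) / h
    out
  }
  ddy <- function(m) t(ddx(t(m)))  # along rows (y)
  ddx(u) + ddy(v)
}

#' Mean divergence over a 9-box region
#'
#' @param field a `velocity_field`.
#' @param region_boxes_9 2-column matrix of (box_row, box_col).
#' @return mean divergence in 1/h.
#' @export
region_divergence <- function(field, region_boxes_9) {
  dv <- field_divergence(field)
  b <- check_region(dim(dv), region_boxes_9)
  mean(dv[b])
}

#' Track primordia along the antero-posterior axis, detecting fusions
#'
#' Runs [detect_primordia()] on every frame and links detections across
#' frames by nearest antero-posterior (row-centroid) position within a
#' gate. An unmatched detection opens a new track; when two tracks claim
#' the same detection the nearer one continues and the other ends, with a
#' fusion event recorded on the surviving track at that frame — the
#' signature of two primordia merging.
#'
#' @param frames list of [image_frame()]s (>= 2).
#' @param threshold_quantile,gaussian_sigma_px,min_area_px,min_area_um2
#'   detector parameters, see [detect_primordia()].
#' @param gate_px association gate in pixels; default 1.5 x the mean
#'   detected blob radius `sqrt(area / pi)`.
#' @return list of `primordium_track`s: `track_id`, `positions` (AP
#'   centroid in px per frame, NA outside `[start_frame, end_frame]`),
#'   `start_frame`, `end_frame`, `fusion_events` (data.frame `frame`,
#'   `absorbed_track_id`).
#' @export
track_primordia <- function(frames, threshold_quantile = 0.30,
                            gaussian_sigma_px = 10, min_area_px = 10000,
                            min_area_um2 = NULL, gate_px = NULL) {
  if (length(frames) < 2) pf_stop("invalid_spec", "need at least 2 frames")
  dets <- lapply(frames, function(f)
    detect_primordia(f, threshold_quantile, gaussian_sigma_px,
                     min_area_px, min_area_um2)$table)
  if (all(vapply(dets, nrow, integer(1)) == 0)) {
    pf_warn("no_detections", "no primordia detected in any frame")
    return(list())
  }
  if (is.null(gate_px)) {
    all_areas <- unlist(lapply(dets, function(d) d$area_px))
    gate_px <- 1.5 * mean(sqrt(all_areas / pi))
  }
  nfr <- length(frames)
  tracks <- list()
  new_track <- function(id, frame, ap) {
    pos <- rep(NA_real_, nfr)
    pos[frame] <- ap
    list(track_id = id, positions = pos, start_frame = frame,
         end_frame = frame,
         fusion_events = data.frame(frame = integer(0),
                                    absorbed_track_id = integer(0)),
         active = TRUE)
  }
  next_id <- 1L
  for (ap in dets[[1]]$row) {
    tracks[[next_id]] <- new_track(next_id, 1L, ap)
    next_id <- next_id + 1L
  }
  for (k in 2:nfr) {
    aps <- dets[[k]]$row
    active <- which(vapply(tracks, function(t) t$active, logical(1)))
    claims <- data.frame(track = integer(0), det = integer(0),
                         dist = numeric(0))
    for (ti in active) {
      last_ap <- tracks[[ti]]$positions[tracks[[ti]]$end_frame]
      if (length(aps) > 0) {
        d <- abs(aps - last_ap)
        j <- which.min(d)
        if (d[j] <= gate_px)
          claims <- rbind(claims, data.frame(track = ti, det = j,
                                             dist = d[j]))
      }
    }
    claimed_det <- integer(0)
    if (nrow(claims) > 0) {
      for (j in unique(claims$det)) {
        grp <- claims[claims$det == j, , drop = FALSE]
        grp <- grp[order(grp$dist, grp$track), , drop = FALSE]
        winner <- grp$track[1]
        tracks[[winner]]$positions[k] <- aps[j]
        tracks[[winner]]$end_frame <- k
        claimed_det <- c(claimed_det, j)
        if (nrow(grp) > 1) for (loser in grp$track[-1]) {
          tracks[[loser]]$active <- FALSE  # absorbed: ends at frame k - 1
          tracks[[winner]]$fusion_events <-
            rbind(tracks[[winner]]$fusion_events,
                  data.frame(frame = k, absorbed_track_id = loser))
        }
      }
    }
    # tracks with no claim end silently
    for (ti in active) {
      if (tracks[[ti]]$active && tracks[[ti]]$end_frame < k)
        tracks[[ti]]$active <- FALSE
    }
    # unclaimed detections open new tracks
    for (j in setdiff(seq_along(aps), claimed_det)) {
      tracks[[next_id]] <- new_track(next_id, k, aps[j])
      next_id <- next_id + 1L
    }
  }
  lapply(tracks, function(t) {
    t$active <- NULL
    class(t) <- "primordium_track"
    t
  })
}

#' Tidy table of primordium tracks
#'
#' @param tracks list of `primordium_track`s from [track_primordia()].
#' @return data.frame `track_id`, `frame`, `ap_position_px`, `event`
#'   (`""`, or `"fusion_absorbs:<id>"` on the surviving track at the
#'   fusion frame).
#' @export
tracks_table <- function(tracks) {
  rows <- lapply(tracks, function(t) {
    fr <- t$start_frame:t$end_frame
    ev <- rep("", length(fr))
    if (nrow(t$fusion_events) > 0)
      for (i in seq_len(nrow(t$fusion_events))) {
        w <- which(fr == t$fusion_events$frame[i])
        if (length(w)) ev[w] <- paste0("fusion_absorbs:",
                                       t$fusion_events$absorbed_track_id[i])
      }
    data.frame(track_id = t$track_id, frame = fr,
               ap_position_px = t$positions[fr], event = ev)
  })
  do.call(rbind, rows)
}
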