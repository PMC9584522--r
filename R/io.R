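# Readers/writers: TIFF stacks, centers CSVs, result bundles, run config.

#' Read a grayscale TIFF image or stack
#'
#' Pages become frames in acquisition order with timestamps
#' `k * frame_interval_min`, k = 0, 1, .... Intensities are rescaled to
#' 16-bit units (0..65535). RGB pages are rejected: split channels
#' upstream.
#'
#' @param path TIFF file path.
#' @param pixel_size_um physical pixel size (not stored reliably in TIFF
#'   tags; must be supplied).
#' @param frame_interval_min interval between pages, minutes (default 5).
#' @return list of [image_frame()]s.
#' @export
read_image_stack <- function(path, pixel_size_um, frame_interval_min = 5) {
  if (!file.exists(path)) pf_stop("format_error", paste("no such file:", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      pf_stop("format_error",
                              paste("not a readable TIFF:", conditionMessage(e))))
  lapply(seq_along(pages), function(k) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1] else
        pf_stop("unsupported_channels",
                "RGB/multi-channel TIFF: split channels before import")
    }
    image_frame(p * 65535, pixel_size_um,
                timestamp_min = (k - 1) * frame_interval_min)
  })
}

#' Write frames as a multi-page 16-bit TIFF
#'
#' @param frames an [image_frame()] or list of them; intensities are
#'   clipped into 0..65535 and stored as 16-bit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path) {
  if (inherits(frames, "image_frame")) frames <- list(frames)
  imgs <- lapply(frames, function(f) {
    m <- f$pixels / 65535
    m[m > 1] <- 1
    m[m < 0] <- 0
    m
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}

#' Read primordium centers from CSV
#'
#' Expected columns `x_um`, `y_um`; extra columns (e.g., `flag` for
#' manual-correction provenance) are preserved.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_centers_csv <- function(path) {
  if (!file.exists(path)) pf_stop("format_error", paste("no such file:", path))
  d <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(d)))
    pf_stop("format_error", "centers CSV needs columns x_um, y_um")
  d
}

#' Write primordium centers to CSV at full double precision
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write/read round trip reproduces the coordinates (and hence any spacing
#' statistic computed from them) bit-identically.
#'
#' @param centers data.frame with at least `x_um`, `y_um`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(centers, path) {
  d <- as.data.frame(centers)
  for (nm in names(d)) if (is.numeric(d[[nm]]))
    d[[nm]] <- formatC(d[[nm]], digits = 17, format = "g")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a resolved run configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults,
#' optionally overlaid from a YAML config file and per-call overrides.
#' Written alongside outputs for provenance.
#'
#' @param config_file optional YAML file path.
#' @param ... named overrides (highest precedence).
#' @return A `run_config` list.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- list(pixel_size_um = 1, frame_interval_min = 5, box_size_um = 25,
              overlap_fraction = 0.5, threshold_quantile = 0.30,
              gaussian_sigma_px = 10, min_area_px = 10000,
              min_area_um2 = NULL, piv_window_px = 32, ap_axis = "rows",
              seed = 1L, output_dir = ".")
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      pf_stop("format_error", paste("no such config:", config_file))
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  over <- list(...)
  cfg[names(over)] <- over
  for (f in c("pixel_size_um", "frame_interval_min", "box_size_um"))
    check_positive(cfg[[f]], f)
  if (cfg$threshold_quantile <= 0 || cfg$threshold_quantile >= 1)
    pf_stop("invalid_spec", "threshold_quantile must lie in (0, 1)")
  if (!cfg$ap_axis %in% c("rows", "cols"))
    pf_stop("invalid_spec", "ap_axis must be 'rows' or 'cols'")
  structure(cfg, class = "run_config")
}

#' Write result tables, resolved config and a log to a directory
#'
#' Tables are written as CSVs with fixed column order, the resolved config
#' as JSON, and the messages as a plain-text log; re-running with
#' identical inputs reproduces identical bytes.
#'
#' @param output_dir destination directory (created if missing).
#' @param tables named list of data.frames; each becomes `<name>.csv`.
#' @param config optional `run_config` (or plain list) written as
#'   `config.json`.
#' @param log_lines character vector appended to `run.log`.
#' @return character vector of paths written, invisibly.
#' @export
write_results <- function(output_dir, tables = list(), config = NULL,
                          log_lines = character(0)) {
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir))
    pf_stop("io_error", paste("cannot create", output_dir))
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(output_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(config)) {
    p <- file.path(output_dir, "config.json")
    jsonlite::write_json(unclass(config), p, auto_unbox = TRUE,
                         null = "null", digits = NA)
    paths <- c(paths, p)
  }
  if (length(log_lines) > 0) {
    p <- file.path(output_dir, "run.log")
    writeLines(log_lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
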