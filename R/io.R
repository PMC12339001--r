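## TIFF/CSV/YAML/JSON I/O, analysis configuration and audit logging.

#' Package logging
#'
#' Every automatically chosen threshold, mask size and region pixel count is
#' logged so each figure-style quantification can be audited post hoc.
#' Logging is off by default; enable with
#' `options(mitoquant.verbose = TRUE)`.
#'
#' @param fmt `sprintf` format string.
#' @param ... Values for `fmt`.
#' @return Invisibly, the formatted line (emitted via [message()] when
#'   verbose).
#' @export
mq_log <- function(fmt, ...) {
  line <- sprintf(paste0("[mitoquant] ", fmt), ...)
  if (isTRUE(getOption("mitoquant.verbose", FALSE))) message(line)
  invisible(line)
}

#' Analysis configuration with the pipeline's standard defaults
#'
#' Holds the parameters every quantification shares. The defaults are the
#' pipeline's standard values: Gaussian radius 2 px, ring width 10 px,
#' rolling-ball radius 5 px, minimum cluster area 0.15 um^2, six 60-degree
#' sectors. Precedence when resolving a value is call argument > config
#' file > default.
#'
#' @param pixel_size_um Micrometres per pixel (no default: must come from
#'   TIFF metadata or be supplied).
#' @param channels Named list mapping channel roles to page indices in
#'   multichannel files.
#' @param ring_width_px Dilation width for the accumulation ring.
#' @param gaussian_radius_px Smoothing radius.
#' @param rolling_ball_radius_px Background-subtraction radius.
#' @param min_cluster_area_um2 Cluster size filter (strictly larger-than).
#' @param n_sectors Angular sectors.
#' @param out_dir Output directory for results.
#' @param seed Integer seed for stochastic steps.
#' @return List of class `mq_config`.
#' @export
analysis_config <- function(pixel_size_um = NULL,
                            channels = list(mito = 1L, chromatin = 2L),
                            ring_width_px = 10L,
                            gaussian_radius_px = 2,
                            rolling_ball_radius_px = 5,
                            min_cluster_area_um2 = 0.15,
                            n_sectors = 6L,
                            out_dir = ".",
                            seed = 1L) {
  structure(list(pixel_size_um = pixel_size_um, channels = channels,
                 ring_width_px = as.integer(ring_width_px),
                 gaussian_radius_px = gaussian_radius_px,
                 rolling_ball_radius_px = rolling_ball_radius_px,
                 min_cluster_area_um2 = min_cluster_area_um2,
                 n_sectors = as.integer(n_sectors),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "mq_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Fields present in the file override the defaults of [analysis_config];
#' unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return List of class `mq_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  base <- analysis_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown))
    stop_input(sprintf("unknown config fields: %s",
                       paste(unknown, collapse = ", ")))
  out <- utils::modifyList(unclass(base), vals)
  class(out) <- "mq_config"
  mq_log("config: %s", paste(names(vals), vals, sep = "=", collapse = " "))
  out
}

.pixel_size_from_info <- function(info) {
  if (is.null(info)) return(NULL)
  xres <- attr(info, "x.resolution")
  if (is.null(xres) && !is.null(info$x.resolution)) xres <- info$x.resolution
  unit <- attr(info, "resolution.unit")
  if (is.null(unit) && !is.null(info$resolution.unit))
    unit <- info$resolution.unit
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  per_unit_um <- switch(as.character(unit %||% "inch"),
                        inch = 25400, cm = 10000, `3` = 10000, `2` = 25400,
                        NULL)
  if (is.null(per_unit_um)) return(NULL)
  per_unit_um / xres
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## integer matrix (0-based intensities) from readTIFF output
.tiff_to_matrix <- function(page) {
  if (length(dim(page)) == 3L) page <- page[, , 1L]   # first sample
  matrix(as.numeric(page), nrow(page), ncol(page))    # strip info attributes
}

#' Read a TIFF image or stack
#'
#' Reads single-plane or multi-page (Z) TIFFs, 8/16-bit unsigned or 32-bit
#' float, preserving integer intensities bit-exactly. The pixel size is
#' resolved in order: the `pixel_size_um` argument (or config), then the
#' file's resolution tags (inch or cm units); if neither is available an
#' error names the missing field.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Optional pixel size override, um/px.
#' @param config Optional [analysis_config]; its `pixel_size_um` acts as the
#'   override and its `z_step_um` default of 1 um applies to stacks.
#' @param channel_role Channel role recorded on the images.
#' @param z_step_um Plane spacing for stacks (default 1 um).
#' @return An [mq_image] (single page) or [mq_zstack] (multi-page).
#' @export
read_image <- function(path, pixel_size_um = NULL, config = NULL,
                       channel_role = "other", z_step_um = 1) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ps <- pixel_size_um %||% config$pixel_size_um %||%
    .pixel_size_from_info(attributes(pages[[1L]]))
  if (is.null(ps))
    stop_input(paste0("pixel_size_um missing: not in TIFF resolution tags ",
                      "and not supplied via argument or config"))
  bit <- attr(pages[[1L]], "bits.per.sample") %||% NULL
  origin <- if (is.null(bit)) "float"
  else if (bit <= 8) "u8" else if (bit <= 16) "u16" else "float"
  imgs <- lapply(pages, function(pg)
    mq_image(.tiff_to_matrix(unclass(pg)), ps, channel_role, origin))
  if (length(imgs) == 1L) imgs[[1L]]
  else mq_zstack(imgs, z_step_um = config$z_step_um %||% z_step_um)
}

#' Write an image (or stack) as TIFF
#'
#' Integer-origin images are written at the requested bit depth and round-
#' trip bit-exactly through [read_image]; float images are stored as 32-bit
#' float. Masks can be written by converting to 0/255 via
#' [write_mask]. Writing is deterministic: identical pixels give
#' byte-identical files.
#'
#' @param img [mq_image], [mq_zstack], or numeric matrix.
#' @param path Output path.
#' @param bits 8, 16 (integer) or 32 (float). Default 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  mats <- if (inherits(img, "mq_zstack"))
    lapply(img$planes, .as_pixels)
  else list(.as_pixels(img))
  if (bits %in% c(8L, 16L)) {
    mx <- 2^bits - 1
    bad <- vapply(mats, function(m)
      any(m < 0 | m > mx | m != round(m)), logical(1))
    if (any(bad))
      stop_parameter(sprintf(
        "intensities must be integers in [0, %d] for %d-bit output", mx, bits))
    mats <- lapply(mats, function(m) m / mx)
    tiff::writeTIFF(if (length(mats) == 1L) mats[[1L]] else mats, path,
                    bits.per.sample = bits)
  } else if (bits == 32L) {
    suppressWarnings(
      tiff::writeTIFF(if (length(mats) == 1L) mats[[1L]] else mats, path,
                      bits.per.sample = 32L))
  } else stop_parameter("'bits' must be 8, 16 or 32")
  invisible(path)
}

#' Write a binary mask as an 8-bit 0/255 TIFF
#'
#' @param mask [mq_mask] or logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- .as_mask(mask)
  write_image(matrix(as.numeric(m) * 255, nrow(m), ncol(m)), path, bits = 8L)
}

#' Write a region table as CSV
#'
#' Fixed, documented column order: `label`, `area_um2`, `centroid_x_px`,
#' `centroid_y_px`, `major_axis_um`, `minor_axis_um`, `aspect_ratio`,
#' `mean_intensity`. An empty table writes the header only. Output is
#' deterministic.
#'
#' @param regions A [label_regions] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_csv <- function(regions, path) {
  cols <- c("label", "area_um2", "centroid_x_px", "centroid_y_px",
            "major_axis_um", "minor_axis_um", "aspect_ratio",
            "mean_intensity")
  df <- as.data.frame(regions)[, cols, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write result tables and masks with a manifest
#'
#' Writes each table as CSV and each mask as an 8-bit 0/255 TIFF into
#' `out_dir`, then a `manifest.json` listing every written file with its
#' MD5 checksum, the effective configuration, and the package version.
#' Re-running with identical inputs and configuration reproduces the CSVs
#' byte-identically.
#'
#' @param tables Named list of data frames.
#' @param masks Named list of [mq_mask] objects (optional).
#' @param out_dir Output directory (created if needed).
#' @param config Optional [analysis_config] recorded verbatim.
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_results <- function(tables, masks = list(), out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    if (inherits(tables[[nm]], "mq_regions")) write_regions_csv(tables[[nm]], f)
    else utils::write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(masks)) {
    f <- file.path(out_dir, paste0(nm, ".tif"))
    write_mask(masks[[nm]], f)
    files <- c(files, f)
  }
  manifest <- list(
    package = "mitoquant",
    version = as.character(utils::packageVersion("mitoquant")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config)) NULL else unclass(config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  mq_log("write_results: %d files -> %s", length(files), out_dir)
  invisible(manifest)
}
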