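#' mitoquant: mitochondrial redistribution and partitioning quantification
#'
#' Image primitives, figure-style quantifications, a stochastic cluster-
#' partitioning simulator and a synthetic scene generator for studying
#' mitochondrial distribution and inheritance in mitotic mouse zygotes.
#'
#' @keywords internal
"_PACKAGE"

## Structured conditions -----------------------------------------------------

mq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mq_error"), call = call))
}

stop_parameter <- function(msg) mq_stop(msg, "mq_parameter_error")
stop_degenerate <- function(msg) mq_stop(msg, "mq_degenerate_error")
stop_input <- function(msg) mq_stop(msg, "mq_input_error")

.channel_roles <- c("mito", "chromatin", "spindle", "er", "golgi",
                    "peroxisome", "ros", "actin", "other")

## Image ---------------------------------------------------------------------

#' Fluorescence image with physical pixel size
#'
#' A single-channel 2D image: a numeric matrix of non-negative intensities
#' plus the physical edge length of a pixel in micrometres and the biological
#' role of the channel. All quantifications in the package operate on this
#' container so that areas and distances can always be reported in physical
#' units; there is no silent default pixel size.
#'
#' @param pixels Numeric matrix (rows = y, columns = x) of finite,
#'   non-negative intensities; at least 2x2.
#' @param pixel_size_um Micrometres per pixel edge, > 0.
#' @param channel_role One of `"mito"`, `"chromatin"`, `"spindle"`, `"er"`,
#'   `"golgi"`, `"peroxisome"`, `"ros"`, `"actin"`, `"other"`.
#' @param bit_origin Bit depth the data originated from: `"u8"`, `"u16"` or
#'   `"float"`. Informational; intensities are held as doubles.
#'
#' @return An object of class `mq_image`.
#' @examples
#' img <- mq_image(matrix(runif(64), 8, 8), pixel_size_um = 0.25)
#' img
#' @export
mq_image <- function(pixels, pixel_size_um, channel_role = "other",
                     bit_origin = "float") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_parameter("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop_parameter("image must be at least 2x2 pixels")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_parameter("all intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop_parameter("'pixel_size_um' must be a single positive number")
  channel_role <- match.arg(channel_role, .channel_roles)
  bit_origin <- match.arg(bit_origin, c("u8", "u16", "float"))
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_role = channel_role, bit_origin = bit_origin),
    class = "mq_image")
}

#' @export
print.mq_image <- function(x, ...) {
  cat(sprintf("<mq_image> %d x %d px, %.4g um/px, channel '%s' (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$channel_role, x$bit_origin))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mq_image <- function(x) dim(x$pixels)

.as_pixels <- function(img) {
  if (inherits(img, "mq_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop_parameter("expected an 'mq_image' or a numeric matrix")
}

.img_like <- function(img, pixels) {
  if (inherits(img, "mq_image")) {
    img$pixels <- pixels
    img
  } else pixels
}

## ZStack --------------------------------------------------------------------

#' Z-stack of equally shaped image planes
#'
#' @param planes List of [mq_image] objects sharing shape and pixel size.
#' @param z_step_um Micrometres between consecutive planes, > 0.
#' @return An object of class `mq_zstack`.
#' @export
mq_zstack <- function(planes, z_step_um) {
  if (!is.list(planes) || length(planes) < 1L)
    stop_parameter("'planes' must be a non-empty list of mq_image objects")
  if (!all(vapply(planes, inherits, logical(1), "mq_image")))
    stop_parameter("all planes must be mq_image objects")
  d1 <- dim(planes[[1L]]$pixels)
  ok <- vapply(planes, function(p) identical(dim(p$pixels), d1), logical(1))
  if (!all(ok)) stop_parameter("all planes must share the same shape")
  ps <- vapply(planes, function(p) p$pixel_size_um, numeric(1))
  if (length(unique(ps)) != 1L)
    stop_parameter("all planes must share the same pixel size")
  if (!is.numeric(z_step_um) || length(z_step_um) != 1L || z_step_um <= 0)
    stop_parameter("'z_step_um' must be a single positive number")
  structure(list(planes = planes, z_step_um = z_step_um), class = "mq_zstack")
}

#' @export
print.mq_zstack <- function(x, ...) {
  cat(sprintf("<mq_zstack> %d planes of %d x %d px, z step %.4g um\n",
              length(x$planes), nrow(x$planes[[1]]$pixels),
              ncol(x$planes[[1]]$pixels), x$z_step_um))
  invisible(x)
}

## BinaryMask ----------------------------------------------------------------

#' Binary segmentation mask with threshold provenance
#'
#' @param pixels Logical matrix, foreground = `TRUE`.
#' @param threshold_used Numeric threshold that produced the mask, or the
#'   string `"manual"`.
#' @param method `"yen"`, `"moments"` or `"manual"`.
#' @return An object of class `mq_mask`.
#' @export
binary_mask <- function(pixels, threshold_used = "manual",
                        method = c("manual", "yen", "moments")) {
  if (is.numeric(pixels)) {
    storage <- matrix(pixels != 0, nrow(pixels), ncol(pixels))
    pixels <- storage
  }
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop_parameter("'pixels' must be a logical matrix")
  method <- match.arg(method)
  structure(list(pixels = pixels, threshold_used = threshold_used,
                 method = method),
            class = "mq_mask")
}

#' @export
print.mq_mask <- function(x, ...) {
  cat(sprintf("<mq_mask> %d x %d px, %d foreground (%.1f%%), method '%s'\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), x$method))
  if (is.numeric(x$threshold_used))
    cat(sprintf("  threshold %.6g\n", x$threshold_used))
  invisible(x)
}

.as_mask <- function(m) {
  if (inherits(m, "mq_mask")) m$pixels
  else if (is.matrix(m) && is.logical(m)) m
  else if (is.matrix(m) && is.numeric(m)) m != 0
  else stop_parameter("expected an 'mq_mask' or a logical matrix")
}
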