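## The named statistics of the pipeline, composed from the image primitives.

#' Perinuclear / perispindle accumulation ratio
#'
#' Quantifies accumulation of a fluorescence channel (typically mitochondria)
#' around an organizer (nucleus or spindle). The organizer mask is dilated by
#' `ring_width_px`; the ring is the dilated mask minus the organizer itself,
#' and the comparison region is the rest of the cell outside the dilated
#' mask. The ratio of the mean per-pixel intensity in the ring to the mean
#' outside is returned, so the statistic does not depend on region sizes.
#'
#' @param mito An [mq_image] (the channel whose accumulation is measured).
#' @param organizer_mask [mq_mask] of the nucleus or spindle (typically from
#'   thresholding the chromatin/spindle channel after Gaussian smoothing,
#'   radius 2 px).
#' @param cell_mask [mq_mask] of the whole cell/embryo.
#' @param ring_width_px Dilation width in pixels (default 10).
#' @return List of class `mq_ring_ratio` with `mean_inner`, `mean_outer`,
#'   `ratio`.
#' @export
accumulation_ratio <- function(mito, organizer_mask, cell_mask,
                               ring_width_px = 10L) {
  m <- .as_pixels(mito)
  org <- .as_mask(organizer_mask)
  cell <- .as_mask(cell_mask)
  if (!identical(dim(m), dim(org)) || !identical(dim(m), dim(cell)))
    stop_parameter("image and masks must share the same shape")
  dil <- .as_mask(dilate_mask(org, ring_width_px))
  ring <- dil & !org
  outside <- cell & !dil
  if (!any(ring) || !any(outside))
    stop_degenerate("empty ring or outside region")
  mean_inner <- mean(m[ring])
  mean_outer <- mean(m[outside])
  if (mean_outer <= 0)
    stop_degenerate("zero mean intensity outside the ring")
  mq_log("accumulation_ratio: ring %d px, outside %d px",
         sum(ring), sum(outside))
  structure(list(mean_inner = mean_inner, mean_outer = mean_outer,
                 ratio = mean_inner / mean_outer),
            class = "mq_ring_ratio")
}

#' @export
print.mq_ring_ratio <- function(x, ...) {
  cat(sprintf("<accumulation ratio> inner %.4g / outer %.4g = %.4g\n",
              x$mean_inner, x$mean_outer, x$ratio))
  invisible(x)
}

#' Symmetry index and inheritance ratio of a partitioned quantity
#'
#' Both conventions for comparing a conserved quantity between two daughter
#' blastomeres: the symmetry index (greater/smaller, >= 1, 1 = perfect
#' symmetry) and the inheritance ratio (smaller/greater, in (0, 1]). The
#' result is invariant to argument order, and the two conventions are exact
#' reciprocals. A single zero total yields symmetry index `Inf` and
#' inheritance ratio 0 with a warning (fully asymmetric partition).
#'
#' @param total_a,total_b Totals (fluorescence, mtDNA copies, ...) in the two
#'   daughters; non-negative, not both zero.
#' @return List of class `mq_partition_measures` with `total_a`, `total_b`,
#'   `symmetry_index`, `inheritance_ratio`.
#' @examples
#' partition_measures(60, 40)   # symmetry 1.5, inheritance 2/3
#' @export
partition_measures <- function(total_a, total_b) {
  if (!is.numeric(total_a) || !is.numeric(total_b) ||
      length(total_a) != 1L || length(total_b) != 1L ||
      !is.finite(total_a) || !is.finite(total_b))
    stop_input("totals must be single finite numbers")
  if (total_a < 0 || total_b < 0)
    stop_input("totals must be non-negative")
  if (total_a == 0 && total_b == 0)
    stop_input("both totals are zero; ratios undefined")
  g <- max(total_a, total_b); s <- min(total_a, total_b)
  if (s == 0) {
    warning("one total is zero: fully asymmetric partition",
            call. = FALSE)
    si <- Inf; ir <- 0
  } else {
    si <- g / s; ir <- s / g
  }
  structure(list(total_a = total_a, total_b = total_b,
                 symmetry_index = si, inheritance_ratio = ir),
            class = "mq_partition_measures")
}

#' @export
print.mq_partition_measures <- function(x, ...) {
  cat(sprintf(
    "<partition> totals %.4g | %.4g; symmetry index %.4g, inheritance ratio %.4g\n",
    x$total_a, x$total_b, x$symmetry_index, x$inheritance_ratio))
  invisible(x)
}

#' Split channel totals across a cleavage plane
#'
#' Assigns every in-cell pixel to one side of a line (the manually outlined
#' cleavage plane) and sums the channel intensity per side. Pixels exactly on
#' the line are assigned to the positive side (the side toward which the
#' line's left normal points).
#'
#' @param img An [mq_image] or numeric matrix.
#' @param cell_mask [mq_mask] of the cell/embryo.
#' @param plane Two distinct (x, y) pixel points defining the line, as a
#'   2x2 matrix (rows = points, columns = x, y); 0-based coordinates.
#' @return Named numeric vector `c(total_a, total_b)`; side A is the
#'   positive side.
#' @export
split_totals_by_plane <- function(img, cell_mask, plane) {
  m <- .as_pixels(img)
  cell <- .as_mask(cell_mask)
  plane <- as.matrix(plane)
  if (!all(dim(plane) == c(2L, 2L)) || all(plane[1L, ] == plane[2L, ]))
    stop_parameter("'plane' must be two distinct (x, y) points")
  d <- plane[2L, ] - plane[1L, ]
  nrm <- c(-d[2L], d[1L])                 # left normal
  idx <- which(cell)
  if (length(idx) == 0L) stop_degenerate("empty cell mask")
  yy <- (idx - 1L) %% nrow(m)
  xx <- (idx - 1L) %/% nrow(m)
  s <- (xx - plane[1L, 1L]) * nrm[1L] + (yy - plane[1L, 2L]) * nrm[2L]
  # the line must pass through the cell's bounding box
  bx <- range(xx); by <- range(yy)
  corner_s <- outer(bx - plane[1L, 1L], rep(1, 2)) * nrm[1L] +
    outer(rep(1, 2), by - plane[1L, 2L]) * nrm[2L]
  if (all(corner_s > 0) || all(corner_s < 0))
    stop_parameter("plane line does not intersect the cell bounding box")
  v <- m[idx]
  c(total_a = sum(v[s >= 0]), total_b = sum(v[s < 0]))
}

#' Mitochondrial cluster statistics
#'
#' Threshold the mitochondrial channel with the Yen criterion, label
#' 8-connected particles, and keep those larger than `min_area_um2` (default
#' 0.15 um^2, the cutoff below which signals are not counted as
#' mitochondrial clusters). Returns the per-cluster region table plus the
#' count and mean area.
#'
#' @param mito An [mq_image] of the mitochondrial channel.
#' @param pixel_size_um Micrometres per pixel; defaults to the image's.
#' @param min_area_um2 Minimum cluster area in um^2 (strictly larger-than).
#' @return List of class `mq_cluster_stats` with `regions` ([label_regions]
#'   table), `n_clusters` and `mean_area_um2`.
#' @export
cluster_stats <- function(mito, pixel_size_um = NULL, min_area_um2 = 0.15) {
  if (is.null(pixel_size_um)) {
    if (!inherits(mito, "mq_image"))
      stop_parameter("'pixel_size_um' is required when 'mito' is a bare matrix")
    pixel_size_um <- mito$pixel_size_um
  }
  mask <- threshold_yen(mito)
  regions <- label_regions(mask, pixel_size_um, min_area_um2,
                           intensity_image = mito)
  structure(list(regions = regions,
                 n_clusters = nrow(regions),
                 mean_area_um2 = if (nrow(regions)) mean(regions$area_um2)
                 else NA_real_,
                 threshold = mask$threshold_used),
            class = "mq_cluster_stats")
}

#' @export
print.mq_cluster_stats <- function(x, ...) {
  cat(sprintf("<cluster stats> %d clusters, mean area %.4g um^2 (Yen threshold %.4g)\n",
              x$n_clusters, x$mean_area_um2, x$threshold))
  invisible(x)
}

## sector index (1..n_sectors) of angles relative to an axis
.sector_index <- function(theta, axis, n_sectors = 6L) {
  rel <- (theta - axis) %% (2 * pi)
  pmin(floor(rel / (2 * pi / n_sectors)) + 1L, n_sectors)
}

#' Angular non-uniformity of a channel around the spindle axis
#'
#' Converts pixel coordinates to polar coordinates about the spindle-mask
#' centroid, bins cytoplasmic pixels into six 60-degree sectors anchored at
#' the spindle long axis (sector boundaries start at the axis and proceed
#' counterclockwise), and returns the per-sector mean intensities and their
#' standard deviation. Higher standard deviation indicates a less uniform
#' angular distribution. The channel is Gaussian-smoothed (radius 2 px)
#' first. Because the long axis has a 180-degree ambiguity the sector means
#' are meaningful as an unordered set; the order-free standard deviation is
#' the primary statistic.
#'
#' @param mito An [mq_image] of the channel to profile.
#' @param spindle_mask [mq_mask] of the spindle (>= 3 px). An isotropic mask
#'   has no defined long axis; the angle falls back to 0 rad and the result
#'   is flagged `degenerate_axis = TRUE` with a warning.
#' @param cell_mask Optional [mq_mask] restricting the profiled pixels;
#'   default: the whole frame. Spindle pixels are always excluded.
#' @param smooth_radius_px Gaussian radius for pre-smoothing (default 2).
#' @param n_sectors Number of equal angular sectors (default 6).
#' @return List of class `mq_angular_profile` with `axis_angle_rad`,
#'   `sector_means`, `nonuniformity_sd`, `degenerate_axis`.
#' @export
angular_uniformity <- function(mito, spindle_mask, cell_mask = NULL,
                               smooth_radius_px = 2, n_sectors = 6L) {
  m <- .as_pixels(gaussian_smooth(mito, smooth_radius_px))
  sp <- .as_mask(spindle_mask)
  if (sum(sp) < 3L) stop_parameter("spindle mask needs at least 3 pixels")
  idx <- which(sp)
  yy <- (idx - 1L) %% nrow(sp); xx <- (idx - 1L) %/% nrow(sp)
  em <- .ellipse_moments(cbind(xx, yy))
  degenerate <- isTRUE(all.equal(em$lambda1, em$lambda2)) || em$lambda1 == 0
  axis <- if (degenerate) 0 else em$theta
  if (degenerate)
    warning("isotropic spindle mask: axis angle tie broken toward 0 rad",
            call. = FALSE)
  keep <- if (is.null(cell_mask)) !sp else .as_mask(cell_mask) & !sp
  kidx <- which(keep)
  ky <- (kidx - 1L) %% nrow(sp); kx <- (kidx - 1L) %/% nrow(sp)
  theta <- atan2(ky - em$centroid[2L], kx - em$centroid[1L])
  sec <- .sector_index(theta, axis, n_sectors)
  vals <- m[kidx]
  sector_means <- vapply(seq_len(n_sectors),
                         function(s) mean(vals[sec == s]), numeric(1))
  structure(list(axis_angle_rad = axis,
                 sector_means = sector_means,
                 nonuniformity_sd = stats::sd(sector_means),
                 degenerate_axis = degenerate),
            class = "mq_angular_profile")
}

#' @export
print.mq_angular_profile <- function(x, ...) {
  cat(sprintf("<angular profile> axis %.3f rad, sector sd %.4g\n",
              x$axis_angle_rad, x$nonuniformity_sd))
  cat("  sector means:", sprintf("%.4g", x$sector_means), "\n")
  invisible(x)
}

#' Whole-embryo mask from the mitochondrial channel
#'
#' Moments-thresholds the Gaussian-smoothed mitochondrial channel and fills
#' the convex hull of the foreground, giving the embryo outline used when no
#' user-supplied ROI is available.
#'
#' @param mito An [mq_image] of the mitochondrial channel.
#' @param smooth_radius_px Gaussian radius before thresholding (default 2).
#' @return An [mq_mask].
#' @export
embryo_mask <- function(mito, smooth_radius_px = 2) {
  .embryo_mask_from_mito(gaussian_smooth(mito, smooth_radius_px))
}

## Moments threshold of the smoothed mito channel, then the filled convex
## hull of the foreground
.embryo_mask_from_mito <- function(mito_smoothed) {
  m <- .as_pixels(mito_smoothed)
  fg <- .as_mask(threshold_moments(m))
  idx <- which(fg)
  yy <- (idx - 1L) %% nrow(m); xx <- (idx - 1L) %/% nrow(m)
  h <- grDevices::chull(xx, yy)
  hx <- xx[h]; hy <- yy[h]
  gx <- rep(0:(ncol(m) - 1L), each = nrow(m))
  gy <- rep(0:(nrow(m) - 1L), times = ncol(m))
  inside <- pracma::inpolygon(gx, gy, hx, hy, boundary = TRUE)
  binary_mask(matrix(inside, nrow(m), ncol(m)))
}

#' ROS enrichment inside mitochondria
#'
#' The mitochondrial channel is background-subtracted (rolling ball, radius
#' 5 px), Gaussian-smoothed (radius 2 px) and thresholded with the Moments
#' criterion to give the inside-mitochondria mask; the outside region is the
#' whole-embryo area minus that mask. The whole-embryo mask, when not
#' supplied, is the filled convex hull of the Moments-thresholded smoothed
#' mitochondrial channel. Returns the ratio of mean ROS-channel intensity
#' inside mitochondria to outside.
#'
#' @param ros [mq_image] of the ROS indicator channel (e.g. H2DCFDA).
#' @param mito [mq_image] of the mitochondrial channel, co-registered.
#' @param cell_mask Optional whole-embryo [mq_mask] overriding the derived
#'   hull.
#' @param ball_radius_px,smooth_radius_px Preprocessing radii (defaults 5, 2).
#' @return List of class `mq_ros_enrichment` with `ratio`, `mean_inside`,
#'   `mean_outside`, `inside_mask`.
#' @export
ros_enrichment <- function(ros, mito, cell_mask = NULL,
                           ball_radius_px = 5, smooth_radius_px = 2) {
  r <- .as_pixels(ros)
  m <- .as_pixels(mito)
  if (!identical(dim(r), dim(m)))
    stop_parameter("channels must be co-registered (same shape)")
  proc <- gaussian_smooth(rolling_ball_subtract(m, ball_radius_px),
                          smooth_radius_px)
  inside <- .as_mask(threshold_moments(proc))
  embryo <- if (is.null(cell_mask)) {
    sm <- gaussian_smooth(m, smooth_radius_px)
    .as_mask(.embryo_mask_from_mito(sm))
  } else .as_mask(cell_mask)
  outside <- embryo & !inside
  if (!any(inside) || !any(outside))
    stop_degenerate("empty inside or outside region")
  mi <- mean(r[inside]); mo <- mean(r[outside])
  if (mo <= 0) stop_degenerate("zero mean ROS intensity outside mitochondria")
  mq_log("ros_enrichment: inside %d px, outside %d px", sum(inside),
         sum(outside))
  structure(list(ratio = mi / mo, mean_inside = mi, mean_outside = mo,
                 inside_mask = binary_mask(inside)),
            class = "mq_ros_enrichment")
}

#' @export
print.mq_ros_enrichment <- function(x, ...) {
  cat(sprintf("<ROS enrichment> inside %.4g / outside %.4g = %.4g\n",
              x$mean_inside, x$mean_outside, x$ratio))
  invisible(x)
}

#' Pixel-wise Pearson correlation of two channels within a mask
#'
#' @param ch_a,ch_b Co-registered [mq_image]s or matrices.
#' @param mask [mq_mask] with at least 10 pixels; both channels must be
#'   non-constant within it.
#' @return Pearson correlation coefficient.
#' @export
pixel_correlation <- function(ch_a, ch_b, mask) {
  a <- .as_pixels(ch_a); b <- .as_pixels(ch_b)
  w <- .as_mask(mask)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(w)))
    stop_parameter("channels and mask must share the same shape")
  if (sum(w) < 10L) stop_parameter("mask must contain at least 10 pixels")
  va <- a[w]; vb <- b[w]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop_degenerate("a channel is constant within the mask")
  stats::cor(va, vb)
}

#' Chromosome-track displacement projection
#'
#' Projects a centroid track onto the unit vector pointing from its initial
#' to its final position (so only motion along the net displacement
#' direction is counted), and reports the final distance to the cell center
#' in micrometres.
#'
#' @param track A data frame with columns `t`, `x`, `y` (pixel coordinates),
#'   ordered or orderable by `t`, with at least 2 points and distinct
#'   initial/final positions.
#' @param center_xy Cell center (x, y) in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @return List of class `mq_track_projection` with `times`, `positions_xy`,
#'   `direction_unit`, `projected_displacements` (signed, px) and
#'   `final_distance_to_center_um`.
#' @export
track_projection <- function(track, center_xy, pixel_size_um) {
  track <- as.data.frame(track)
  if (!all(c("t", "x", "y") %in% names(track)))
    stop_input("track must have columns t, x, y")
  if (nrow(track) < 2L) stop_input("track needs at least 2 points")
  track <- track[order(track$t), , drop = FALSE]
  p0 <- c(track$x[1L], track$y[1L])
  p1 <- c(track$x[nrow(track)], track$y[nrow(track)])
  d <- p1 - p0
  nd <- sqrt(sum(d^2))
  if (nd == 0)
    stop_degenerate("initial and final positions coincide: direction undefined")
  u <- d / nd
  proj <- (track$x - p0[1L]) * u[1L] + (track$y - p0[2L]) * u[2L]
  fd <- sqrt(sum((p1 - center_xy)^2)) * pixel_size_um
  structure(list(times = track$t,
                 positions_xy = cbind(x = track$x, y = track$y),
                 direction_unit = u,
                 projected_displacements = proj,
                 final_distance_to_center_um = fd),
            class = "mq_track_projection")
}

#' @export
print.mq_track_projection <- function(x, ...) {
  cat(sprintf(
    "<track projection> %d points, net displacement %.4g px, final distance to center %.4g um\n",
    length(x$times), x$projected_displacements[length(x$times)],
    x$final_distance_to_center_um))
  invisible(x)
}
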