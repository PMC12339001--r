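## Self-implemented image primitives the quantifications are composed from.
## All operate on plain numeric/logical matrices internally (rows = y,
## columns = x); coordinates reported to users are 0-based with x = column.

## -- separable convolution with edge replication ----------------------------

.replicate_pad_rows <- function(m, h) {
  nr <- nrow(m)
  m[c(rep.int(1L, h), seq_len(nr), rep.int(nr, h)), , drop = FALSE]
}

.conv_rows <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  p <- .replicate_pad_rows(m, h)
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * p[i:(i + nr - 1L), , drop = FALSE]
  out
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with edge-replication boundary handling.
#' The `radius_px` parameter is mapped to the kernel standard deviation in
#' pixels (radius 2 means sigma = 2), matching the parameter semantics of the
#' interactive analysis software this pipeline mirrors; the kernel is
#' truncated at 3 sigma and renormalised so a constant image is exactly
#' preserved.
#'
#' @param img An [mq_image] or numeric matrix.
#' @param radius_px Kernel standard deviation in pixels, > 0.
#' @return Smoothed image of the same class, shape and pixel size.
#' @examples
#' img <- mq_image(matrix(runif(256), 16, 16), 0.25)
#' sm <- gaussian_smooth(img, 2)
#' @export
gaussian_smooth <- function(img, radius_px) {
  if (!is.numeric(radius_px) || length(radius_px) != 1L ||
      !is.finite(radius_px) || radius_px <= 0)
    stop_parameter("'radius_px' must be a single positive number")
  m <- .as_pixels(img)
  h <- max(1L, as.integer(ceiling(3 * radius_px)))
  k <- stats::dnorm(seq.int(-h, h), sd = radius_px)
  k <- k / sum(k)
  out <- .conv_rows(m, k)
  out <- t(.conv_rows(t(out), k))
  out[out < 0] <- 0
  .img_like(img, out)
}

## -- grayscale/binary morphology with disk elements -------------------------

.disk_offsets <- function(r) {
  ri <- as.integer(floor(r))
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  g
}

## min/max over disk-shifted copies; pad value chosen so out-of-image
## neighbours never win
.morph_gray <- function(m, off, fun, pad_val) {
  nr <- nrow(m); nc <- ncol(m)
  r <- max(abs(off$dy), abs(off$dx))
  p <- matrix(pad_val, nr + 2L * r, nc + 2L * r)
  p[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  out <- matrix(pad_val, nr, nc)
  rows <- (r + 1L):(r + nr); cols <- (r + 1L):(r + nc)
  for (i in seq_len(nrow(off)))
    out <- fun(out, p[rows + off$dy[i], cols + off$dx[i], drop = FALSE])
  out
}

.gray_erode <- function(m, off) .morph_gray(m, off, pmin, Inf)
.gray_dilate <- function(m, off) .morph_gray(m, off, pmax, -Inf)

#' Rolling-ball background subtraction
#'
#' Removes slowly varying background by subtracting the grayscale opening of
#' the image (erosion then dilation by a disk structuring element of the
#' given radius, the standard "distance <= r" discretization). Features
#' smaller than the element survive intact; the background never exceeds the
#' image, and the result is clipped at zero.
#'
#' @param img An [mq_image] or numeric matrix.
#' @param radius_px Ball/disk radius in pixels, >= 1 and smaller than the
#'   image extent.
#' @return Background-subtracted image of the same class and shape.
#' @export
rolling_ball_subtract <- function(img, radius_px) {
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px < 1)
    stop_parameter("'radius_px' must be a single number >= 1")
  m <- .as_pixels(img)
  if (2 * radius_px + 1 > min(dim(m)))
    stop_parameter("'radius_px' exceeds the image extent")
  off <- .disk_offsets(radius_px)
  bg <- .gray_dilate(.gray_erode(m, off), off)
  out <- m - bg
  out[out < 0] <- 0
  .img_like(img, out)
}

#' Morphological dilation of a binary mask by a disk
#'
#' @param mask An [mq_mask] or logical matrix.
#' @param width_px Disk radius in pixels, integer >= 1. A pixel is foreground
#'   in the output if any input foreground pixel lies within Euclidean
#'   distance `width_px`.
#' @return An [mq_mask] containing the input (dilation is extensive).
#' @export
dilate_mask <- function(mask, width_px) {
  if (!is.numeric(width_px) || length(width_px) != 1L ||
      width_px < 1 || width_px != floor(width_px))
    stop_parameter("'width_px' must be a positive integer")
  m <- .as_mask(mask)
  off <- .disk_offsets(width_px)
  out <- .morph_gray(m * 1, off, pmax, 0) > 0
  if (inherits(mask, "mq_mask"))
    binary_mask(out, mask$threshold_used, mask$method)
  else binary_mask(out)
}

## -- histogram thresholding -------------------------------------------------

## 256 equal-width bins spanning [min, max]; returns counts plus the upper
## edge of each bin (the candidate threshold levels)
.hist256 <- function(v) {
  lo <- min(v); hi <- max(v)
  if (!(hi > lo))
    stop_degenerate("constant image: intensity thresholding is undefined")
  bin <- pmin(floor((v - lo) / (hi - lo) * 256) + 1L, 256L)
  counts <- tabulate(bin, nbins = 256L)
  upper <- lo + (hi - lo) * seq_len(256L) / 256
  list(counts = counts, upper = upper, lo = lo, hi = hi)
}

## Yen's maximum-correlation criterion per candidate level t (background =
## bins 1..t). Returns the criterion vector; NA where a class is empty.
.yen_criterion <- function(counts) {
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- rep(-Inf, 256L)
  for (t in 1:255) {
    a <- P1sq[t] * P2sq[t]
    b <- P1[t] * (1 - P1[t])
    crit[t] <- (if (a > 0) -log(a) else 0) + (if (b > 0) 2 * log(b) else 0)
  }
  crit
}

## Tsai moment-preserving fraction: fraction of pixels that should fall at or
## below the threshold so that the binary image preserves the first three
## gray-level moments of the input histogram.
.moments_pd <- function(counts, upper) {
  p <- counts / sum(counts)
  z <- upper                       # representative level per bin
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) return(NA_real_)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(NA_real_)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (z1 == z0) return(NA_real_)
  pd <- (z1 - m1) / (z1 - z0)
  min(max(pd, 0), 1)
}

.threshold_mask <- function(img, level, method) {
  m <- .as_pixels(img)
  fg <- m > level
  if (!any(fg))
    stop_degenerate(sprintf("%s threshold %.6g selects no foreground",
                            method, level))
  mq_log("threshold_%s: level %.6g, %d foreground px (%.2f%%)",
         method, level, sum(fg), 100 * mean(fg))
  binary_mask(fg, threshold_used = level, method = method)
}

#' Yen automatic threshold
#'
#' Selects the level maximizing Yen's maximum-correlation criterion over all
#' candidate levels of a 256-bin histogram spanning the intensity range
#' (ties broken toward the lowest qualifying level). Foreground is strictly
#' greater than the threshold.
#'
#' @param img An [mq_image] or numeric matrix with at least two distinct
#'   intensity values.
#' @return An [mq_mask] with the chosen threshold recorded.
#' @export
threshold_yen <- function(img) {
  h <- .hist256(.as_pixels(img))
  crit <- .yen_criterion(h$counts)
  t <- which.max(crit)             # which.max returns the first maximum
  .threshold_mask(img, h$upper[t], "yen")
}

#' Moment-preserving (Tsai) automatic threshold
#'
#' Chooses the level whose cumulative histogram fraction is closest to the
#' moment-preserving fraction, i.e. the binarization preserving the first
#' three gray-level moments of the input histogram (ties broken toward the
#' lowest level). Foreground is strictly greater than the threshold.
#'
#' @inheritParams threshold_yen
#' @return An [mq_mask] with the chosen threshold recorded.
#' @export
threshold_moments <- function(img) {
  h <- .hist256(.as_pixels(img))
  pd <- .moments_pd(h$counts, h$upper)
  if (is.na(pd))
    stop_degenerate("histogram too degenerate for moment-preserving threshold")
  q <- cumsum(h$counts) / sum(h$counts)
  t <- which.min(abs(q[1:255] - pd))
  .threshold_mask(img, h$upper[t], "moments")
}

## -- connected components and region measures -------------------------------

## 8-connected labeling by iterated neighbourhood-minimum with pointer
## jumping (labels are linear pixel indices until final relabeling)
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- nr * nc
  lab <- rep(Inf, n)
  fg <- which(mask)
  if (length(fg) == 0L)
    return(matrix(0L, nr, nc))
  lab[fg] <- fg
  rows <- 2:(nr + 1L); cols <- 2:(nc + 1L)
  off <- expand.grid(dy = -1:1, dx = -1:1)
  off <- off[!(off$dy == 0 & off$dx == 0), ]
  repeat {
    M <- matrix(lab, nr, nc)
    P <- matrix(Inf, nr + 2L, nc + 2L)
    P[rows, cols] <- M
    nb <- M
    for (i in seq_len(nrow(off)))
      nb <- pmin(nb, P[rows + off$dy[i], cols + off$dx[i]])
    v <- as.vector(nb)
    v[-fg] <- Inf
    # path compression: follow label pointers to their current root
    repeat {
      v2 <- v
      v2[fg] <- v[v[fg]]
      if (identical(v2, v)) break
      v <- v2
    }
    if (identical(v, lab)) break
    lab <- v
  }
  out <- integer(n)
  out[fg] <- match(lab[fg], sort(unique(lab[fg])))
  matrix(out, nr, nc)
}

## equal-second-moment ellipse of a pixel set; coords are (x, y) in px
.ellipse_moments <- function(xy) {
  n <- nrow(xy)
  mu <- colMeans(xy)
  dx <- xy[, 1] - mu[1]; dy <- xy[, 2] - mu[2]
  mxx <- sum(dx * dx) / n
  myy <- sum(dy * dy) / n
  mxy <- sum(dx * dy) / n
  tr <- mxx + myy
  det <- mxx * myy - mxy * mxy
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  list(centroid = mu, lambda1 = l1, lambda2 = l2, theta = theta)
}

#' Equal-second-moment ellipse axes of a pixel region
#'
#' Returns the full major and minor axis lengths of the ellipse whose second
#' central moments equal those of the pixel set (the convention of the usual
#' particle-analysis "fit ellipse": axis = 4 * sqrt(eigenvalue of the
#' coordinate covariance)).
#'
#' @param region_pixels Two-column matrix of pixel coordinates (x, y), at
#'   least 3 pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @return Named list with `major_axis_um`, `minor_axis_um`, `aspect_ratio`
#'   (major/minor, `Inf` for collinear regions) and `theta_rad` (major-axis
#'   orientation, measured from the +x axis toward +y).
#' @export
region_ellipse_axes <- function(region_pixels, pixel_size_um) {
  xy <- as.matrix(region_pixels)
  if (nrow(xy) < 3L)
    stop_parameter("a region needs at least 3 pixels for ellipse moments")
  em <- .ellipse_moments(xy)
  major <- 4 * sqrt(em$lambda1) * pixel_size_um
  minor <- 4 * sqrt(em$lambda2) * pixel_size_um
  list(major_axis_um = major, minor_axis_um = minor,
       aspect_ratio = if (minor > 0) major / minor else Inf,
       theta_rad = em$theta)
}

#' Label and measure particles in a binary mask
#'
#' Connected components under 8-connectivity, with an area filter: only
#' components whose area strictly exceeds `min_area_um2` are kept
#' ("larger than" the cutoff). Area is pixel count times the squared pixel
#' size; axes come from the equal-second-moment ellipse. Centroids are
#' 0-based pixel coordinates with x = column, y = row.
#'
#' @param mask An [mq_mask] or logical matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_um2 Minimum area in square micrometres; components with
#'   `area_um2 <= min_area_um2` are excluded. Default 0 keeps everything.
#' @param intensity_image Optional [mq_image]/matrix from which per-region
#'   mean intensities are measured; `NA` otherwise.
#' @return A `data.frame` (class `mq_regions`) with columns `label`,
#'   `area_um2`, `centroid_x_px`, `centroid_y_px`, `major_axis_um`,
#'   `minor_axis_um`, `aspect_ratio`, `mean_intensity`; zero rows allowed.
#' @export
label_regions <- function(mask, pixel_size_um, min_area_um2 = 0,
                          intensity_image = NULL) {
  if (missing(pixel_size_um) && inherits(mask, "mq_mask"))
    stop_parameter("'pixel_size_um' is required to report areas in um^2")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_parameter("'pixel_size_um' must be a single positive number")
  m <- .as_mask(mask)
  lab <- .label8(m)
  k <- max(lab)
  ii <- if (is.null(intensity_image)) NULL else .as_pixels(intensity_image)
  rows <- vector("list", k)
  kept <- 0L
  for (j in seq_len(k)) {
    idx <- which(lab == j)
    npx <- length(idx)
    area <- npx * pixel_size_um^2
    if (area <= min_area_um2) next
    yy <- (idx - 1L) %% nrow(m)          # 0-based row
    xx <- (idx - 1L) %/% nrow(m)         # 0-based col
    xy <- cbind(x = xx, y = yy)
    if (npx >= 3L) {
      ax <- region_ellipse_axes(xy, pixel_size_um)
    } else {
      ax <- list(major_axis_um = NA_real_, minor_axis_um = NA_real_,
                 aspect_ratio = NA_real_)
    }
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      label = kept,
      area_um2 = area,
      centroid_x_px = mean(xx),
      centroid_y_px = mean(yy),
      major_axis_um = ax$major_axis_um,
      minor_axis_um = ax$minor_axis_um,
      aspect_ratio = ax$aspect_ratio,
      mean_intensity = if (is.null(ii)) NA_real_ else mean(ii[idx]))
  }
  out <- if (kept)
    do.call(rbind, rows[seq_len(kept)])
  else
    data.frame(label = integer(), area_um2 = numeric(),
               centroid_x_px = numeric(), centroid_y_px = numeric(),
               major_axis_um = numeric(), minor_axis_um = numeric(),
               aspect_ratio = numeric(), mean_intensity = numeric())
  class(out) <- c("mq_regions", "data.frame")
  mq_log("label_regions: %d components, %d kept above %.3g um^2",
         k, nrow(out), min_area_um2)
  out
}

#' Maximum-intensity projection of a Z-stack
#'
#' @param stack An [mq_zstack] or list of numeric matrices.
#' @return An [mq_image] holding the per-pixel maximum across planes.
#' @export
max_project <- function(stack) {
  planes <- if (inherits(stack, "mq_zstack")) stack$planes else stack
  if (length(planes) < 1L) stop_parameter("stack must have at least 1 plane")
  mats <- lapply(planes, .as_pixels)
  proj <- Reduce(pmax, mats)
  if (inherits(planes[[1L]], "mq_image"))
    mq_image(proj, planes[[1L]]$pixel_size_um,
             planes[[1L]]$channel_role, planes[[1L]]$bit_origin)
  else proj
}
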