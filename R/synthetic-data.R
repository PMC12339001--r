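## Synthetic two-channel zygote scenes with planted ground truth. The
## generator emulates the statistical structure the quantifications assume:
## diffraction-limited mitochondrial puncta (isotropic Gaussian spots,
## sigma = punctum_radius / 2) scattered in the cytoplasm of a disk-shaped
## embryo, optionally aggregated into clumps, enriched in a perinuclear
## shell, or concentrated in angle around the organizer long axis; an
## organizer (nucleus or spindle) ellipse in the second channel; and
## Poisson photon noise plus Gaussian read noise applied last.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

#' Synthetic scene parameters
#'
#' Ground-truth parameters for [generate_zygote_scene] and
#' [generate_two_cell_scene]. Defaults render a 512x512 px field at
#' 0.25 um/px holding an embryo of 40 um radius with 200 dispersed puncta of
#' 0.3 um^2 nominal area, no clumping, no perinuclear enrichment, no angular
#' concentration, and modest noise.
#'
#' @param image_size_px Canvas size (square), px.
#' @param pixel_size_um Micrometres per pixel.
#' @param embryo_radius_um Embryo disk radius, um.
#' @param organizer_center_um Organizer (nucleus/spindle) center relative to
#'   the embryo center, um; default `c(0, 0)`.
#' @param organizer_radii_um Semi-axes of the organizer ellipse (long,
#'   short), um.
#' @param organizer_angle_rad Orientation of the organizer long axis.
#' @param n_puncta Number of mitochondrial puncta.
#' @param punctum_radius_um Nominal punctum radius, um (nominal area
#'   `pi * r^2`); spots are rendered as Gaussians with sigma = r / 2.
#' @param punctum_peak Peak spot amplitude, a.u.
#' @param n_clumps Number of clumps (0 = fully dispersed).
#' @param clump_spread_um Gaussian spread of puncta about their clump
#'   center, um.
#' @param perinuclear_enrichment Relative punctum density in the shell
#'   around the organizer versus elsewhere in the cytoplasm, >= 1.
#' @param shell_width_um Width of the perinuclear shell, um.
#' @param angular_kappa Von Mises concentration of punctum polar angles
#'   about the organizer long axis, >= 0 (0 = isotropic).
#' @param min_separation_um Hard-core minimum distance between punctum
#'   centers in dispersed scenes, um; `NULL` (default) uses 2.5 times the
#'   punctum radius, so that distinct clusters stay resolvable after
#'   thresholding, as real fragmented mitochondria are. Set 0 for a pure
#'   inhomogeneous Poisson pattern (used when intensity densities, not
#'   counts, are the planted quantity). Ignored inside clumps, where
#'   aggregation is the point.
#' @param scene_rotation_rad Global rotation applied to the whole realized
#'   configuration (organizer and punctum positions) after sampling; with a
#'   fixed seed this rotates the identical scene, which is how rotation
#'   invariance of downstream statistics is verified.
#' @param partition_fraction Fraction of total mitochondrial mass on side A
#'   of the cleavage plane in two-cell scenes, in (0, 1).
#' @param noise `NULL` for noise-free rendering, or a list with `gain`
#'   (photons per intensity unit for Poisson noise), `read_sd` (Gaussian
#'   read-noise sd, a.u.), `offset` (background offset, a.u.), `gradient`
#'   (linear background slope across the field, a.u.).
#' @param seed Integer seed; all randomness flows from it through documented
#'   sub-seeds (positions, then per-channel noise), so channels are
#'   independently reproducible.
#' @return List of class `mq_scene_params`.
#' @export
scene_params <- function(image_size_px = 512L,
                         pixel_size_um = 0.25,
                         embryo_radius_um = 40,
                         organizer_center_um = c(0, 0),
                         organizer_radii_um = c(10, 10),
                         organizer_angle_rad = 0,
                         n_puncta = 200L,
                         punctum_radius_um = sqrt(0.3 / pi),
                         punctum_peak = 150,
                         n_clumps = 0L,
                         clump_spread_um = 2,
                         perinuclear_enrichment = 1,
                         shell_width_um = 5,
                         angular_kappa = 0,
                         min_separation_um = NULL,
                         scene_rotation_rad = 0,
                         partition_fraction = 0.5,
                         noise = list(gain = 20, read_sd = 2,
                                      offset = 5, gradient = 0),
                         seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_size_um = pixel_size_um,
            embryo_radius_um = embryo_radius_um,
            organizer_center_um = organizer_center_um,
            organizer_radii_um = organizer_radii_um,
            organizer_angle_rad = organizer_angle_rad,
            n_puncta = as.integer(n_puncta),
            punctum_radius_um = punctum_radius_um,
            punctum_peak = punctum_peak,
            n_clumps = as.integer(n_clumps),
            clump_spread_um = clump_spread_um,
            perinuclear_enrichment = perinuclear_enrichment,
            shell_width_um = shell_width_um,
            angular_kappa = angular_kappa,
            min_separation_um = if (is.null(min_separation_um))
              2.5 * punctum_radius_um else min_separation_um,
            scene_rotation_rad = scene_rotation_rad,
            partition_fraction = partition_fraction,
            noise = noise,
            seed = as.integer(seed))
  if (any(c(p$pixel_size_um, p$embryo_radius_um, p$punctum_radius_um,
            p$organizer_radii_um, p$clump_spread_um, p$shell_width_um) <= 0))
    stop_parameter("all lengths must be positive")
  if (p$image_size_px < 16L)
    stop_parameter("'image_size_px' must be at least 16")
  if (p$perinuclear_enrichment < 1)
    stop_parameter("'perinuclear_enrichment' must be >= 1")
  if (p$angular_kappa < 0)
    stop_parameter("'angular_kappa' must be >= 0")
  if (p$min_separation_um < 0)
    stop_parameter("'min_separation_um' must be >= 0")
  if (p$partition_fraction <= 0 || p$partition_fraction >= 1)
    stop_parameter("'partition_fraction' must be in (0, 1)")
  if (max(p$organizer_radii_um) >= p$embryo_radius_um)
    stop_parameter("organizer does not fit inside the embryo")
  if (2 * p$embryo_radius_um > p$image_size_px * p$pixel_size_um)
    stop_parameter("embryo does not fit inside the field of view")
  structure(p, class = "mq_scene_params")
}

## normalized ellipse radius of points (x, y) relative to an ellipse
.ellipse_rho <- function(x, y, cx, cy, a, b, phi) {
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  sqrt((u / a)^2 + (v / b)^2)
}

## sample n punctum centers (um, embryo-centered coordinates)
.sample_puncta <- function(p) {
  R <- p$embryo_radius_um
  oc <- p$organizer_center_um
  a <- p$organizer_radii_um[1L]; b <- p$organizer_radii_um[2L]
  phi <- p$organizer_angle_rad
  margin <- 2 * p$punctum_radius_um
  rho_shell <- 1 + p$shell_width_um / sqrt(a * b)
  f <- p$perinuclear_enrichment
  kap <- p$angular_kappa
  n <- p$n_puncta
  if (p$n_clumps > 0L) {
    # clump centers uniform in the cytoplasm, kept apart so clumps never
    # fuse; punctum offsets are Gaussian truncated at 1.5 spreads so each
    # clump segments as one solid aggregate
    trunc_r <- 1.5 * p$clump_spread_um
    centers <- matrix(NA_real_, p$n_clumps, 2L)
    got <- 0L
    tries <- 0L
    while (got < p$n_clumps) {
      tries <- tries + 1L
      if (tries > 1e5L)
        stop_parameter("cannot place clump centers: geometry too tight")
      r <- (R - trunc_r - margin) * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cand <- c(r * cos(th), r * sin(th))
      if (.ellipse_rho(cand[1], cand[2], oc[1], oc[2], a, b, phi) <
          1 + trunc_r / sqrt(a * b)) next
      if (got > 0L) {
        dmin <- min(sqrt(rowSums((centers[seq_len(got), , drop = FALSE] -
                                    matrix(cand, got, 2L, byrow = TRUE))^2)))
        if (dmin < 6 * p$clump_spread_um) next
      }
      got <- got + 1L
      centers[got, ] <- cand
    }
    clump_id <- rep_len(seq_len(p$n_clumps), n)
    xy <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      repeat {
        off <- stats::rnorm(2L, sd = p$clump_spread_um)
        if (sqrt(sum(off^2)) > trunc_r) next
        cand <- centers[clump_id[i], ] + off
        ok <- sqrt(sum(cand^2)) < R - margin &&
          .ellipse_rho(cand[1], cand[2], oc[1], oc[2], a, b, phi) > 1
        if (ok) break
      }
      xy[i, ] <- cand
    }
    return(list(xy = xy, clump_id = clump_id))
  }
  # dispersed: rejection sampling with perinuclear-shell and angular
  # weights, plus hard-core thinning at min_separation_um
  wmax <- f * exp(kap)
  dmin2 <- p$min_separation_um^2
  xy <- matrix(NA_real_, n, 2L)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop_parameter("cannot place puncta: density too high for the hard-core separation")
    m <- max(4L * (n - got), 64L)
    r <- (R - margin) * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
    rho <- .ellipse_rho(x, y, oc[1], oc[2], a, b, phi)
    ang <- atan2(y - oc[2], x - oc[1])
    w <- ifelse(rho > 1 & rho <= rho_shell, f, 1) * exp(kap * cos(ang - phi))
    keep <- which(rho > 1 & stats::runif(m) * wmax < w)
    for (j in keep) {
      if (got >= n) break
      cand <- c(x[j], y[j])
      if (dmin2 > 0 && got > 0L) {
        d2 <- (xy[seq_len(got), 1L] - cand[1L])^2 +
          (xy[seq_len(got), 2L] - cand[2L])^2
        if (min(d2) < dmin2) next
      }
      got <- got + 1L
      xy[got, ] <- cand
    }
  }
  list(xy = xy, clump_id = rep(NA_integer_, n))
}

## rotate realized punctum positions and organizer geometry by the scene
## rotation angle
.apply_scene_rotation <- function(p, xy) {
  rot <- p$scene_rotation_rad
  if (rot == 0) return(list(p = p, xy = xy))
  cr <- cos(rot); sr <- sin(rot)
  Rm <- matrix(c(cr, sr, -sr, cr), 2L, 2L)
  p$organizer_center_um <- as.numeric(Rm %*% p$organizer_center_um)
  p$organizer_angle_rad <- p$organizer_angle_rad + rot
  list(p = p, xy = xy %*% t(Rm))
}

## render Gaussian spots (um coordinates, embryo-centered) onto a canvas
.render_spots <- function(xy_um, amps, p) {
  np <- p$image_size_px
  ps <- p$pixel_size_um
  ctr <- (np - 1) / 2                       # embryo center, 0-based px
  img <- matrix(0, np, np)
  sig <- (p$punctum_radius_um / 2) / ps     # sigma in px
  w <- max(2L, as.integer(ceiling(4 * sig)))
  for (i in seq_len(nrow(xy_um))) {
    px <- xy_um[i, 1L] / ps + ctr
    py <- xy_um[i, 2L] / ps + ctr
    x0 <- max(0L, as.integer(floor(px)) - w)
    x1 <- min(np - 1L, as.integer(ceiling(px)) + w)
    y0 <- max(0L, as.integer(floor(py)) - w)
    y1 <- min(np - 1L, as.integer(ceiling(py)) + w)
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-((xs - px)^2) / (2 * sig^2))
    gy <- exp(-((ys - py)^2) / (2 * sig^2))
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
      amps[i] * outer(gy, gx)
  }
  img
}

## filled organizer ellipse channel
.render_organizer <- function(p, center_um = p$organizer_center_um,
                              amp = 200) {
  np <- p$image_size_px; ps <- p$pixel_size_um
  ctr <- (np - 1) / 2
  xs <- ((0:(np - 1)) - ctr) * ps
  gx <- matrix(xs, np, np, byrow = TRUE)
  gy <- matrix(xs, np, np)
  rho <- .ellipse_rho(gx, gy, center_um[1L], center_um[2L],
                      p$organizer_radii_um[1L], p$organizer_radii_um[2L],
                      p$organizer_angle_rad)
  out <- matrix(0, np, np)
  out[rho <= 1] <- amp
  out
}

.apply_noise <- function(m, noise, seed) {
  if (is.null(noise)) return(m)
  .with_seed(seed, {
    g <- noise$gain
    out <- if (!is.null(g) && g > 0)
      stats::rpois(length(m), lambda = g * m) / g
    else as.vector(m)
    if (!is.null(noise$read_sd) && noise$read_sd > 0)
      out <- out + stats::rnorm(length(m), sd = noise$read_sd)
    out <- matrix(out, nrow(m), ncol(m))
    if (!is.null(noise$offset)) out <- out + noise$offset
    if (!is.null(noise$gradient) && noise$gradient != 0) {
      ramp <- matrix(seq(0, noise$gradient, length.out = ncol(m)),
                     nrow(m), ncol(m), byrow = TRUE)
      out <- out + ramp
    }
    out[out < 0] <- 0
    out
  })
}

.scene_seeds <- function(seed, n = 4L)
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))

#' Generate a synthetic one-cell (zygote) scene
#'
#' Renders a two-channel scene (mitochondria + organizer) from
#' [scene_params], recording the realized punctum centers and per-punctum
#' rendered masses as ground truth. Puncta are placed by the configured
#' mixture (uniform in cytoplasm, clump-centered Gaussians, perinuclear
#' shell enrichment, von Mises angular concentration), rendered as Gaussian
#' spots, and noise is applied last. Bit-identical for a fixed seed.
#'
#' @param params An [scene_params] object.
#' @return List of class `mq_scene` with `mito` ([mq_image]), `organizer`
#'   ([mq_image]) and `truth` (params, punctum centers in um and px, per-
#'   punctum masses, clump ids, organizer geometry in px, noise-free
#'   channels).
#' @export
generate_zygote_scene <- function(params) {
  p <- params
  if (!inherits(p, "mq_scene_params")) stop_parameter("need scene_params()")
  seeds <- .scene_seeds(p$seed, 3L)
  pts <- .with_seed(seeds[1L], .sample_puncta(p))
  rotd <- .apply_scene_rotation(p, pts$xy)
  pr <- rotd$p; xy <- rotd$xy
  amps <- rep(p$punctum_peak, p$n_puncta)
  mito0 <- .render_spots(xy, amps, pr)
  org0 <- .render_organizer(pr)
  mito <- .apply_noise(mito0, p$noise, seeds[2L])
  org <- .apply_noise(org0, p$noise, seeds[3L])
  np <- p$image_size_px; ctr <- (np - 1) / 2
  truth <- list(
    params = p,
    punctum_xy_um = xy,
    punctum_xy_px = xy / p$pixel_size_um + ctr,
    punctum_mass = amps * 2 * pi * (p$punctum_radius_um / 2 /
                                      p$pixel_size_um)^2,
    clump_id = pts$clump_id,
    organizer_center_px = pr$organizer_center_um / p$pixel_size_um + ctr,
    organizer_radii_px = pr$organizer_radii_um / p$pixel_size_um,
    organizer_angle_rad = pr$organizer_angle_rad,
    mito_noise_free = mito0,
    organizer_noise_free = org0)
  structure(list(
    mito = mq_image(mito, p$pixel_size_um, "mito"),
    organizer = mq_image(org, p$pixel_size_um, "chromatin"),
    truth = truth), class = "mq_scene")
}

#' @export
print.mq_scene <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "<synthetic scene> %d x %d px @ %.3g um/px, %d puncta, %d clumps, f = %.3g, kappa = %.3g\n",
    p$image_size_px, p$image_size_px, p$pixel_size_um, p$n_puncta,
    p$n_clumps, p$perinuclear_enrichment, p$angular_kappa))
  invisible(x)
}

#' Generate a synthetic two-cell (dividing) scene
#'
#' Places mitochondrial mass on the two sides of a vertical cleavage line
#' through the embryo center so that side A (left) receives exactly
#' `partition_fraction` of the total noise-free mass: whole puncta are
#' assigned per side and one fractional-amplitude punctum per side absorbs
#' the remainder. Puncta keep a margin from the line so spot tails do not
#' leak across. Two nuclei are rendered in the organizer channel.
#'
#' @param params An [scene_params] object with `partition_fraction` set.
#' @return List of class `mq_scene`; `truth` additionally records
#'   `plane_px` (two 0-based (x, y) points on the cleavage line),
#'   `mass_a`/`mass_b` (realized noise-free totals) and
#'   `partition_fraction`.
#' @export
generate_two_cell_scene <- function(params) {
  p <- params
  if (!inherits(p, "mq_scene_params")) stop_parameter("need scene_params()")
  seeds <- .scene_seeds(p$seed, 3L)
  f <- p$partition_fraction
  n <- p$n_puncta
  amp <- p$punctum_peak
  sig_um <- p$punctum_radius_um / 2
  margin <- 5 * sig_um + p$pixel_size_um
  R <- p$embryo_radius_um
  nL <- floor(f * n); fracL <- f * n - nL
  nR <- floor((1 - f) * n); fracR <- (1 - f) * n - nR
  sample_side <- function(k, side) {
    xy <- matrix(NA_real_, k, 2L)
    got <- 0L
    while (got < k) {
      m <- max(4L * (k - got), 32L)
      r <- (R - 2 * p$punctum_radius_um) * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      keep <- if (side < 0) x < -margin else x > margin
      nk <- sum(keep)
      if (nk) {
        take <- min(nk, k - got)
        sel <- which(keep)[seq_len(take)]
        xy[got + seq_len(take), ] <- cbind(x[sel], y[sel])
        got <- got + take
      }
    }
    xy
  }
  pts <- .with_seed(seeds[1L], {
    xyL <- sample_side(nL + (fracL > 0), -1)
    xyR <- sample_side(nR + (fracR > 0), +1)
    list(xyL = xyL, xyR = xyR)
  })
  ampsL <- c(rep(amp, nL), if (fracL > 0) amp * fracL)
  ampsR <- c(rep(amp, nR), if (fracR > 0) amp * fracR)
  xy <- rbind(pts$xyL, pts$xyR)
  amps <- c(ampsL, ampsR)
  mito0 <- .render_spots(xy, amps, p)
  # two nuclei, one per prospective blastomere
  oc <- p$organizer_radii_um
  pn <- p
  pn$organizer_radii_um <- pmin(oc, R / 5)
  org0 <- .render_organizer(pn, center_um = c(-R / 2, 0)) +
    .render_organizer(pn, center_um = c(R / 2, 0))
  mito <- .apply_noise(mito0, p$noise, seeds[2L])
  org <- .apply_noise(org0, p$noise, seeds[3L])
  np <- p$image_size_px; ctr <- (np - 1) / 2
  left_cols <- seq_len(floor(ctr) + 1L)       # columns with x-center < ctr
  mass_a <- sum(mito0[, left_cols])
  mass_b <- sum(mito0) - mass_a
  truth <- list(
    params = p,
    punctum_xy_um = xy,
    punctum_xy_px = xy / p$pixel_size_um + ctr,
    punctum_amp = amps,
    plane_px = rbind(c(ctr, 0), c(ctr, np - 1)),
    mass_a = mass_a, mass_b = mass_b,
    partition_fraction = f,
    mito_noise_free = mito0,
    organizer_noise_free = org0)
  structure(list(
    mito = mq_image(mito, p$pixel_size_um, "mito"),
    organizer = mq_image(org, p$pixel_size_um, "chromatin"),
    truth = truth), class = "mq_scene")
}

#' Generate a field of non-overlapping filled ellipses with known axes
#'
#' Fixture for electron-microscopy-style morphometry: ellipses with known
#' major/minor axes and random orientations are laid out on a grid so they
#' never touch, and their planted geometry is returned alongside the image.
#'
#' @param n Number of ellipses.
#' @param major_range_um Range of full major-axis lengths, um.
#' @param aspect_range Range of aspect ratios (major/minor), >= 1.
#' @param pixel_size_um Micrometres per pixel (default 0.05, EM-like).
#' @param seed Integer seed.
#' @return List with `image` ([mq_image], foreground 200 on background 0)
#'   and `truth` (data frame `id`, `center_x_px`, `center_y_px`,
#'   `major_um`, `minor_um`, `aspect_ratio`, `theta_rad`).
#' @export
generate_em_ellipses <- function(n, major_range_um = c(1.5, 3),
                                 aspect_range = c(1, 3),
                                 pixel_size_um = 0.05, seed = 1L) {
  if (n < 1) stop_parameter("'n' must be >= 1")
  if (min(aspect_range) < 1) stop_parameter("aspect ratios must be >= 1")
  .with_seed(seed, {
    major <- stats::runif(n, major_range_um[1L], major_range_um[2L])
    aspect <- stats::runif(n, aspect_range[1L], aspect_range[2L])
    minor <- major / aspect
    theta <- stats::runif(n, 0, pi)
    cell_px <- ceiling(max(major_range_um) / pixel_size_um) + 8L
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    np_x <- ncols * cell_px; np_y <- nrows * cell_px
    img <- matrix(0, np_y, np_x)
    cx <- cy <- numeric(n)
    for (i in seq_len(n)) {
      gc <- (i - 1L) %% ncols; gr <- (i - 1L) %/% ncols
      cx[i] <- gc * cell_px + cell_px / 2
      cy[i] <- gr * cell_px + cell_px / 2
      a <- major[i] / 2 / pixel_size_um    # semi-axes in px
      b <- minor[i] / 2 / pixel_size_um
      x0 <- max(0L, floor(cx[i] - a - 2)); x1 <- min(np_x - 1L, ceiling(cx[i] + a + 2))
      y0 <- max(0L, floor(cy[i] - a - 2)); y1 <- min(np_y - 1L, ceiling(cy[i] + a + 2))
      xs <- x0:x1; ys <- y0:y1
      gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      gy <- matrix(ys, length(ys), length(xs))
      rho <- .ellipse_rho(gx, gy, cx[i], cy[i], a, b, theta[i])
      blk <- img[ys + 1L, xs + 1L]
      blk[rho <= 1] <- 200
      img[ys + 1L, xs + 1L] <- blk
    }
    list(image = mq_image(img, pixel_size_um, "other"),
         truth = data.frame(id = seq_len(n), center_x_px = cx,
                            center_y_px = cy, major_um = major,
                            minor_um = minor, aspect_ratio = aspect,
                            theta_rad = theta))
  })
}

#' Generate a centroid track along waypoints
#'
#' Linearly interpolates between waypoints and adds isotropic Gaussian
#' positional noise, producing the (t, x, y) table the track-projection
#' analysis consumes.
#'
#' @param waypoints Matrix or data frame of (x, y) waypoints (>= 2 rows),
#'   px.
#' @param n_per_segment Interpolated points per waypoint segment.
#' @param noise_sd_px Positional noise sd, px (0 = noise-free).
#' @param seed Integer seed.
#' @return Data frame with columns `t`, `x`, `y`.
#' @export
generate_track <- function(waypoints, n_per_segment = 10L,
                           noise_sd_px = 0, seed = 1L) {
  w <- as.matrix(waypoints)
  if (nrow(w) < 2L) stop_parameter("need at least 2 waypoints")
  segs <- lapply(seq_len(nrow(w) - 1L), function(i) {
    s <- seq(0, 1, length.out = n_per_segment + 1L)
    s <- s[-length(s)]
    cbind(w[i, 1L] + s * (w[i + 1L, 1L] - w[i, 1L]),
          w[i, 2L] + s * (w[i + 1L, 2L] - w[i, 2L]))
  })
  xy <- rbind(do.call(rbind, segs), w[nrow(w), , drop = FALSE])
  if (noise_sd_px > 0)
    xy <- .with_seed(seed,
                     xy + matrix(stats::rnorm(length(xy), sd = noise_sd_px),
                                 nrow(xy), 2L))
  data.frame(t = seq_len(nrow(xy)) - 1L, x = xy[, 1L], y = xy[, 2L])
}

#' Embryo disk mask for a synthetic scene
#'
#' The ground-truth cell mask: pixels within the embryo radius of the field
#' center. Rotation invariant, so it is also the natural region argument for
#' angular statistics on synthetic scenes.
#'
#' @param params An [scene_params] object (or the `truth$params` of a
#'   generated scene).
#' @return An [mq_mask].
#' @export
scene_cell_mask <- function(params) {
  p <- params
  if (inherits(p, "mq_scene")) p <- p$truth$params
  if (!inherits(p, "mq_scene_params")) stop_parameter("need scene_params()")
  np <- p$image_size_px; ps <- p$pixel_size_um
  ctr <- (np - 1) / 2
  xs <- ((0:(np - 1)) - ctr) * ps
  gx <- matrix(xs, np, np, byrow = TRUE)
  gy <- matrix(xs, np, np)
  binary_mask(gx^2 + gy^2 <= p$embryo_radius_um^2)
}

#' Ground-truth organizer mask for a synthetic scene
#'
#' The realized organizer (nucleus/spindle) ellipse as a binary mask, taken
#' from the scene's ground truth rather than from thresholding the rendered
#' channel, for planted-truth tests of the downstream statistics.
#'
#' @param scene An `mq_scene` from [generate_zygote_scene].
#' @return An [mq_mask].
#' @export
scene_organizer_mask <- function(scene) {
  if (!inherits(scene, "mq_scene")) stop_parameter("need an mq_scene")
  tr <- scene$truth
  np <- tr$params$image_size_px
  gx <- matrix(0:(np - 1), np, np, byrow = TRUE)
  gy <- matrix(0:(np - 1), np, np)
  rho <- .ellipse_rho(gx, gy, tr$organizer_center_px[1L],
                      tr$organizer_center_px[2L],
                      tr$organizer_radii_px[1L], tr$organizer_radii_px[2L],
                      tr$organizer_angle_rad)
  binary_mask(rho <= 1)
}
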