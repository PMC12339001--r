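make_square_mask <- function(n, rows, cols) {
  m <- matrix(FALSE, n, n); m[rows, cols] <- TRUE
  binary_mask(m)
}

test_that("accumulation ratio is exact on constructed ring geometries", {
  n <- 128L
  org <- make_square_mask(n, 55:73, 55:73)
  cell <- binary_mask(matrix(TRUE, n, n))

  # uniform channel -> ratio 1
  u <- mq_image(matrix(5, n, n), 0.1)
  expect_equal(accumulation_ratio(u, org, cell)$ratio, 1, tolerance = 1e-6)

  # intensity 2u in the ring, u outside -> ratio 2
  ring <- dilate_mask(org, 10L)$pixels & !org$pixels
  m <- matrix(3, n, n); m[ring] <- 6
  expect_equal(accumulation_ratio(mq_image(m, 0.1), org, cell)$ratio, 2,
               tolerance = 1e-6)

  # invariance to positive scaling of the channel
  r1 <- accumulation_ratio(mq_image(m, 0.1), org, cell)$ratio
  r2 <- accumulation_ratio(mq_image(17.3 * m, 0.1), org, cell)$ratio
  expect_equal(r1, r2, tolerance = 1e-12)

  # degenerate geometry: cell fully inside the dilated organizer
  tiny_cell <- make_square_mask(n, 50:78, 50:78)
  expect_error(accumulation_ratio(u, org, tiny_cell),
               class = "mq_degenerate_error")
})

test_that("accumulation ratio recovers planted perinuclear enrichment", {
  # shell width matched to the measurement ring (2 um = 20 px); density
  # ratios need a Poisson pattern, so the hard core is disabled
  measure <- function(f, s) {
    p <- scene_params(image_size_px = 400L, pixel_size_um = 0.1,
                      embryo_radius_um = 19, organizer_radii_um = c(6, 6),
                      n_puncta = 300L, perinuclear_enrichment = f,
                      shell_width_um = 2, min_separation_um = 0,
                      noise = NULL, seed = s)
    sc <- generate_zygote_scene(p)
    accumulation_ratio(sc$mito, scene_organizer_mask(sc), scene_cell_mask(p),
                       ring_width_px = 20L)$ratio
  }
  ratios <- vapply(c(1, 2, 4), function(f)
    mean(vapply(1:6, function(s) measure(f, s), numeric(1))), numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios, c(1, 2, 4), tolerance = 0.1)
})

test_that("symmetry index and inheritance ratio are reciprocal and order-free", {
  pm <- partition_measures(100, 100)
  expect_equal(pm$symmetry_index, 1)
  expect_equal(pm$inheritance_ratio, 1)

  pm2 <- partition_measures(60, 40)
  expect_equal(pm2$symmetry_index, 1.5)
  expect_equal(pm2$inheritance_ratio, 2 / 3)
  pm3 <- partition_measures(40, 60)
  expect_equal(pm3$symmetry_index, pm2$symmetry_index)
  expect_equal(pm3$inheritance_ratio, pm2$inheritance_ratio)

  set.seed(99)
  for (i in 1:1000) {
    ab <- runif(2, 1e-6, 1e6)
    pm <- partition_measures(ab[1], ab[2])
    expect_equal(pm$symmetry_index * pm$inheritance_ratio, 1,
                 tolerance = 1e-12)
  }

  expect_warning(z <- partition_measures(10, 0))
  expect_identical(z$symmetry_index, Inf)
  expect_identical(z$inheritance_ratio, 0)
  expect_error(partition_measures(-1, 5), class = "mq_input_error")
  expect_error(partition_measures(0, 0), class = "mq_input_error")
})

test_that("cleavage-plane splitting respects symmetry and sidedness", {
  n <- 64L
  set.seed(21)
  half <- matrix(runif(n * n / 2, 0, 50), n, n / 2)
  m <- cbind(half, half[, (n / 2):1])         # mirror symmetric about x
  cell <- binary_mask(matrix(TRUE, n, n))
  plane <- rbind(c((n - 1) / 2, 0), c((n - 1) / 2, n - 1))  # between columns
  tt <- split_totals_by_plane(m, cell, plane)
  expect_equal(unname(tt["total_a"]), unname(tt["total_b"]), tolerance = 1e-9)

  # all intensity strictly on one side
  left <- matrix(0, n, n); left[, 1:10] <- 4
  tl <- split_totals_by_plane(left, cell, plane)
  expect_equal(unname(tl), c(sum(left), 0))

  # line outside the cell bounding box
  far <- rbind(c(500, 0), c(500, 10))
  expect_error(split_totals_by_plane(m, cell, far),
               class = "mq_parameter_error")
})

test_that("two-cell scenes recover the planted partition fraction", {
  for (f in c(0.5, 0.7, 0.8)) {
    p <- test_scene_params(31, partition_fraction = f)
    sc <- generate_two_cell_scene(p)
    tt <- split_totals_by_plane(sc$mito, scene_cell_mask(p), sc$truth$plane_px)
    expect_equal(unname(tt["total_a"] / sum(tt)), f, tolerance = 0.02)
  }
  # fraction 0.8: symmetry index ~ 4 and mirrored scenes give identical measures
  p8 <- test_scene_params(32, partition_fraction = 0.8)
  sc8 <- generate_two_cell_scene(p8)
  tt8 <- split_totals_by_plane(sc8$mito, scene_cell_mask(p8), sc8$truth$plane_px)
  pm <- partition_measures(tt8[1], tt8[2])
  expect_equal(pm$symmetry_index, 4, tolerance = 0.15)
  pm_sw <- partition_measures(tt8[2], tt8[1])
  expect_identical(pm$symmetry_index, pm_sw$symmetry_index)
})

test_that("cluster statistics recover dispersed and aggregated planted truth", {
  sc <- generate_zygote_scene(test_scene_params(7))
  cs <- cluster_stats(sc$mito)
  expect_equal(cs$n_clusters, 200, tolerance = 2 / 200)
  expect_gt(cs$mean_area_um2, 0.15)
  expect_lt(cs$mean_area_um2, 0.6)

  sc5 <- generate_zygote_scene(test_scene_params(7, n_clumps = 5L,
                                                 clump_spread_um = 0.6))
  cs5 <- cluster_stats(sc5$mito)
  expect_identical(cs5$n_clusters, 5L)
  expect_gt(cs5$mean_area_um2, 10 * cs$mean_area_um2)

  # total thresholded area is conserved when the filter is off
  mask <- threshold_yen(sc$mito)
  reg0 <- label_regions(mask, 0.1, min_area_um2 = 0)
  expect_equal(sum(reg0$area_um2), sum(mask$pixels) * 0.1^2)

  expect_error(cluster_stats(mq_image(matrix(0, 16, 16), 0.1)),
               class = "mq_degenerate_error")
})

test_that("angular non-uniformity is zero for isotropic channels and follows closed forms", {
  n <- 201L
  ctr <- (n - 1) / 2
  gx <- matrix(0:(n - 1), n, n, byrow = TRUE) - ctr
  gy <- t(gx)
  rr <- sqrt(gx^2 + gy^2)
  spindle <- binary_mask(rr <= 15)
  cell <- binary_mask(rr <= 90)

  # exactly isotropic channel (constant): sd = 0 to machine precision
  expect_warning(
    ap0 <- angular_uniformity(mq_image(matrix(40, n, n), 0.1), spindle,
                              cell_mask = cell),
    "isotropic spindle mask")
  expect_lt(ap0$nonuniformity_sd, 1e-6)

  # discretized isotropic ring: sub-percent residual non-uniformity
  ring <- mq_image(100 * exp(-(rr - 60)^2 / 18), 0.1)
  expect_warning(apr <- angular_uniformity(ring, spindle, cell_mask = cell))
  expect_lt(apr$nonuniformity_sd / mean(apr$sector_means), 0.01)

  # all intensity in one sector: sd equals the closed form sd({m,0,0,0,0,0})
  elong <- binary_mask(abs(gx) <= 20 & abs(gy) <= 3)   # axis along x
  wedge <- matrix(0, n, n)
  ang <- atan2(gy, gx)
  inw <- ang > 0.1 & ang < pi / 3 - 0.1 & rr > 25 & rr <= 85
  wedge[inw] <- 30
  ap1 <- angular_uniformity(mq_image(wedge, 0.1), elong, cell_mask = cell,
                            smooth_radius_px = 0.26)
  sm <- ap1$sector_means
  expect_identical(which.max(sm), 1L)
  m1 <- max(sm)
  expect_equal(ap1$nonuniformity_sd, sd(c(m1, rep(0, 5))), tolerance = 0.05)

  expect_error(angular_uniformity(ring, binary_mask(matrix(FALSE, n, n))),
               class = "mq_parameter_error")
})

test_that("angular non-uniformity increases with planted angular concentration", {
  sd_for <- function(kap, s) {
    p <- test_scene_params(s, angular_kappa = kap, min_separation_um = 0)
    sc <- generate_zygote_scene(p)
    sp <- threshold_yen(gaussian_smooth(sc$organizer, 2))
    angular_uniformity(sc$mito, sp,
                       cell_mask = scene_cell_mask(p))$nonuniformity_sd
  }
  seeds <- 1:8
  sds <- vapply(c(0, 1, 4), function(k)
    mean(vapply(seeds, function(s) sd_for(k, s), numeric(1))), numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("angular non-uniformity is invariant to scene rotation", {
  base <- function(rot) test_scene_params(11, angular_kappa = 2,
                                          min_separation_um = 0,
                                          scene_rotation_rad = rot)
  sd_of <- function(p) {
    sc <- generate_zygote_scene(p)
    sp <- threshold_yen(gaussian_smooth(sc$organizer, 2))
    angular_uniformity(sc$mito, sp,
                       cell_mask = scene_cell_mask(p))$nonuniformity_sd
  }
  s0 <- sd_of(base(0))
  for (rot in c(0.7, 1.9)) {
    expect_equal(sd_of(base(rot)), s0, tolerance = 0.05 * s0)
  }
})

test_that("ROS enrichment recovers constructed and planted ratios", {
  p <- scene_params(image_size_px = 256L, pixel_size_um = 0.1,
                    embryo_radius_um = 11, organizer_radii_um = c(3, 3),
                    n_puncta = 120L, noise = NULL, seed = 5)
  sc <- generate_zygote_scene(p)
  n <- 256L
  u <- 50

  # uniform ROS -> 1
  expect_equal(ros_enrichment(mq_image(matrix(u, n, n), 0.1, "ros"),
                              sc$mito)$ratio, 1, tolerance = 0.05)

  # ROS = 3u on the mitochondrial mask, u elsewhere -> 3
  proc <- gaussian_smooth(rolling_ball_subtract(sc$mito, 5), 2)
  inside <- threshold_moments(proc)
  ros3 <- mq_image(matrix(u, n, n) + 2 * u * inside$pixels, 0.1, "ros")
  expect_equal(ros_enrichment(ros3, sc$mito)$ratio, 3, tolerance = 0.1)

  # planted enrichment recovered monotonically
  ratios <- vapply(c(1, 2, 4), function(e) {
    ros <- mq_image(matrix(u, n, n) + (e - 1) * u * inside$pixels, 0.1, "ros")
    ros_enrichment(ros, sc$mito)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))

  expect_error(ros_enrichment(mq_image(matrix(u, 32, 32), 0.1),
                              mq_image(matrix(0:1, 16, 16) + 0, 0.1)),
               class = "mq_parameter_error")
})

test_that("pixel correlation detects affine relations and independence", {
  set.seed(8)
  n <- 100L
  a <- matrix(runif(n * n, 10, 200), n, n)
  mask <- binary_mask(matrix(TRUE, n, n))
  expect_equal(pixel_correlation(a, 2 * a + 5, mask), 1)
  expect_equal(pixel_correlation(a, -a + 300, mask), -1)

  b <- matrix(runif(n * n, 10, 200), n, n)   # independent, 10^4 px
  expect_lt(abs(pixel_correlation(a, b, mask)), 0.05)

  small <- binary_mask({m <- matrix(FALSE, n, n); m[1, 1:5] <- TRUE; m})
  expect_error(pixel_correlation(a, b, small), class = "mq_parameter_error")
  expect_error(pixel_correlation(a, matrix(3, n, n), mask),
               class = "mq_degenerate_error")
})

test_that("track projection follows its geometric definition", {
  # straight +x track: projections 0, 1, 2, ...
  tr <- data.frame(t = 0:5, x = 10 + 0:5, y = 3)
  tp <- track_projection(tr, center_xy = c(0, 0), pixel_size_um = 1)
  expect_equal(tp$projected_displacements, 0:5)
  expect_equal(tp$direction_unit, c(1, 0))

  # orthogonal intermediate motion projects to zero
  tr2 <- data.frame(t = 0:2, x = c(0, 0, 10), y = c(0, 7, 0))
  # chord is +x; intermediate point moved only in y
  tp2 <- track_projection(tr2, c(0, 0), 1)
  expect_equal(tp2$projected_displacements[2], 0)

  # 3-4-5 distance arithmetic
  tr3 <- data.frame(t = 0:1, x = c(0, 30), y = c(0, 40))
  tp3 <- track_projection(tr3, center_xy = c(0, 0), pixel_size_um = 0.5)
  expect_equal(tp3$final_distance_to_center_um, 25)
  # projected displacement at final time = |final - initial|
  expect_equal(tp3$projected_displacements[2], 50)

  same <- data.frame(t = 0:1, x = c(2, 2), y = c(3, 3))
  expect_error(track_projection(same, c(0, 0), 1),
               class = "mq_degenerate_error")
})
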