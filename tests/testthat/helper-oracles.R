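# Independent brute-force oracles the fast implementations are checked
# against. Deliberately written as direct loops/enumeration.

# full 2D convolution with a sampled separable Gaussian kernel and
# edge-replicated boundary
oracle_conv2_replicate <- function(m, kernel2d) {
  h <- (nrow(kernel2d) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1L), nr)
      jj <- min(max(j + dj, 1L), nc)
      acc <- acc + kernel2d[di + h + 1L, dj + h + 1L] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

gaussian_kernel2d <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq.int(-h, h), sd = sigma)
  k <- k / sum(k)
  outer(k, k)
}

# exhaustive Yen criterion search over the 256-level histogram
oracle_yen_level <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA_integer_
  for (t in 1:255) {
    p1 <- sum(p[1:t]); p1sq <- sum(p[1:t]^2); p2sq <- sum(p[(t + 1):256]^2)
    a <- p1sq * p2sq
    b <- p1 * (1 - p1)
    crit <- (if (a > 0) -log(a) else 0) + (if (b > 0) 2 * log(b) else 0)
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}

# exhaustive moment-preserving search: the level whose cumulative histogram
# fraction is closest to the Tsai fraction (ties -> lowest level)
oracle_moments_level <- function(counts, levels) {
  p <- counts / sum(counts)
  m1 <- 0; m2 <- 0; m3 <- 0
  for (i in 1:256) {
    m1 <- m1 + levels[i] * p[i]
    m2 <- m2 + levels[i]^2 * p[i]
    m3 <- m3 + levels[i]^3 * p[i]
  }
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  pd <- (z1 - m1) / (z1 - z0)
  pd <- min(max(pd, 0), 1)
  best <- Inf; best_t <- NA_integer_
  cum <- 0
  for (t in 1:255) {
    cum <- cum + p[t]
    if (abs(cum - pd) < best) { best <- abs(cum - pd); best_t <- t }
  }
  best_t
}

# a matrix whose histogram equals 'counts' on 256 bins over [0, 255]
matrix_from_histogram <- function(counts) {
  v <- rep(0:255, counts)
  n <- length(v)
  nr <- floor(sqrt(n))
  while (n %% nr != 0L) nr <- nr - 1L
  matrix(as.numeric(v), nr, n / nr)
}

# dilation by "any foreground within Euclidean distance w", point by point
oracle_dilate <- function(mask, w) {
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(fg) == 0L) return(out)
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    d2 <- (fg[, 1] - i)^2 + (fg[, 2] - j)^2
    out[i, j] <- any(d2 <= w^2)
  }
  out
}

# covariance-eigenvalue axes of a pixel set by direct enumeration
oracle_region_axes <- function(xy, pixel_size) {
  n <- nrow(xy)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  sxx <- sum((xy[, 1] - cx)^2) / n
  syy <- sum((xy[, 2] - cy)^2) / n
  sxy <- sum((xy[, 1] - cx) * (xy[, 2] - cy)) / n
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2))$values
  c(major = 4 * sqrt(ev[1]) * pixel_size, minor = 4 * sqrt(ev[2]) * pixel_size)
}

# exact moments of the inheritance ratio for n equal clusters by full
# enumeration of all 2^n assignments
oracle_partition_enum <- function(n, p) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  prob <- apply(grid, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  ka <- rowSums(grid)
  ratio <- ifelse(pmax(ka, n - ka) > 0, pmin(ka, n - ka) / pmax(ka, n - ka), 0)
  m <- sum(prob * ratio)
  list(mean = m, sd = sqrt(sum(prob * ratio^2) - m^2))
}

# standard scene geometry used across tests: small field, fine pixels so a
# 0.3 um^2 punctum spans enough pixels for area measurement
test_scene_params <- function(seed, ...) {
  args <- list(image_size_px = 384L, pixel_size_um = 0.1,
               embryo_radius_um = 17, organizer_radii_um = c(5, 2.5),
               organizer_angle_rad = 0.4, n_puncta = 200L,
               noise = NULL, seed = seed)
  dots <- list(...)
  for (nm in names(dots)) args[nm] <- dots[nm]
  do.call(scene_params, args)
}
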