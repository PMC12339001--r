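## Stochastic cluster-partitioning model: each mitochondrial cluster is
## assigned independently to one daughter blastomere. Fragmentation into many
## small clusters concentrates the inheritance ratio near 1 (symmetric
## partitioning); aggregation into few large clusters makes inheritance
## biased. This independent-Bernoulli assignment is the minimal
## formalization of the verbal mechanism.

#' Cluster population
#'
#' A set of positive cluster masses (arbitrary units: segmented cluster
#' areas in um^2, mtDNA copies, fluorescence totals, ...). Cluster areas
#' from [cluster_stats] can be fed in directly, linking the image pipeline
#' to the partition model.
#'
#' @param sizes Numeric vector of positive masses.
#' @return List of class `mq_cluster_population` with `sizes`, `n_clusters`,
#'   `total_mass`.
#' @examples
#' cluster_population(rep(1, 10))
#' @export
cluster_population <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 1L || !all(is.finite(sizes)) || any(sizes <= 0))
    stop_parameter("'sizes' must be a non-empty vector of positive masses")
  structure(list(sizes = sizes, n_clusters = length(sizes),
                 total_mass = sum(sizes)),
            class = "mq_cluster_population")
}

#' @export
print.mq_cluster_population <- function(x, ...) {
  cat(sprintf("<cluster population> %d clusters, total mass %.4g\n",
              x$n_clusters, x$total_mass))
  invisible(x)
}

.as_population <- function(pop) {
  if (inherits(pop, "mq_cluster_population")) pop
  else cluster_population(pop)
}

#' Simulate stochastic partitioning of clusters between daughter cells
#'
#' Each replicate assigns every cluster independently to daughter A with
#' probability `p` (otherwise B), sums the masses per side, and records the
#' inheritance ratio (smaller/greater total, in `[0, 1]`; 0 when one side
#' receives nothing). Mass is conserved exactly in every replicate, and the
#' result is reproducible for a fixed seed.
#'
#' @param pop A [cluster_population] or a numeric vector of cluster masses.
#' @param p Probability a cluster goes to side A, in (0, 1); default 0.5
#'   (geometrically symmetric division).
#' @param n_rep Number of replicate divisions, >= 1.
#' @param seed Integer RNG seed.
#' @return List of class `mq_partition_distribution` with `samples`
#'   (data frame `mass_a`, `mass_b`), `inheritance_ratios`, `mean_ratio`,
#'   `sd_ratio`, `n_rep`, `seed`.
#' @examples
#' simulate_partition(rep(1, 100), n_rep = 1000, seed = 1)
#' @export
simulate_partition <- function(pop, p = 0.5, n_rep, seed) {
  pop <- .as_population(pop)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) ||
      p <= 0 || p >= 1)
    stop_parameter("'p' must be a single number in (0, 1)")
  if (!is.numeric(n_rep) || length(n_rep) != 1L || n_rep < 1 ||
      n_rep != floor(n_rep))
    stop_parameter("'n_rep' must be a positive integer")
  n_rep <- as.integer(n_rep)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k <- pop$n_clusters
  # replicate-major draw matrix; columns are clusters
  to_a <- matrix(stats::runif(n_rep * k) < p, nrow = n_rep, ncol = k)
  mass_a <- as.numeric(to_a %*% pop$sizes)
  mass_b <- pop$total_mass - mass_a
  g <- pmax(mass_a, mass_b); s <- pmin(mass_a, mass_b)
  ratios <- s / g                     # g > 0 since total_mass > 0
  structure(list(samples = data.frame(mass_a = mass_a, mass_b = mass_b),
                 inheritance_ratios = ratios,
                 mean_ratio = mean(ratios),
                 sd_ratio = stats::sd(ratios),
                 n_rep = n_rep, seed = as.integer(seed)),
            class = "mq_partition_distribution")
}

#' @export
print.mq_partition_distribution <- function(x, ...) {
  cat(sprintf(
    "<partition distribution> %d replicates, mean inheritance ratio %.4f (sd %.4f)\n",
    x$n_rep, x$mean_ratio, x$sd_ratio))
  invisible(x)
}

## save/restore the global RNG state so simulators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Exact partition distribution for equal clusters
#'
#' For `n` equal-mass clusters assigned independently with probability `p`,
#' the split (k, n - k) follows the binomial law; every split and its exact
#' probability are enumerated and the exact mean and standard deviation of
#' the inheritance ratio min(k, n-k)/max(k, n-k) are computed. This is the
#' closed-form oracle the Monte-Carlo simulator is checked against.
#'
#' @param n_equal_clusters Number of equal clusters, integer in 1..20
#'   (enumeration regime).
#' @param p Assignment probability to side A, in \[0, 1\] (the boundary
#'   values are allowed and put all mass on one side with probability 1).
#' @return List of class `mq_exact_partition` with `table` (data frame `k`,
#'   `prob`, `inheritance_ratio`), `mean_ratio`, `sd_ratio`.
#' @export
exact_partition_distribution <- function(n_equal_clusters, p) {
  n <- n_equal_clusters
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > 20 ||
      n != floor(n))
    stop_parameter("'n_equal_clusters' must be an integer in 1..20")
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop_parameter("'p' must be in [0, 1]")
  n <- as.integer(n)
  k <- 0:n
  prob <- stats::dbinom(k, n, p)
  ratio <- ifelse(pmax(k, n - k) > 0, pmin(k, n - k) / pmax(k, n - k), 0)
  m <- sum(prob * ratio)
  v <- sum(prob * ratio^2) - m^2
  structure(list(table = data.frame(k = k, prob = prob,
                                    inheritance_ratio = ratio),
                 mean_ratio = m, sd_ratio = sqrt(max(v, 0))),
            class = "mq_exact_partition")
}

#' @export
print.mq_exact_partition <- function(x, ...) {
  cat(sprintf(
    "<exact partition> n = %d, mean inheritance ratio %.4f (sd %.4f)\n",
    nrow(x$table) - 1L, x$mean_ratio, x$sd_ratio))
  invisible(x)
}

#' Mean inheritance ratio as a function of fragmentation
#'
#' Splits a fixed total mass into `n` equal clusters for each `n` in
#' `n_values` and simulates partitioning; the mean inheritance ratio is
#' monotone non-decreasing in the number of clusters (up to Monte-Carlo
#' error), formalizing why fragmented, dispersed mitochondria are inherited
#' symmetrically while aggregates are not. The curve does not depend on the
#' total mass (ratios are scale-free).
#'
#' @param total_mass Total mass to split (any positive value).
#' @param n_values Integer vector of cluster counts, all >= 1.
#' @param p Assignment probability (default 0.5).
#' @param n_rep Replicates per cluster count.
#' @param seed Integer seed; each cluster count uses a sub-seed derived from
#'   it so the curve is reproducible as a whole.
#' @return Data frame with columns `n_clusters`, `mean_ratio`, `sd_ratio`.
#' @export
asymmetry_vs_fragmentation <- function(total_mass, n_values, p = 0.5,
                                       n_rep, seed) {
  if (!is.numeric(total_mass) || total_mass <= 0)
    stop_parameter("'total_mass' must be positive")
  if (any(n_values < 1) || any(n_values != floor(n_values)))
    stop_parameter("'n_values' must be positive integers")
  res <- lapply(seq_along(n_values), function(i) {
    n <- n_values[i]
    sim <- simulate_partition(rep(total_mass / n, n), p = p,
                              n_rep = n_rep,
                              seed = (as.integer(seed) + i) %% .Machine$integer.max)
    data.frame(n_clusters = n, mean_ratio = sim$mean_ratio,
               sd_ratio = sim$sd_ratio)
  })
  do.call(rbind, res)
}
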