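# shared helpers for the test suite

# desk-scale analysis profile used throughout the tests: the synthetic grid is
# 24^3 with radius-2 planted regions, so the conventional 200-voxel extent is
# replaced by 10 and permutation counts kept modest for runtime
desk_config <- function(...) {
  analysis_config(min_cluster_voxels = 10, n_perm = 200, ...)
}

# independent least-squares oracle for the signed lag-1 GC path coefficient:
# standardize both series with scale(), fit the autoregression with lm(), and
# return the coefficient of the lagged exogenous series
lm_gc_oracle <- function(x, y) {
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y))
  T <- length(xs)
  fit <- stats::lm(ys[2:T] ~ ys[1:(T - 1)] + xs[1:(T - 1)])
  unname(stats::coef(fit)[3])
}

# standardized single-mediator data with planted paths; unit-variance
# construction so the population standardized coefficients equal (a, b, cp)
med_sim <- function(seed, n = 500, a = -0.8, b = 0.7, cp = -0.3) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- a * x + sqrt(1 - a^2) * stats::rnorm(n)
  y <- cp * x + b * m +
    sqrt(max(0, 1 - (cp^2 + b^2 + 2 * a * b * cp))) * stats::rnorm(n)
  list(x = x, m = m, y = y)
}

# the radial density template and mask used by the image generator,
# recomputed independently for reconstruction oracles
template_and_mask <- function(dm = c(24L, 24L, 24L)) {
  ctr <- (dm + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(dm[k]) - ctr[k])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  template <- exp(-d2 / (2 * 7^2))
  list(template = template, mask = template > 0.27)
}

# mean pseudo-time series over a set of regions
region_series <- function(pts, regions) {
  vapply(regions, function(r) {
    v <- region_voxels(r, pts$geometry$dim)
    cols <- match(intersect(v, pts$feature_index), pts$feature_index)
    rowMeans(pts$data[, cols, drop = FALSE])
  }, numeric(nrow(pts$data)))
}

# a ground truth with one positive and one negative lag-1 target: the only
# layout whose compensatory effect is visible to a lag-1 seed GC map
lag1_truth <- function() {
  ground_truth(
    positive_targets = list(
      list(roi = region(c(8, 18, 12), 2, "pos_A"), weight = 0.8, lag = 1L)),
    negative_targets = list(
      list(roi = region(c(16, 18, 8), 2, "neg_C"), weight = -0.6, lag = 1L)))
}

# enumerate all set partitions of 1..n (test-local implementation,
# independent of the package's optimizer internals)
enum_partitions <- function(n) {
  grow <- function(prefix) {
    if (length(prefix) == n) return(list(prefix))
    mx <- if (length(prefix)) max(prefix) else 0L
    out <- list()
    for (v in seq_len(mx + 1L)) out <- c(out, grow(c(prefix, v)))
    out
  }
  grow(integer(0))
}

# directed weighted modularity evaluated by igraph (independent oracle)
igraph_q <- function(graph, membership) {
  A <- abs(graph$adjacency); A[is.na(A)] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed", weighted = TRUE)
  igraph::modularity(g, membership, weights = igraph::E(g)$weight,
                     directed = TRUE)
}

# random signed adjacency matrix with every |gc| above the retention threshold
random_adjacency <- function(n, p_edge = 0.35) {
  adj <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && stats::runif(1) < p_edge)
      adj[i, j] <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 1)
  }
  if (all(is.na(adj))) adj[1, 2] <- 0.8
  adj
}
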