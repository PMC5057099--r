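# Independent oracles used to gate the implementation. Each is deliberately
# written the naive way (loops, explicit set arithmetic) and never shares code
# with the package.

# Eq-style neighbor-set distance via explicit set operations on index vectors.
local_distance_set_oracle <- function(R, i, j) {
  gi <- which(R[, i] == 1)
  gj <- which(R[, j] == 1)
  sym_diff <- length(setdiff(gi, gj)) + length(setdiff(gj, gi))
  sym_diff / length(union(gi, gj))
}

# All-pairs shortest paths by Floyd-Warshall on a dense weight matrix
# (Inf where no edge, 0 diagonal).
floyd_warshall_oracle <- function(W) {
  D <- W
  for (k in seq_len(nrow(W))) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Random connected weighted graph as an igraph object plus its dense weight
# matrix; a random spanning chain guarantees connectivity.
random_connected_graph <- function(n, extra_edges = n, seed = 1) {
  set.seed(seed)
  perm <- sample(n)
  edges <- cbind(perm[-n], perm[-1])
  more <- cbind(sample(n, extra_edges, replace = TRUE),
                sample(n, extra_edges, replace = TRUE))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  edges <- rbind(edges, more)
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  w <- runif(nrow(edges), 0.1, 2)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges), weight = w)
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    W[i, j] <- min(W[i, j], w[e])
    W[j, i] <- W[i, j]
  }
  list(graph = g, W = W)
}

# Random symmetric binary matrix with unit diagonal.
random_recurrence_matrix <- function(n, density = 0.3, seed = 1) {
  set.seed(seed)
  R <- matrix(0L, n, n)
  R[upper.tri(R)] <- rbinom(n * (n - 1) / 2, 1, density)
  R <- R + t(R)
  diag(R) <- 1L
  R
}

# One explicit RK4 step, independent of deSolve.
rk4_step_oracle <- function(f, y, dt) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# Naive O(n^3) agglomerative clustering on a dissimilarity matrix; returns
# merge heights in order and the member sets merged at each step.
naive_agglomeration_oracle <- function(D, linkage = "average") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  link <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    switch(linkage,
           average = mean(vals), complete = max(vals), single = min(vals))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in seq(a + 1, length(clusters))) {
        d <- link(clusters[[a]], clusters[[b]])
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1]] <-
      list(sort(clusters[[best[1]]]), sort(clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Procrustes-aligned RMSD between two configurations (uses the package's
# aligner); convenience for recovery checks.
aligned_rmsd <- function(A, B, allow_scale = TRUE) {
  procrustes_align(A, B, allow_reflection = TRUE,
                   allow_scale = allow_scale)$rmsd
}

# A small single-chromosome contact map fixture derived from a fixed curve.
fixture_map <- function(n_bins = 40, seed = 7, rate = 0.1) {
  sc <- synthetic_chromosome(n_bins = n_bins, seed = seed)
  contact_map_from_structure(sc, target_rate = rate)
}

expect_valid_contact_map <- function(map) {
  testthat::expect_s3_class(map, "contact_map")
  R <- map$R
  testthat::expect_true(isSymmetric(unname(R)))
  testthat::expect_true(all(R %in% c(0L, 1L)))
  testthat::expect_true(all(diag(R) == 1L))
  if (!is.null(map$bins)) testthat::expect_equal(nrow(map$bins), nrow(R))
}
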