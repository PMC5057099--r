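test_that("column_neighbor_set returns the plotted indices of a column", {
  expect_equal(column_neighbor_set(diag(1L, 3), 1), 1)
  expect_equal(column_neighbor_set(matrix(1L, 3, 3), 2), 1:3)
  m <- diag(1L, 4); m[1, 2] <- m[2, 1] <- 1L
  expect_equal(column_neighbor_set(m, 1), c(1, 2))
  expect_true(all(vapply(1:4, function(i) i %in% column_neighbor_set(m, i),
                         logical(1))))
  expect_error(column_neighbor_set(m, 5), "out of range")
  expect_error(column_neighbor_set(m, 0), "out of range")
})

test_that("local_distance matches hand-evaluated neighbor-set arithmetic", {
  # chain recurrence matrix: columns 2 and 3 have neighbor sets {1,2,3} and
  # {2,3,4}; symmetric difference {1,4}, union {1,2,3,4} -> 2/4 = 0.5
  m <- diag(1L, 5)
  for (i in 1:3) m[i, i + 1] <- m[i + 1, i] <- 1L
  expect_equal(column_neighbor_set(m, 2), c(1, 2, 3))
  expect_equal(column_neighbor_set(m, 3), c(2, 3, 4))
  expect_equal(local_distance(m, 2, 3), 0.5)

  # zero iff identical neighbor sets; i = j is zero
  dup <- matrix(1L, 4, 4); dup[1, 4] <- dup[4, 1] <- 0L
  expect_equal(local_distance(dup, 2, 3), 0)   # both columns see everyone
  expect_equal(local_distance(dup, 1, 1), 0)
  expect_gt(local_distance(dup, 1, 2), 0)
})

test_that("local_distance agrees exactly with the set-arithmetic oracle", {
  for (seed in 1:50) {
    n <- sample(4:12, 1)
    R <- random_recurrence_matrix(n, density = runif(1, 0.15, 0.6),
                                  seed = seed)
    pairs <- which(upper.tri(R) & R == 1, arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      expect_identical(local_distance(R, i, j),
                       local_distance_set_oracle(R, i, j))
      expect_identical(local_distance(R, i, j), local_distance(R, j, i))
    }
  }
})

test_that("build_graph creates one weighted edge per contact pair", {
  m <- diag(1L, 3)
  m[1, 2] <- m[2, 1] <- 1L
  m[2, 3] <- m[3, 2] <- 1L
  g <- build_graph(m)
  expect_equal(igraph::ecount(g), 2)
  el <- igraph::as_edgelist(g)
  weights <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    expect_equal(weights[e],
                 local_distance_set_oracle(m, el[e, 1], el[e, 2]))
  }

  gc <- build_graph(m, mode = "constant", constant_value = 1)
  expect_true(all(igraph::E(gc)$weight == 1))
  gc2 <- build_graph(m, mode = "constant", constant_value = 0.3)
  expect_true(all(igraph::E(gc2)$weight == 0.3))

  ones <- matrix(1L, 6, 6)
  expect_equal(igraph::ecount(build_graph(ones)), 6 * 5 / 2)
})

test_that("all_pairs_shortest computes exact geodesics", {
  g <- igraph::make_empty_graph(2, directed = FALSE)
  g <- igraph::add_edges(g, c(1, 2), weight = 0.5)
  D <- all_pairs_shortest(g, "dijkstra")
  expect_equal(D[1, 2], 0.5)
  expect_equal(diag(D), c(0, 0))

  # detour shorter than the direct edge
  tg <- igraph::make_empty_graph(3, directed = FALSE)
  tg <- igraph::add_edges(tg, c(1, 2, 2, 3, 1, 3), weight = c(1, 1, 3))
  expect_equal(all_pairs_shortest(tg, "dijkstra")[1, 3], 2)
})

test_that("dijkstra and johnson match an independent Floyd-Warshall", {
  for (seed in 1:20) {
    n <- sample(10:30, 1)
    rg <- random_connected_graph(n, extra_edges = 2 * n, seed = seed)
    Dd <- all_pairs_shortest(rg$graph, "dijkstra")
    Dj <- all_pairs_shortest(rg$graph, "johnson")
    Dfw <- floyd_warshall_oracle(rg$W)
    expect_lt(max(abs(Dd - Dfw)), 1e-12)
    expect_lt(max(abs(Dj - Dd)), 1e-12)
    expect_true(isSymmetric(Dd))
  }
})

test_that("disconnected graphs are rejected with a component report", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  g <- igraph::add_edges(g, c(1, 2, 3, 4), weight = c(1, 1))
  expect_error(all_pairs_shortest(g), "2 components.*2, 2")
})

test_that("adding an edge never increases a shortest-path distance", {
  set.seed(42)
  rg <- random_connected_graph(25, extra_edges = 30, seed = 99)
  D0 <- all_pairs_shortest(rg$graph)
  for (rep in 1:10) {
    ij <- sample(25, 2)
    g2 <- igraph::add_edges(rg$graph, ij, weight = runif(1, 0.05, 1))
    D1 <- all_pairs_shortest(g2)
    expect_true(all(D1 <= D0 + 1e-12))
  }
})

test_that("classical MDS recovers simple configurations", {
  # two points at distance 1 embed at +/- 0.5 on the first axis
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  s <- suppressWarnings(classical_mds(D, ndim = 3))
  expect_equal(sort(s$coordinates[, 1]), c(-0.5, 0.5))
  expect_equal(s$coordinates[, 2], c(0, 0))

  # unit square: re-derived pairwise distances equal the input
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  Dsq <- as.matrix(dist(sq))
  ssq <- suppressWarnings(classical_mds(Dsq, ndim = 3))  # planar: axis 3 padded
  expect_equal(as.matrix(dist(ssq$coordinates)), Dsq, tolerance = 1e-10)
  expect_true(all(diff(ssq$eigenvalues) <= 1e-12))
  expect_equal(colMeans(ssq$coordinates), c(x = 0, y = 0, z = 0),
               tolerance = 1e-12)
})

test_that("classical MDS inverts exact Euclidean distance matrices", {
  for (n in c(20, 80)) {
    set.seed(n)
    X <- matrix(rnorm(3 * n), n, 3)
    D <- as.matrix(dist(X))
    s <- classical_mds(D, ndim = 3)
    expect_lt(aligned_rmsd(X, s$coordinates, allow_scale = FALSE), 1e-8)
    # agreement with the base-R classical scaling as independent route
    ref <- stats::cmdscale(D, k = 3)
    for (d in 1:3) {
      expect_lt(min(max(abs(s$coordinates[, d] - ref[, d])),
                    max(abs(s$coordinates[, d] + ref[, d]))), 1e-8)
    }
  }
})

test_that("classical MDS clamps negative eigenvalues and zero-pads", {
  # 4-point star metric is non-Euclidean in 3D only partially; force a
  # degenerate case: 3 collinear points need 1 dimension, axes 2-3 padded
  X <- cbind(c(0, 1, 2), 0, 0)
  D <- as.matrix(dist(X))
  expect_warning(s <- classical_mds(D, ndim = 3), "zero-padded")
  expect_equal(s$coordinates[, 2], rep(0, 3))
  expect_equal(s$coordinates[, 3], rep(0, 3))
  expect_equal(s$eigenvalues[2:3], c(0, 0))
  expect_equal(as.matrix(dist(s$coordinates)), D, tolerance = 1e-10)
  # retained eigenvalues are never negative
  expect_true(all(s$eigenvalues >= 0))
})

test_that("reconstruct is deterministic and composes the pipeline", {
  cm <- fixture_map(n_bins = 30, seed = 11, rate = 0.1)
  s1 <- reconstruct(cm)
  s2 <- reconstruct(cm)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  # 2-bin map with no contacts: two points separated by the backbone weight
  bins <- make_bins(c(X = 500), 250)
  s3 <- suppressWarnings(reconstruct(contact_map(diag(1L, 2), bins = bins)))
  g <- build_graph(add_backbone(contact_map(diag(1L, 2), bins = bins)))
  w <- igraph::E(g)$weight
  expect_equal(dist(s3$coordinates)[1], w, tolerance = 1e-12)

  # disconnected non-genomic map is refused with advice
  m <- diag(1L, 4); m[1, 2] <- m[2, 1] <- 1L; m[3, 4] <- m[4, 3] <- 1L
  expect_error(reconstruct(contact_map(m)), "disconnected")
})

test_that("reconstructed global distances form a metric", {
  for (fix in list(fixture_map(n_bins = 50, seed = 2, rate = 0.08),
                   recurrence_plot(simulate_lorenz(60), target_rate = 0.1))) {
    s <- reconstruct(fix)
    D <- s$distances
    n <- nrow(D)
    expect_true(all(abs(diag(D)) == 0))
    expect_true(isSymmetric(D))
    expect_true(all(D[upper.tri(D)] >= 0))
    # exhaustive triangle inequality
    ok <- TRUE
    for (k in seq_len(n)) {
      if (any(D > outer(D[, k], D[k, ], `+`) + 1e-12)) { ok <- FALSE; break }
    }
    expect_true(ok)
  }
})

test_that("constant mode reproduces unit-resistance graph distances", {
  cm <- fixture_map(n_bins = 25, seed = 4, rate = 0.12)
  s <- reconstruct(cm, mode = "constant", constant_value = 1)
  bb <- add_backbone(binarize(cm))
  g <- build_graph(bb, mode = "constant", constant_value = 1)
  expect_equal(s$distances,
               unname(igraph::distances(g, weights = NA)))
})

test_that("tidy and glance summarize reconstructed structures", {
  cm <- fixture_map(n_bins = 20, seed = 9, rate = 0.15)
  s <- reconstruct(cm)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20)
  expect_true(all(c("chrom", "start", "end", "bin", "x", "y", "z") %in%
                    names(td)))
  gl <- glance(s)
  expect_equal(gl$n, 20)
  expect_gt(gl$radius_of_gyration, 0)
  expect_true(gl$lambda1 >= gl$lambda2 && gl$lambda2 >= gl$lambda3)
  expect_s3_class(autoplot(s), "ggplot")
})
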