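#' Neighbor set of a recurrence-matrix column
#'
#' The neighbor set of node `i` is the set of indices plotted in column `i`
#' of the recurrence matrix, G_i = \{k : R(k, i) = 1\}. Because the diagonal
#' is fixed to 1, `i` itself always belongs to G_i.
#'
#' @param R A `contact_map` or square binary matrix.
#' @param i Node index (1-based).
#' @return Integer vector of neighbor indices, sorted.
#' @export
column_neighbor_set <- function(R, i) {
  m <- if (inherits(R, "contact_map")) R$R else R
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > nrow(m) ||
      i != round(i)) {
    rlang::abort(sprintf("Index i = %s out of range 1..%d.",
                         format(i), nrow(m)))
  }
  which(m[, i] == 1)
}

#' Local distance between two contacting nodes
#'
#' The weight assigned to a contact edge: the Jaccard distance between the
#' neighbor sets of the two nodes,
#' \deqn{d(i, j) = \frac{|G_i \Delta G_j|}{|G_i \cup G_j|},}
#' where \eqn{G_i = \{k : R(k, i) = 1\}}. Two nodes whose neighborhoods
#' coincide are locally indistinguishable and get distance 0; the more their
#' recurrence neighborhoods differ, the larger the local distance, up to 1.
#' Because the diagonal of R is 1, the union is never empty.
#'
#' @param R A `contact_map` or square binary matrix.
#' @param i,j Node indices (1-based).
#' @return A number in \[0, 1\], symmetric in `i` and `j`.
#' @export
local_distance <- function(R, i, j) {
  m <- if (inherits(R, "contact_map")) R$R else R
  n <- nrow(m)
  for (k in c(i, j)) {
    if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k)) {
      rlang::abort(sprintf("Index %s out of range 1..%d.", format(k), n))
    }
  }
  gi <- m[, i] == 1
  gj <- m[, j] == 1
  sum(xor(gi, gj)) / sum(gi | gj)
}

#' Build the weighted neighborhood graph of a contact map
#'
#' One undirected edge per off-diagonal contact pair R(i, j) = 1. In `"rpr"`
#' mode every edge carries the neighbor-set local distance
#' ([local_distance()]); in `"constant"` mode every edge carries the same
#' constant weight, which reduces the method to a Paulsen-style
#' unit-resistance graph.
#'
#' @param R A `contact_map` (backbone already applied for genomic inputs).
#' @param mode `"rpr"` (neighbor-set weights, the default) or `"constant"`.
#' @param constant_value Edge weight used in `"constant"` mode.
#' @return An `igraph` undirected graph with edge attribute `weight` and
#'   graph attribute `mode`; vertices are matrix indices.
#' @export
build_graph <- function(R, mode = c("rpr", "constant"), constant_value = 1) {
  mode <- match.arg(mode)
  m <- if (inherits(R, "contact_map")) R$R else R
  n <- nrow(m)
  ut <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
  if (mode == "rpr" && nrow(ut) > 0) {
    # Jaccard weights for all edges at once: crossprod gives |Gi ∩ Gj|
    M <- (m == 1) * 1
    sizes <- colSums(M)
    inter <- crossprod(M)[ut]
    uni <- sizes[ut[, 1]] + sizes[ut[, 2]] - inter
    w <- (uni - inter) / uni
  } else {
    if (!is.numeric(constant_value) || constant_value <= 0) {
      rlang::abort("`constant_value` must be positive.")
    }
    w <- rep(constant_value, nrow(ut))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ut) > 0) {
    g <- igraph::add_edges(g, rbind(ut[, 1], ut[, 2]), weight = w)
  }
  g <- igraph::set_graph_attr(g, "mode", mode)
  g
}

#' All-pairs shortest-path distances (metric completion)
#'
#' Completes the local edge weights into a global metric: the distance between
#' any two nodes is the length of the shortest path between them. With
#' non-negative weights, Dijkstra and Johnson produce identical matrices;
#' Johnson is faster on large sparse graphs.
#'
#' @param G An `igraph` graph with non-negative edge weights.
#' @param algorithm `"auto"` (Johnson above 2000 nodes, Dijkstra otherwise),
#'   `"dijkstra"` or `"johnson"`.
#' @return Symmetric numeric matrix of shortest-path distances, zero diagonal.
#' @export
all_pairs_shortest <- function(G, algorithm = c("auto", "dijkstra", "johnson")) {
  algorithm <- match.arg(algorithm)
  w <- igraph::E(G)$weight
  if (!is.null(w) && any(w < 0)) rlang::abort("Edge weights must be non-negative.")
  comp <- igraph::components(G)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    rlang::abort(sprintf(
      paste0("Graph is disconnected (%d components of sizes %s): every pair ",
             "of nodes must be joined by a path. Reconstruct per component ",
             "or per chromosome, or add backbone contacts."),
      comp$no, sizes))
  }
  if (algorithm == "auto") {
    algorithm <- if (igraph::vcount(G) > 2000) "johnson" else "dijkstra"
  }
  D <- igraph::distances(G, algorithm = algorithm)
  dimnames(D) <- NULL
  D
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances, B = -1/2 J D^2 J, eigendecomposes B,
#' and returns the configuration spanned by the `ndim` largest positive
#' eigenvalues, each eigenvector scaled by the square root of its eigenvalue.
#' Negative eigenvalues (non-Euclidean parts of D) are never selected; if
#' fewer than `ndim` positive eigenvalues exist, the remaining coordinates
#' are zero-padded with a warning. Each axis is sign-canonicalized (the entry
#' of largest magnitude is made positive) so that identical inputs yield
#' byte-identical coordinates.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param ndim Number of embedding dimensions (default 3).
#' @param bins Optional `genomic_bins` table carried into the result.
#' @return An `rpr_structure`: list with `coordinates` (n x ndim matrix),
#'   `eigenvalues` (the `ndim` retained eigenvalues, descending), `bins`.
#' @export
classical_mds <- function(D, ndim = 3, bins = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || !isSymmetric(unname(D), tol = 1e-8)) {
    rlang::abort("`D` must be a symmetric square matrix.")
  }
  if (!is.numeric(ndim) || ndim < 1 || ndim != round(ndim)) {
    rlang::abort("`ndim` must be a positive integer.")
  }
  D2 <- D^2
  B <- -0.5 * (D2 - outer(rowMeans(D2), colMeans(D2), `+`) + mean(D2))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)   # eigenvalues descending
  pos <- which(e$values > max(e$values[1], 0) * .Machine$double.eps * n)
  k <- min(ndim, length(pos))
  X <- matrix(0, n, ndim)
  lambda <- numeric(ndim)
  if (k > 0) {
    X[, seq_len(k)] <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(e$values[pos[seq_len(k)]]), k)
    lambda[seq_len(k)] <- e$values[pos[seq_len(k)]]
  }
  if (k < ndim) {
    rlang::warn(sprintf(
      "Only %d positive eigenvalue(s); %d coordinate axis/axes zero-padded.",
      k, ndim - k))
  }
  # sign canonicalization: largest-magnitude entry of each axis made positive
  for (d in seq_len(ndim)) {
    im <- which.max(abs(X[, d]))
    if (length(im) == 1 && X[im, d] < 0) X[, d] <- -X[, d]
  }
  X <- sweep(X, 2, colMeans(X))   # re-center (numerical hygiene)
  new_rpr_structure(X, eigenvalues = lambda, bins = bins)
}

new_rpr_structure <- function(coordinates, eigenvalues, bins = NULL,
                              distances = NULL, params = list()) {
  colnames(coordinates) <- c("x", "y", "z", paste0("dim", seq_len(max(
    0, ncol(coordinates) - 3)) + 3))[seq_len(ncol(coordinates))]
  structure(list(coordinates = coordinates,
                 eigenvalues = eigenvalues,
                 bins = bins,
                 distances = distances,
                 params = params),
            class = "rpr_structure")
}

#' Reconstruct a 3D structure from a contact map
#'
#' The full recurrence-plot-based reconstruction (RPR) pipeline:
#' binarize, add chromosome backbone contacts (genomic maps), assign
#' neighbor-set local distances to contact edges, complete the metric by
#' all-pairs shortest paths, and embed with classical MDS keeping the three
#' largest eigenvalue components. The pipeline is fully deterministic:
#' identical inputs give byte-identical structures.
#'
#' @param map A `contact_map` (or count matrix, binarized on entry).
#' @param mode `"rpr"` (neighbor-set edge weights) or `"constant"`.
#' @param algorithm Shortest-path algorithm: `"auto"`, `"dijkstra"`, `"johnson"`.
#' @param ndim Embedding dimension (default 3).
#' @param backbone Add backbone contacts first when a bin table is present
#'   (default `TRUE`).
#' @param constant_value Edge weight for `"constant"` mode.
#' @return An `rpr_structure` with `coordinates`, `eigenvalues`, `bins`,
#'   the global `distances` matrix, and the `params` used.
#' @export
reconstruct <- function(map, mode = c("rpr", "constant"),
                        algorithm = c("auto", "dijkstra", "johnson"),
                        ndim = 3, backbone = TRUE, constant_value = 1) {
  mode <- match.arg(mode)
  algorithm <- match.arg(algorithm)
  map <- binarize(map)
  if (backbone && !is.null(map$bins)) map <- add_backbone(map)
  G <- build_graph(map, mode = mode, constant_value = constant_value)
  D <- all_pairs_shortest(G, algorithm = algorithm)
  s <- classical_mds(D, ndim = ndim, bins = map$bins)
  s$distances <- D
  s$params <- list(mode = mode, algorithm = algorithm, ndim = ndim,
                   backbone = backbone, constant_value = constant_value)
  s
}

#' @export
print.rpr_structure <- function(x, ...) {
  cat(sprintf("RPR structure: %d points in %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  ev <- x$eigenvalues
  if (length(ev) > 0 && any(is.finite(ev))) {
    cat("Retained MDS eigenvalues:",
        paste(signif(ev, 5), collapse = ", "), "\n")
  }
  if (!is.null(x$bins)) {
    cat(sprintf("Anchored to %d genomic bins at %s bp resolution\n",
                nrow(x$bins),
                format(bin_resolution(x$bins), big.mark = ",")))
  }
  invisible(x)
}

#' Tidy a reconstructed structure into a tibble
#'
#' @param x An `rpr_structure`.
#' @param ... Unused.
#' @return A tibble with one row per bin/point: `bin` index, genomic columns
#'   (`chrom`, `start`, `end`) when a bin table is present, and coordinates.
#' @export
tidy.rpr_structure <- function(x, ...) {
  out <- tibble::as_tibble(x$coordinates)
  out <- dplyr::bind_cols(tibble::tibble(bin = seq_len(nrow(out))), out)
  if (!is.null(x$bins)) {
    out <- dplyr::bind_cols(
      tibble::as_tibble(x$bins)[c("chrom", "start", "end")], out)
  }
  out
}

#' One-row summary of a reconstructed structure
#'
#' @param x An `rpr_structure`.
#' @param ... Unused.
#' @return A tibble with point count, embedding dimension, retained
#'   eigenvalues, and the radius of gyration of the configuration.
#' @export
glance.rpr_structure <- function(x, ...) {
  X <- x$coordinates
  rg <- sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  ev <- x$eigenvalues
  tibble::tibble(n = nrow(X), ndim = ncol(X),
                 lambda1 = ev[1], lambda2 = ev[2], lambda3 = ev[3],
                 radius_of_gyration = rg)
}

#' Plot a reconstructed structure
#'
#' Projection onto the two leading MDS axes, points joined in bin order and
#' colored by position along the chromosome/trajectory.
#'
#' @param object An `rpr_structure`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rpr_structure <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$bin)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "bin") +
    ggplot2::theme_minimal()
}
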