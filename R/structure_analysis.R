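#' Procrustes superposition of two point configurations
#'
#' Least-squares superposition of configuration `B` onto `A` over translations
#' and rotations, optionally allowing reflection and isotropic scaling
#' (MDS output is defined only up to such transforms). Solved by SVD of the
#' cross-covariance (Kabsch); when reflection is disallowed the determinant of
#' the rotation is constrained to +1.
#'
#' @param A,B `rpr_structure`s or n x d coordinate matrices with equal n.
#' @param allow_reflection Allow an improper rotation (default `TRUE`).
#' @param allow_scale Fit an isotropic scale factor (default `FALSE`).
#' @return An `rpr_alignment`: list with `rotation` (d x d orthogonal),
#'   `translation` (length d), `scale`, `rmsd`, and `B_aligned`, such that
#'   `B_aligned = scale * B %*% rotation + translation` superposes onto `A`.
#' @export
procrustes_align <- function(A, B, allow_reflection = TRUE,
                             allow_scale = FALSE) {
  A <- trajectory_coords(A)
  B <- trajectory_coords(B)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B)) {
    rlang::abort(sprintf("Configurations differ in shape: %d x %d vs %d x %d.",
                         nrow(A), ncol(A), nrow(B), ncol(B)))
  }
  if (nrow(A) < 3) rlang::abort("Need at least 3 points to align.")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))
  R <- s$u %*% t(s$v)
  d_sign <- rep(1, ncol(A))
  if (!allow_reflection && det(R) < 0) {
    d_sign[ncol(A)] <- -1
    R <- s$u %*% diag(d_sign) %*% t(s$v)
  }
  trace_term <- sum(s$d * d_sign)
  scale <- if (allow_scale) trace_term / sum(B0^2) else 1
  Bfit <- sweep(scale * B0 %*% R, 2, ca, `+`)
  rmsd <- sqrt(mean(rowSums((A - Bfit)^2)))
  structure(list(rotation = R, translation = ca - scale * drop(cb %*% R),
                 scale = scale, rmsd = rmsd, B_aligned = Bfit),
            class = "rpr_alignment")
}

#' @export
print.rpr_alignment <- function(x, ...) {
  cat(sprintf("Procrustes alignment: rmsd = %.6g, scale = %.6g, det(R) = %+d\n",
              x$rmsd, x$scale, round(det(x$rotation))))
  invisible(x)
}

#' Pearson correlation between two distance matrices
#'
#' Computed over strictly upper-triangle entries; the statistic the method
#' uses to compare reconstructions of the same chromosome across cells.
#'
#' @param D1,D2 Square symmetric matrices of equal dimension (plain matrices
#'   or the `distances` field of an `rpr_structure`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A correlation coefficient in \[-1, 1\].
#' @export
distance_matrix_correlation <- function(D1, D2, method = "pearson") {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) {
    rlang::abort("Distance matrices must have equal dimensions.")
  }
  v1 <- D1[upper.tri(D1)]; v2 <- D2[upper.tri(D2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    rlang::abort("Correlation undefined: a distance matrix is constant.")
  }
  stats::cor(v1, v2, method = method)
}

#' Cross-resolution consistency of reconstructed distances
#'
#' Block-averages the fine distance matrix (`factor` x `factor` blocks of
#' consecutive bins) down to the coarse shape, then computes the Pearson
#' correlation with the coarse matrix over the strict upper triangle
#' (diagonal blocks are excluded by the triangle).
#'
#' @param D_fine,D_coarse Distance matrices at fine and coarse binning.
#' @param factor Integer binning ratio (fine bins per coarse bin).
#' @param method `"pearson"` or `"spearman"`.
#' @return A correlation coefficient.
#' @export
cross_resolution_correlation <- function(D_fine, D_coarse, factor,
                                         method = "pearson") {
  D_fine <- as.matrix(D_fine); D_coarse <- as.matrix(D_coarse)
  nf <- nrow(D_fine); nc <- nrow(D_coarse)
  if (ceiling(nf / factor) != nc) {
    rlang::abort(sprintf(
      "Incompatible shapes: %d fine bins / factor %d != %d coarse bins.",
      nf, factor, nc))
  }
  grp <- (seq_len(nf) - 1L) %/% as.integer(factor) + 1L
  P <- matrix(0, nf, nc)
  P[cbind(seq_len(nf), grp)] <- 1
  Dc <- crossprod(P, D_fine %*% P) / outer(colSums(P), colSums(P))
  distance_matrix_correlation(Dc, D_coarse, method = method)
}

#' Windowed local 3D correlation between two structures
#'
#' Slides a genomic window (default 1 Mb) along the shared bin table and, for
#' each window, computes the Pearson correlation between the intra-window
#' pairwise-distance vectors of the two structures. Being built on pairwise
#' distances, the profile is invariant to rigid motion and reflection of
#' either structure, so no alignment is needed.
#'
#' @param S1,S2 `rpr_structure`s with identical bin tables.
#' @param window_bp Window length in base pairs (default 1e6).
#' @param stride_bp Distance between window starts; defaults to `window_bp`
#'   (non-overlapping windows).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `similarity_profile`: tibble with `chrom`, `window_center` (bp)
#'   and `correlation`, plus attributes `mean` and `sigma`.
#' @export
local_3d_correlation <- function(S1, S2, window_bp = 1e6,
                                 stride_bp = window_bp, method = "pearson") {
  stopifnot(inherits(S1, "rpr_structure"), inherits(S2, "rpr_structure"))
  if (is.null(S1$bins) || is.null(S2$bins)) {
    rlang::abort("Both structures need bin tables.")
  }
  if (!identical(tibble::as_tibble(S1$bins)[c("chrom", "start", "end")],
                 tibble::as_tibble(S2$bins)[c("chrom", "start", "end")])) {
    rlang::abort("Structures must share one bin table.")
  }
  bins <- S1$bins
  res <- bin_resolution(bins)
  if (window_bp < 3 * res) {
    rlang::abort("`window_bp` must span at least 3 bins.")
  }
  rows <- list()
  for (cn in unique(bins$chrom)) {
    idx <- which(bins$chrom == cn)
    cmax <- max(bins$end[idx])
    starts <- seq(0, max(0, cmax - 1), by = stride_bp)
    for (ws in starts) {
      we <- ws + window_bp
      in_w <- idx[bins$start[idx] >= ws & bins$end[idx] <= we]
      if (length(in_w) < 3) next
      d1 <- stats::dist(S1$coordinates[in_w, , drop = FALSE])
      d2 <- stats::dist(S2$coordinates[in_w, , drop = FALSE])
      r <- if (stats::sd(d1) == 0 || stats::sd(d2) == 0) NA_real_ else
        stats::cor(as.vector(d1), as.vector(d2), method = method)
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = cn, window_center = (ws + min(we, cmax)) / 2, correlation = r)
    }
  }
  if (length(rows) == 0) rlang::abort("No window contains 3 or more bins.")
  out <- dplyr::bind_rows(rows)
  attr(out, "mean") <- mean(out$correlation, na.rm = TRUE)
  attr(out, "sigma") <- stats::sd(out$correlation, na.rm = TRUE)
  class(out) <- c("similarity_profile", class(out))
  out
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf(
    "Local 3D similarity profile: %d windows, mean r = %.4f (sigma %.4f)\n",
    nrow(x), attr(x, "mean"), attr(x, "sigma")))
  NextMethod()
}

#' Plot a local-similarity profile
#'
#' @param object A `similarity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$window_center / 1e6, .data$correlation)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Local 3D correlation") +
    ggplot2::theme_minimal()
}

#' Radial profile of a structure
#'
#' Euclidean distance of each bin from the configuration centroid — how far
#' each chromosome segment protrudes from the body of the structure (open
#' loops and telomeres stand out as peaks).
#'
#' @param S An `rpr_structure` or coordinate matrix.
#' @return A tibble with `bin`, genomic columns when available, and `radius`.
#' @export
radial_profile <- function(S) {
  X <- trajectory_coords(S)
  r <- sqrt(rowSums(sweep(X, 2, colMeans(X))^2))
  out <- tibble::tibble(bin = seq_along(r), radius = r)
  if (inherits(S, "rpr_structure") && !is.null(S$bins)) {
    out <- dplyr::bind_cols(
      tibble::as_tibble(S$bins)[c("chrom", "start", "end")], out)
  }
  out
}

#' Hierarchical clustering of cells by structural similarity
#'
#' Clusters cells on the dissimilarity 1 - correlation derived from a
#' symmetric table of pairwise mean local-structure correlations, showing
#' which cell's chromosome structure is most similar to which.
#'
#' @param similarity Symmetric numeric matrix of pairwise correlations with
#'   unit diagonal; row/column names label the cells.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An `hclust` tree.
#' @export
cell_similarity_dendrogram <- function(similarity,
                                       linkage = c("average", "complete",
                                                   "single")) {
  linkage <- match.arg(linkage)
  similarity <- as.matrix(similarity)
  if (nrow(similarity) != ncol(similarity) ||
      !isSymmetric(unname(similarity), tol = 1e-10)) {
    rlang::abort("`similarity` must be a symmetric square matrix.")
  }
  if (any(abs(diag(similarity) - 1) > 1e-8)) {
    rlang::abort("`similarity` must have unit diagonal.")
  }
  if (is.null(rownames(similarity))) {
    rownames(similarity) <- colnames(similarity) <-
      paste0("cell", seq_len(nrow(similarity)))
  }
  stats::hclust(stats::as.dist(1 - similarity), method = linkage)
}

#' Serialize a dendrogram as Newick
#'
#' @param tree An `hclust` tree (e.g. from [cell_similarity_dendrogram()]).
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
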