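#' Binary contact map / recurrence matrix
#'
#' A `contact_map` is the package's shared abstraction for a Hi-C contact map
#' and a recurrence plot: a square, symmetric, binary matrix `R` with unit
#' diagonal (a state is always close to itself), optionally anchored to
#' genomic coordinates through a [make_bins()] table.
#'
#' @param R Square symmetric matrix with entries in \{0, 1\}.
#' @param bins Optional `genomic_bins` table with one row per matrix row.
#' @return An object of class `contact_map`: a list with elements `R`
#'   (integer matrix) and `bins`.
#' @export
contact_map <- function(R, bins = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) rlang::abort("Contact matrix must be square.")
  if (!isSymmetric(unname(R))) rlang::abort("Contact matrix must be symmetric.")
  if (any(!R %in% c(0, 1))) {
    rlang::abort("Contact matrix entries must be 0 or 1 (use binarize() for counts).")
  }
  storage.mode(R) <- "integer"
  diag(R) <- 1L
  dimnames(R) <- NULL
  if (!is.null(bins)) {
    if (!inherits(bins, "genomic_bins")) {
      rlang::abort("`bins` must be a genomic_bins table (see make_bins()).")
    }
    if (nrow(bins) != nrow(R)) {
      rlang::abort(sprintf("Bin table has %d rows but matrix is %d x %d.",
                           nrow(bins), nrow(R), nrow(R)))
    }
  }
  structure(list(R = R, bins = bins), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$R)
  dens <- if (n > 1) {
    sum(x$R[upper.tri(x$R)]) / (n * (n - 1) / 2)
  } else 0
  cat(sprintf("Contact map: %d x %d, off-diagonal contact density %.4f%s\n",
              n, n, dens,
              if (is.null(x$bins)) "" else
                sprintf(", %d chromosome(s)", length(unique(x$bins$chrom)))))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$R)

n_bins <- function(map) nrow(map$R)

#' Binarize a count matrix into a contact map
#'
#' Implements the universal binarization rule of the recurrence-plot view of
#' Hi-C: two segments detected as neighbors at least once get a 1, everything
#' else a 0. No read-count threshold is involved, so the same rule serves
#' single-cell and ensemble Hi-C. The diagonal is always 1. Idempotent.
#'
#' @param counts Square symmetric non-negative matrix (raw counts or already
#'   binary), or a `contact_map`.
#' @param bins Optional `genomic_bins` table attached to the result.
#' @return A `contact_map`.
#' @export
binarize <- function(counts, bins = NULL) {
  if (inherits(counts, "contact_map")) {
    if (is.null(bins)) bins <- counts$bins
    counts <- counts$R
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || !isSymmetric(unname(counts))) {
    rlang::abort("`counts` must be a square symmetric matrix.")
  }
  if (any(counts < 0)) rlang::abort("`counts` must be non-negative.")
  contact_map((counts > 0) * 1L, bins = bins)
}

#' Add chromosome backbone contacts
#'
#' Declares consecutive bins on the same chromosome to be neighbors:
#' R(i, i+1) = R(i+1, i) = 1. This guarantees that, within each chromosome,
#' the contact graph is connected — the necessary condition for shortest-path
#' metric completion. No edge is added across a chromosome boundary.
#' Idempotent.
#'
#' @param map A `contact_map` with a bin table.
#' @return A `contact_map` with backbone contacts set.
#' @export
add_backbone <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(map$bins)) {
    rlang::abort("add_backbone() needs a bin table to know chromosome boundaries.")
  }
  R <- map$R
  n <- nrow(R)
  if (n > 1) {
    same <- map$bins$chrom[-n] == map$bins$chrom[-1]
    i <- which(same)
    R[cbind(i, i + 1L)] <- 1L
    R[cbind(i + 1L, i)] <- 1L
  }
  contact_map(R, bins = map$bins)
}

#' Restrict a contact map to one chromosome
#'
#' @param map A `contact_map` with a bin table.
#' @param chromosome Chromosome name present in the bin table.
#' @return The intra-chromosomal `contact_map` for that chromosome.
#' @export
extract_region <- function(map, chromosome) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(map$bins)) rlang::abort("extract_region() needs a bin table.")
  rows <- which(map$bins$chrom == chromosome)
  if (length(rows) == 0) {
    rlang::abort(sprintf("Chromosome '%s' is not in the bin table.", chromosome))
  }
  sub_bins <- new_genomic_bins(tibble::as_tibble(map$bins)[rows, ],
                               resolution = bin_resolution(map$bins),
                               chrom_levels = chromosome)
  contact_map(map$R[rows, rows, drop = FALSE], bins = sub_bins)
}

#' Coarsen a contact map to a lower resolution
#'
#' Aggregates `factor` consecutive fine bins of one chromosome into one coarse
#' bin (the last group of a chromosome may be shorter). A coarse cell is the
#' logical OR of all fine cells in its block, preserving the
#' detected-at-least-once semantics of the binary map.
#'
#' @param map A `contact_map` with a bin table.
#' @param factor Positive integer aggregation factor.
#' @return A `contact_map` at `resolution * factor`.
#' @export
coarsen <- function(map, factor) {
  stopifnot(inherits(map, "contact_map"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    rlang::abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(map)
  if (is.null(map$bins)) rlang::abort("coarsen() needs a bin table.")
  bins <- map$bins
  # group id: consecutive runs of `factor` bins within each chromosome
  grp <- integer(nrow(bins))
  gid <- 0L
  for (cn in unique(bins$chrom)) {
    rows <- which(bins$chrom == cn)
    g <- (seq_along(rows) - 1L) %/% factor
    grp[rows] <- gid + g + 1L
    gid <- gid + max(g) + 1L
  }
  ng <- gid
  # indicator matrix bins x groups, coarse = (t(P) R P) > 0
  P <- matrix(0L, nrow(bins), ng)
  P[cbind(seq_len(nrow(bins)), grp)] <- 1L
  Rc <- (t(P) %*% map$R %*% P > 0) * 1L
  coarse_bins <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(bins)[c("chrom", "start", "end")] |>
                      dplyr::mutate(.grp = grp), .data$.grp),
    chrom = dplyr::first(.data$chrom),
    start = min(.data$start), end = max(.data$end), .groups = "drop")
  coarse_bins <- coarse_bins[order(coarse_bins$.grp), c("chrom", "start", "end")]
  contact_map(Rc, bins = new_genomic_bins(
    coarse_bins, resolution = bin_resolution(bins) * factor,
    chrom_levels = attr(bins, "chrom_levels")))
}

#' Read pairwise contacts into a contact map
#'
#' Reads a pairs-style text file (4DN `.pairs`-compatible columns
#' `chrom1 pos1 chrom2 pos2 [count]`, whitespace- or tab-separated, lines
#' starting with `#` ignored) and records each contact symmetrically in the
#' bins containing the two positions. Any record (or positive count) sets the
#' cell to 1; duplicates are harmless. Positions are 0-based.
#'
#' @param path Path to the pairs file.
#' @param bins A `genomic_bins` table defining the matrix indexing.
#' @return A `contact_map` over `bins`.
#' @export
read_pairs <- function(path, bins) {
  stopifnot(inherits(bins, "genomic_bins"))
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  n <- nrow(bins)
  R <- diag(1L, n)
  if (length(keep) > 0) {
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    nf <- lengths(fields)
    bad <- which(nf < 4)
    if (length(bad) > 0) {
      rlang::abort(sprintf("Line %d: expected at least 4 fields, found %d.",
                           keep[bad[1]], nf[bad[1]]))
    }
    c1 <- vapply(fields, `[[`, "", 1)
    p1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
    c2 <- vapply(fields, `[[`, "", 3)
    p2 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
    cnt <- rep(1, length(keep))
    has5 <- nf >= 5
    cnt[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[[`, "", 5)))
    bad <- which(!is.finite(p1) | !is.finite(p2) | !is.finite(cnt) | cnt < 0)
    if (length(bad) > 0) {
      rlang::abort(sprintf("Line %d: malformed record '%s'.",
                           keep[bad[1]], lines[keep[bad[1]]]))
    }
    unknown <- which(!(c1 %in% bins$chrom) | !(c2 %in% bins$chrom))
    if (length(unknown) > 0) {
      rlang::abort(sprintf("Line %d: unknown chromosome in record '%s'.",
                           keep[unknown[1]], lines[keep[unknown[1]]]))
    }
    i <- bin_index(bins, c1, p1)
    j <- bin_index(bins, c2, p2)
    bad <- which(is.na(i) | is.na(j))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "Line %d: position outside chromosome bounds in record '%s'.",
        keep[bad[1]], lines[keep[bad[1]]]))
    }
    pos <- cnt > 0
    R[cbind(i[pos], j[pos])] <- 1L
    R[cbind(j[pos], i[pos])] <- 1L
  }
  contact_map(R, bins = bins)
}

#' Read / write a dense contact matrix as TSV
#'
#' Plain tab-separated numeric matrix, no row or column names.
#'
#' @param path File path.
#' @param bins Optional `genomic_bins` table for the rows.
#' @return `read_matrix_tsv()` returns a `contact_map` (values are binarized).
#' @export
read_matrix_tsv <- function(path, bins = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  binarize(m, bins = bins)
}

#' @param map A `contact_map` (or plain matrix for `write_matrix_tsv`).
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(map, path) {
  m <- if (inherits(map, "contact_map")) map$R else as.matrix(map)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop bins with no informative contacts
#'
#' Removes bins whose only contacts are the diagonal (zero-coverage bins),
#' together with their rows/columns. By default the reconstruction keeps all
#' bins and relies on backbone edges to bridge them; this helper implements
#' the alternative.
#'
#' @param map A `contact_map`.
#' @return A `contact_map` without all-zero bins.
#' @export
drop_empty_bins <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  deg <- rowSums(map$R) - 1L
  keep <- which(deg > 0)
  if (length(keep) == nrow(map$R)) return(map)
  if (length(keep) == 0) rlang::abort("All bins are empty.")
  bins <- map$bins
  if (!is.null(bins)) {
    bins <- new_genomic_bins(tibble::as_tibble(bins)[keep, ],
                             resolution = bin_resolution(bins),
                             chrom_levels = attr(bins, "chrom_levels"))
  }
  contact_map(map$R[keep, keep, drop = FALSE], bins = bins)
}

#' Heat-map display of a contact map
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$R)),
                           j = seq_len(ncol(object$R)))
  df$value <- as.vector(object$R)
  ggplot2::ggplot(df[df$value == 1, ], ggplot2::aes(.data$i, .data$j)) +
    ggplot2::geom_raster(fill = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}
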