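#' Write / read a reconstructed structure as TSV
#'
#' Tab-separated table with columns `chrom`, `start`, `end` (when a bin table
#' is present), `bin`, `x`, `y`, `z`. Retained MDS eigenvalues are stored in
#' `# eigenvalues:` header comments and restored on read.
#'
#' @param S An `rpr_structure`.
#' @param path File path.
#' @return `read_structure_tsv()` returns an `rpr_structure`.
#' @export
write_structure_tsv <- function(S, path) {
  stopifnot(inherits(S, "rpr_structure"))
  df <- tidy(S)
  header <- sprintf("# eigenvalues: %s",
                    paste(format(S$eigenvalues, digits = 17), collapse = "\t"))
  readr::write_lines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_structure_tsv
#' @export
read_structure_tsv <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  ev <- rep(NA_real_, 3)
  skip <- 0
  if (startsWith(first, "# eigenvalues:")) {
    fields <- strsplit(sub("^# eigenvalues:\\s*", "", first), "\t")[[1]]
    ev <- suppressWarnings(as.numeric(fields))   # "NA" for generated curves
    skip <- 1
  }
  df <- readr::read_tsv(path, skip = skip, col_types = readr::cols(),
                        progress = FALSE)
  coord_cols <- intersect(c("x", "y", "z"), names(df))
  X <- as.matrix(df[coord_cols])
  bins <- NULL
  if (all(c("chrom", "start", "end") %in% names(df))) {
    widths <- df$end - df$start
    res <- as.numeric(names(sort(table(widths), decreasing = TRUE))[1])
    bins <- new_genomic_bins(df[c("chrom", "start", "end")], resolution = res,
                             chrom_levels = unique(df$chrom))
  }
  new_rpr_structure(X, eigenvalues = ev, bins = bins)
}

#' Write a structure as a PDB pseudo-molecule
#'
#' One CA pseudo-atom per bin, one chain per chromosome, consecutive bins of a
#' chain joined by CONECT records, for inspection in molecular viewers.
#' Coordinates are rescaled so the structure's radius of gyration is ~20
#' Angstrom-equivalents (PDB columns are fixed-width).
#'
#' @param S An `rpr_structure`.
#' @param path Output path.
#' @export
write_structure_pdb <- function(S, path) {
  stopifnot(inherits(S, "rpr_structure"))
  X <- S$coordinates[, 1:3, drop = FALSE]
  rg <- sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  if (rg > 0) X <- X * (20 / rg)
  chroms <- if (is.null(S$bins)) rep("A", nrow(X)) else S$bins$chrom
  chain_ids <- c(LETTERS, letters, 0:9)
  chain <- chain_ids[pmin(as.integer(factor(chroms, levels = unique(chroms))),
                          length(chain_ids))]
  lines <- character(0)
  for (i in seq_len(nrow(X))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i %% 100000, chain[i], i %% 10000, X[i, 1], X[i, 2], X[i, 3]))
  }
  for (i in seq_len(nrow(X) - 1)) {
    if (chain[i] == chain[i + 1]) {
      lines <- c(lines, sprintf("CONECT%5d%5d", i, i + 1))
    }
  }
  lines <- c(lines, "END")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param D Square numeric matrix (e.g. the `distances` field of an
#'   `rpr_structure`).
#' @param path Output path.
#' @export
write_distance_tsv <- function(D, path) {
  write_matrix_tsv(as.matrix(D), path)
}
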