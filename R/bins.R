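#' Partition a genome into fixed-width bins
#'
#' Tiles every chromosome with contiguous, non-overlapping bins of width
#' `resolution` (0-based, half-open, BED convention). The last bin of a
#' chromosome is truncated to the chromosome end, so every base is covered
#' exactly once. The bin table anchors the row/column index of a contact
#' matrix to genomic coordinates.
#'
#' @param chrom_sizes Named numeric vector or list mapping chromosome name to
#'   its length in base pairs.
#' @param resolution Bin width in base pairs.
#'
#' @return A tibble of class `genomic_bins` with columns `chrom`, `start`,
#'   `end` and attribute `resolution`. Row order is chromosome order as given,
#'   then `start`.
#' @examples
#' make_bins(c(X = 1000), 250)
#' @export
make_bins <- function(chrom_sizes, resolution) {
  chrom_sizes <- unlist(chrom_sizes)
  if (length(chrom_sizes) == 0) {
    rlang::abort("`chrom_sizes` must name at least one chromosome.")
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    rlang::abort("`chrom_sizes` must be named by chromosome.")
  }
  if (!is.numeric(resolution) || length(resolution) != 1 ||
      !is.finite(resolution) || resolution <= 0) {
    rlang::abort("`resolution` must be a single positive number of base pairs.")
  }
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    rlang::abort("All chromosome lengths must be positive.")
  }
  bins <- purrr::map2_dfr(names(chrom_sizes), chrom_sizes, function(chrom, len) {
    starts <- seq(0, len - 1, by = resolution)
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + resolution, len))
  })
  new_genomic_bins(bins, resolution = resolution,
                   chrom_levels = names(chrom_sizes))
}

new_genomic_bins <- function(bins, resolution, chrom_levels = unique(bins$chrom)) {
  bins <- tibble::as_tibble(bins[c("chrom", "start", "end")])
  bins$chrom <- as.character(bins$chrom)
  attr(bins, "resolution") <- as.numeric(resolution)
  attr(bins, "chrom_levels") <- chrom_levels
  class(bins) <- c("genomic_bins", class(tibble::tibble()))
  bins
}

#' @export
print.genomic_bins <- function(x, ...) {
  cat(sprintf("Genomic bins: %d bins on %d chromosome(s) at %s bp resolution\n",
              nrow(x), length(unique(x$chrom)),
              format(attr(x, "resolution"), big.mark = ",")))
  NextMethod()
}

bin_resolution <- function(bins) attr(bins, "resolution")

#' Locate the bin containing a genomic position
#'
#' @param bins A `genomic_bins` table.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s) in base pairs.
#' @return Integer bin indices (1-based rows of `bins`); `NA` where the
#'   position falls outside the table.
#' @keywords internal
bin_index <- function(bins, chrom, pos) {
  res <- bin_resolution(bins)
  idx <- rep(NA_integer_, length(chrom))
  for (cn in unique(chrom)) {
    rows <- which(bins$chrom == cn)
    if (length(rows) == 0) next
    sel <- chrom == cn
    within <- pos[sel] >= 0 & pos[sel] < max(bins$end[rows])
    off <- floor(pos[sel] / res) + 1L
    val <- ifelse(within & off <= length(rows), rows[pmin(off, length(rows))],
                  NA_integer_)
    idx[sel] <- val
  }
  idx
}

#' Read / write a bin table as BED
#'
#' Three-column BED (chrom, start, end), 0-based half-open, tab-separated,
#' no header. The resolution is inferred as the modal bin width.
#'
#' @param path File path.
#' @return `read_bins_bed()` returns a `genomic_bins` table.
#' @export
read_bins_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                        col_types = "cdd", comment = "#", progress = FALSE)
  if (nrow(df) == 0) rlang::abort(sprintf("No bins in '%s'.", path))
  widths <- df$end - df$start
  res <- as.numeric(names(sort(table(widths), decreasing = TRUE))[1])
  new_genomic_bins(df, resolution = res, chrom_levels = unique(df$chrom))
}

#' @param bins A `genomic_bins` table.
#' @rdname read_bins_bed
#' @export
write_bins_bed <- function(bins, path) {
  readr::write_tsv(tibble::as_tibble(bins)[c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
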