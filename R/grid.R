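#' Tile a genome into fixed-width bins
#'
#' Builds a `bin_grid`, the binning substrate shared by binarized tracks,
#' segmentations and methylation tracks. Bins tile each chromosome from 0 in
#' steps of `bin_size`; the final bin of a chromosome may be shorter than
#' `bin_size`. All coordinates in the package are 0-based half-open.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 200, the convention of
#'   segmentation tools for histone-mark tracks).
#' @return an object of class `bin_grid` with fields `chrom_sizes`,
#'   `bin_size`, `n_bins` (per chromosome) and `total_bins`.
#' @examples
#' bin_genome(c(chr1 = 1000, chr2 = 1001), bin_size = 200)
#' @export
bin_genome <- function(chrom_sizes, bin_size = 200L) {
  if (length(chrom_sizes) == 0L) stop("chrom_sizes must be non-empty")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes < 1)) stop("all chromosome lengths must be >= 1")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop("bin_size must be >= 1")
  n_bins <- as.integer(ceiling(chrom_sizes / bin_size))
  names(n_bins) <- names(chrom_sizes)
  structure(
    list(chrom_sizes = chrom_sizes, bin_size = bin_size,
         n_bins = n_bins, total_bins = sum(n_bins)),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d chromosome(s), bin size %d bp, %d bins\n",
              length(x$chrom_sizes), x$bin_size, x$total_bins))
  invisible(x)
}

#' Bins of a grid as a GRanges
#'
#' @param grid a `bin_grid`.
#' @return a [GenomicRanges::GRanges] with one range per bin, in grid order
#'   (chromosomes in `chrom_sizes` order, bins left to right). Ranges are
#'   1-based closed as usual for GRanges; the grid itself is 0-based
#'   half-open.
#' @export
grid_bins <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  chroms <- rep(names(grid$chrom_sizes), grid$n_bins)
  start0 <- unlist(lapply(seq_along(grid$chrom_sizes), function(i) {
    seq_len(grid$n_bins[i]) - 1L
  }), use.names = FALSE) * grid$bin_size
  end0 <- pmin(start0 + grid$bin_size,
               rep(unname(grid$chrom_sizes), grid$n_bins))
  GenomicRanges::GRanges(chroms, IRanges::IRanges(start0 + 1L, end0),
                         seqlengths = grid$chrom_sizes)
}

# widths of every bin, in grid order (last bin per chromosome may be short)
grid_bin_widths <- function(grid) {
  w <- rep(grid$bin_size, grid$total_bins)
  offs <- cumsum(grid$n_bins)
  rem <- grid$chrom_sizes - (grid$n_bins - 1L) * grid$bin_size
  w[offs] <- rem
  w
}

# per-chromosome index offsets into the flat bin vector
grid_offsets <- function(grid) {
  c(0L, cumsum(unname(grid$n_bins))[-length(grid$n_bins)])
}

#' Map genomic positions to flat bin indices
#'
#' @param grid a `bin_grid`.
#' @param chrom character vector of chromosome names.
#' @param pos 0-based bp positions.
#' @return 1-based indices into the flat bin vector of the grid.
#' @export
grid_bin_index <- function(grid, chrom, pos) {
  stopifnot(inherits(grid, "bin_grid"))
  ci <- match(chrom, names(grid$chrom_sizes))
  if (anyNA(ci)) {
    bad <- unique(chrom[is.na(ci)])
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (any(pos < 0) || any(pos >= grid$chrom_sizes[ci]))
    stop("position outside chromosome bounds")
  offs <- grid_offsets(grid)
  offs[ci] + pos %/% grid$bin_size + 1L
}
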