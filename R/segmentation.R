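#' Per-bin chromatin-state segmentation
#'
#' @param grid a `bin_grid`.
#' @param labels character (or factor) vector of state labels, one per bin.
#' @param state_names state vocabulary; defaults to the sorted unique labels.
#' @param cell_type label.
#' @return an object of class `segmentation`.
#' @export
segmentation <- function(grid, labels, state_names = NULL,
                         cell_type = "cell") {
  stopifnot(inherits(grid, "bin_grid"))
  labels <- as.character(labels)
  if (length(labels) != grid$total_bins)
    stop("labels must cover every bin exactly once")
  if (is.null(state_names)) state_names <- sort(unique(labels))
  if (!all(labels %in% state_names))
    stop("labels outside the state vocabulary")
  structure(list(grid = grid, labels = labels, state_names = state_names,
                 cell_type = cell_type),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %s, %d bins, %d states\n",
              x$cell_type, length(x$labels), length(x$state_names)))
  tb <- table(factor(x$labels, levels = x$state_names))
  print(round(tb / sum(tb), 3))
  invisible(x)
}

#' Maximal same-state intervals of a segmentation
#'
#' Collapses runs of identically-labeled adjacent bins (within one
#' chromosome) into bp-space intervals.
#'
#' @param seg a `segmentation`.
#' @param state optional label to restrict to.
#' @return GRanges with a `state` metadata column, sorted.
#' @export
seg_intervals <- function(seg, state = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  grid <- seg$grid
  offs <- grid_offsets(grid)
  chrom <- character(0); s0 <- integer(0); e0 <- integer(0)
  st <- character(0)
  for (i in seq_along(grid$chrom_sizes)) {
    rows <- offs[i] + seq_len(grid$n_bins[i])
    r <- rle(seg$labels[rows])
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    chrom <- c(chrom, rep(names(grid$chrom_sizes)[i], length(r$values)))
    s0 <- c(s0, (starts_bin - 1L) * grid$bin_size)
    e0 <- c(e0, pmin(ends_bin * grid$bin_size, grid$chrom_sizes[[i]]))
    st <- c(st, r$values)
  }
  gr <- GRanges(factor(chrom, levels = names(grid$chrom_sizes)),
                IRanges(s0 + 1L, e0), state = st)
  if (!is.null(state)) gr <- gr[mcols(gr)$state == state]
  gr
}

#' Write / read a segmentation as BED4
#'
#' ChromHMM `_segments.bed` style: chrom, start, end, state name.
#'
#' @param seg a `segmentation`.
#' @param path destination.
#' @export
write_segmentation <- function(seg, path) {
  gr <- seg_intervals(seg)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   state = mcols(gr)$state)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @param grid the `bin_grid` to reconstruct per-bin labels on.
#' @param state_names optional vocabulary.
#' @param cell_type label.
#' @export
read_segmentation <- function(path, grid, state_names = NULL,
                              cell_type = "cell") {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "state"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  labels <- rep(NA_character_, grid$total_bins)
  idx_first <- grid_bin_index(grid, df$chrom, df$start)
  idx_last <- grid_bin_index(grid, df$chrom, df$end - 1L)
  for (i in seq_len(nrow(df)))
    labels[idx_first[i]:idx_last[i]] <- df$state[i]
  if (anyNA(labels)) stop("segmentation file does not cover every bin")
  segmentation(grid, labels, state_names, cell_type)
}
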