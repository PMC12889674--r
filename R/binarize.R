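#' Binarized mark matrix
#'
#' Container for ChromHMM-style presence calls: one row per genomic bin, one
#' column per mark, entries in \{0, 1\}.
#'
#' @param grid a `bin_grid`.
#' @param values integer matrix, bins x marks, entries 0/1.
#' @param mark_names column labels.
#' @param cell_type label of the cell type the calls describe.
#' @return an object of class `binarized_matrix`.
#' @export
binarized_matrix <- function(grid, values, mark_names = colnames(values),
                             cell_type = "cell") {
  stopifnot(inherits(grid, "bin_grid"))
  values <- as.matrix(values)
  if (nrow(values) != grid$total_bins)
    stop("values must have one row per grid bin")
  if (is.null(mark_names) || length(mark_names) != ncol(values))
    stop("mark_names must label every column")
  if (!all(values %in% c(0L, 1L))) stop("entries must be 0 or 1")
  storage.mode(values) <- "integer"
  colnames(values) <- mark_names
  structure(list(grid = grid, values = values, mark_names = mark_names,
                 cell_type = cell_type),
            class = "binarized_matrix")
}

#' @export
print.binarized_matrix <- function(x, ...) {
  cat(sprintf("binarized_matrix: %s, %d bins x %d marks (%s)\n",
              x$cell_type, nrow(x$values), ncol(x$values),
              paste(x$mark_names, collapse = ", ")))
  invisible(x)
}

#' Binarize peaks onto a bin grid
#'
#' A bin is called present (1) for a mark iff any peak overlaps it by at
#' least one base pair, the any-overlap rule of ChromHMM's BinarizeBed.
#'
#' @param peaks a GRanges of peak calls.
#' @param grid a `bin_grid`; peak chromosomes must be a subset of the grid's.
#' @param mark_name label for the resulting column.
#' @return integer 0/1 vector of length `grid$total_bins`, named by
#'   `mark_name` as a one-column matrix.
#' @export
binarize_by_overlap <- function(peaks, grid, mark_name = "mark") {
  stopifnot(inherits(grid, "bin_grid"))
  col <- integer(grid$total_bins)
  if (length(peaks)) {
    check_bounds(peaks, grid$chrom_sizes)
    bins <- grid_bins(grid)
    hits <- unique(S4Vectors::queryHits(findOverlaps(bins, peaks)))
    col[hits] <- 1L
  }
  m <- matrix(col, ncol = 1, dimnames = list(NULL, mark_name))
  m
}

#' Assemble a binarized matrix from per-mark peak sets
#'
#' @param peak_list named list of GRanges, one per mark.
#' @param grid a `bin_grid`.
#' @param cell_type label.
#' @return a `binarized_matrix`.
#' @export
binarize_marks <- function(peak_list, grid, cell_type = "cell") {
  stopifnot(length(peak_list) > 0, !is.null(names(peak_list)))
  cols <- lapply(names(peak_list), function(m)
    binarize_by_overlap(peak_list[[m]], grid, m))
  binarized_matrix(grid, do.call(cbind, cols), cell_type = cell_type)
}

#' Write / read ChromHMM-style binarized track text
#'
#' The dialect is: line 1 `cell<TAB>chrom`, line 2 tab-separated mark names,
#' then one 0/1 row per bin of that chromosome. One file per chromosome.
#'
#' @param bm a `binarized_matrix`.
#' @param dir output directory; files are named `<cell>_<chrom>_binary.txt`.
#' @return invisibly, the written paths.
#' @export
write_binarized <- function(bm, dir) {
  stopifnot(inherits(bm, "binarized_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  offs <- grid_offsets(bm$grid)
  paths <- character(0)
  for (i in seq_along(bm$grid$chrom_sizes)) {
    chrom <- names(bm$grid$chrom_sizes)[i]
    rows <- offs[i] + seq_len(bm$grid$n_bins[i])
    path <- file.path(dir, sprintf("%s_%s_binary.txt", bm$cell_type, chrom))
    con <- file(path, "w")
    writeLines(paste(bm$cell_type, chrom, sep = "\t"), con)
    writeLines(paste(bm$mark_names, collapse = "\t"), con)
    utils::write.table(bm$values[rows, , drop = FALSE], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_binarized
#' @param paths files written by [write_binarized()], one per chromosome.
#' @param grid the `bin_grid` the files describe.
#' @export
read_binarized <- function(paths, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  values <- matrix(NA_integer_, nrow = grid$total_bins, ncol = 0)
  cell <- NULL; marks <- NULL
  offs <- grid_offsets(grid)
  chunks <- vector("list", length(grid$chrom_sizes))
  names(chunks) <- names(grid$chrom_sizes)
  for (path in paths) {
    hdr <- readLines(path, n = 2L)
    meta <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
    if (length(meta) != 2L) stop("malformed binarized header in ", path)
    cell_i <- meta[1]; chrom <- meta[2]
    marks_i <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]]
    if (is.null(cell)) { cell <- cell_i; marks <- marks_i }
    if (!identical(marks_i, marks)) stop("inconsistent mark names in ", path)
    if (!chrom %in% names(chunks)) stop("unknown chromosome ", chrom)
    vals <- as.matrix(utils::read.table(path, skip = 2L, sep = "\t"))
    if (nrow(vals) != grid$n_bins[chrom])
      stop("row count mismatch for ", chrom)
    chunks[[chrom]] <- vals
  }
  if (any(vapply(chunks, is.null, TRUE)))
    stop("missing chromosome file(s): ",
         paste(names(chunks)[vapply(chunks, is.null, TRUE)], collapse = ", "))
  values <- do.call(rbind, chunks)
  dimnames(values) <- list(NULL, marks)
  binarized_matrix(grid, values, marks, cell)
}
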