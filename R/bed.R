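#' Read a BED file into a GRanges
#'
#' Accepts BED3 or BED6 (name, score, strand). Input coordinates are 0-based
#' half-open per the BED convention; the returned GRanges is 1-based closed.
#' Malformed lines (non-integer coordinates, start >= end) raise an error
#' naming the offending line number.
#'
#' @param path file path.
#' @param chrom_sizes optional named vector; when given, intervals are checked
#'   against chromosome bounds and seqlengths are set.
#' @return a [GenomicRanges::GRanges]; columns `name`, `score` when present.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GRanges()
    if (!is.null(chrom_sizes)) gr <- set_seqinfo(gr, chrom_sizes)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": non-integer coordinates")
  bad <- which(start0 >= end0 | start0 < 0L)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": start must satisfy 0 <= start < end")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) mcols(gr)$score <-
      as.numeric(vapply(fields, `[[`, "", 5L))
  if (all(nf >= 6L)) {
    str <- vapply(fields, `[[`, "", 6L)
    str[!str %in% c("+", "-")] <- "*"
    strand(gr) <- str
  }
  if (!is.null(chrom_sizes)) {
    check_bounds(gr, chrom_sizes)
    gr <- set_seqinfo(gr, chrom_sizes)
  }
  gr
}

set_seqinfo <- function(gr, chrom_sizes) {
  seqlevels(gr) <- union(names(chrom_sizes), seqlevels(gr))
  seqlengths(gr) <- chrom_sizes[seqlevels(gr)]
  gr
}

check_bounds <- function(gr, chrom_sizes) {
  ci <- match(as.character(seqnames(gr)), names(chrom_sizes))
  if (anyNA(ci)) {
    bad <- unique(as.character(seqnames(gr))[is.na(ci)])
    stop("interval(s) on unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  if (any(end(gr) > chrom_sizes[ci]))
    stop("interval(s) extend beyond chromosome bounds")
  invisible(TRUE)
}

#' Write a GRanges to a BED file
#'
#' Writes BED6 when `name` or `score` metadata are present, BED3 otherwise.
#' Coordinates are converted back to the 0-based half-open BED convention.
#'
#' @param gr a GRanges.
#' @param path destination path.
#' @export
write_bed <- function(gr, path) {
  mc <- mcols(gr)
  has_extra <- any(c("name", "score") %in% colnames(mc))
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr))
  if (has_extra) {
    df$name <- if ("name" %in% colnames(mc)) as.character(mc$name) else "."
    df$score <- if ("score" %in% colnames(mc)) mc$score else 0
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    df$strand <- str
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a peak set
#'
#' Convenience constructor from 0-based half-open coordinates, the native
#' convention of BED and of this package's generators. The result is sorted
#' into canonical (chrom, start) order.
#'
#' @param chrom,start0,end0 vectors of chromosome, 0-based start, exclusive end.
#' @param score optional non-negative scores (interpreted as -log10 q where
#'   relevant).
#' @param name optional names.
#' @param chrom_sizes optional named vector for bounds checking.
#' @param summit optional 0-based offset of the summit from `start0`.
#' @return a sorted GRanges.
#' @export
peak_set <- function(chrom, start0, end0, score = NULL, name = NULL,
                     chrom_sizes = NULL, summit = NULL) {
  if (any(start0 < 0) || any(start0 >= end0))
    stop("need 0 <= start < end")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(score)) {
    if (any(score < 0)) stop("scores must be non-negative")
    mcols(gr)$score <- score
  }
  if (!is.null(summit)) mcols(gr)$summit <- as.integer(summit)
  if (!is.null(chrom_sizes)) {
    check_bounds(gr, chrom_sizes)
    gr <- set_seqinfo(gr, chrom_sizes)
  }
  sort(gr)
}

# 0-based center of each interval: floor((start0 + end0) / 2), honouring a
# summit offset column when present
interval_centers <- function(gr) {
  s0 <- start(gr) - 1L
  e0 <- end(gr)
  ctr <- (s0 + e0) %/% 2L
  mc <- mcols(gr)
  if ("summit" %in% colnames(mc)) {
    has <- !is.na(mc$summit)
    ctr[has] <- s0[has] + mc$summit[has]
  }
  ctr
}
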