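#' Grid-aligned methylation count track
#'
#' @param grid a `bin_grid`.
#' @param met,total integer per-bin methylated and total counts
#'   (0 <= met <= total); total 0 means missing coverage.
#' @param context "mCG" or "mCH".
#' @return object of class `methyl_track`.
#' @export
methyl_track <- function(grid, met, total, context = c("mCG", "mCH")) {
  context <- match.arg(context)
  stopifnot(inherits(grid, "bin_grid"))
  if (length(met) != grid$total_bins || length(total) != grid$total_bins)
    stop("met and total must have one entry per bin")
  if (any(met < 0) || any(total < 0) || any(met > total))
    stop("need 0 <= met <= total")
  structure(list(grid = grid, met = as.integer(met),
                 total = as.integer(total), context = context),
            class = "methyl_track")
}

#' Write / read a methylation track as TSV
#'
#' Columns: chrom, bin_start (0-based bp), met_count, total_count.
#'
#' @param mt a `methyl_track`.
#' @param path destination.
#' @export
write_methyl <- function(mt, path) {
  grid <- mt$grid
  chroms <- rep(names(grid$chrom_sizes), grid$n_bins)
  start0 <- unlist(lapply(grid$n_bins, function(n) seq_len(n) - 1L),
                   use.names = FALSE) * grid$bin_size
  utils::write.table(
    data.frame(chroms, start0, mt$met, mt$total), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_methyl
#' @param grid the `bin_grid` the file describes.
#' @param context methylation context.
#' @export
read_methyl <- function(path, grid, context = "mCG") {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "met", "total"))
  idx <- grid_bin_index(grid, df$chrom, df$start)
  met <- integer(grid$total_bins); total <- integer(grid$total_bins)
  met[idx] <- df$met; total[idx] <- df$total
  methyl_track(grid, met, total, context)
}

#' Per-state genomic coverage
#'
#' @param seg a `segmentation`.
#' @return data frame `state`, `bp`, `fraction`; fractions sum to 1 over all
#'   vocabulary states (including ND).
#' @export
state_coverage <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  w <- grid_bin_widths(seg$grid)
  bp <- rowsum(w, factor(seg$labels, levels = seg$state_names))[, 1]
  bp[is.na(bp)] <- 0
  full <- setNames(numeric(length(seg$state_names)), seg$state_names)
  full[names(bp)] <- bp
  data.frame(state = seg$state_names, bp = unname(full),
             fraction = unname(full) / sum(full))
}

#' Conservation proportion of a state between two cell types
#'
#' For each maximal interval of `state` in the reference segmentation, the
#' single most-overlapping same-state interval in the other segmentation is
#' found and its overlapping base pairs recorded (0 when none). The
#' proportion is the sum of these best-overlaps divided by the total length
#' of the reference intervals. Returns 0 (flagged via attribute
#' `"no_reference_intervals"`) when the reference carries no interval of the
#' state.
#'
#' @param seg_ref,seg_other `segmentation` objects on the same genome (bin
#'   sizes may differ; the comparison is in bp space).
#' @param state state label.
#' @return proportion in \[0, 1\].
#' @export
conservation_proportion <- function(seg_ref, seg_other, state) {
  if (!setequal(names(seg_ref$grid$chrom_sizes),
                names(seg_other$grid$chrom_sizes)))
    stop("segmentations cover different chromosome sets")
  ref <- seg_intervals(seg_ref, state)
  if (length(ref) == 0L)
    return(structure(0, no_reference_intervals = TRUE))
  oth <- seg_intervals(seg_other, state)
  best <- best_overlap_bp(ref, oth)
  sum(best) / sum(width(ref))
}

# per query interval, the width of its largest single overlap with any
# subject interval (0 when none)
best_overlap_bp <- function(query, subject) {
  best <- numeric(length(query))
  if (length(subject) == 0L) return(best)
  hits <- findOverlaps(query, subject)
  if (length(hits) == 0L) return(best)
  ov <- width(pintersect(query[S4Vectors::queryHits(hits)],
                         subject[S4Vectors::subjectHits(hits)]))
  agg <- tapply(ov, S4Vectors::queryHits(hits), max)
  best[as.integer(names(agg))] <- agg
  best
}

#' Variation of a state's conservation across cell types
#'
#' Population variance (divide by n) of the conservation proportions of the
#' reference against each comparator segmentation.
#'
#' @param seg_ref reference `segmentation`.
#' @param segs_others list of >= 2 comparator segmentations.
#' @param state state label.
#' @return non-negative variance.
#' @export
state_variation <- function(seg_ref, segs_others, state) {
  if (length(segs_others) < 2L) stop("need at least 2 comparators")
  p <- vapply(segs_others, function(s)
    as.numeric(conservation_proportion(seg_ref, s, state)), numeric(1))
  mean((p - mean(p))^2)
}

#' Chromatin-state transitions between two cell types
#'
#' Interval-level accounting: each maximal source-state interval is assigned
#' the target-state covering the plurality of its bases (ties toward the
#' earlier state in the vocabulary), and the K x K count matrix of
#' (source state, target state) is tabulated with row totals and row
#' percentages. Bin-level accounting is available via `units = "bins"`.
#'
#' @param seg_source,seg_target `segmentation` objects on a shared grid.
#' @param units "intervals" (default) or "bins".
#' @param convention "nearest" (default) or "truncate" for the displayed
#'   percentages; exact fractions are always retained.
#' @return object of class `transition_summary`: list with `counts`,
#'   `row_totals`, `row_pct_exact`, `row_pct` and the labels.
#' @export
transition_summary <- function(seg_source, seg_target,
                               units = c("intervals", "bins"),
                               convention = c("nearest", "truncate")) {
  units <- match.arg(units); convention <- match.arg(convention)
  if (!identical(seg_source$grid, seg_target$grid))
    stop("segmentations must share the grid")
  src_states <- seg_source$state_names
  tgt_states <- seg_target$state_names
  counts <- matrix(0L, length(src_states), length(tgt_states),
                   dimnames = list(src_states, tgt_states))
  if (units == "bins") {
    tb <- table(factor(seg_source$labels, src_states),
                factor(seg_target$labels, tgt_states))
    counts[] <- as.integer(tb)
  } else {
    iv <- seg_intervals(seg_source)
    tgt_idx <- match(seg_target$labels, tgt_states)
    w <- grid_bin_widths(seg_source$grid)
    offs <- grid_offsets(seg_source$grid)
    ci <- match(as.character(seqnames(iv)), names(seg_source$grid$chrom_sizes))
    first_bin <- offs[ci] + (start(iv) - 1L) %/% seg_source$grid$bin_size + 1L
    last_bin <- offs[ci] + (end(iv) - 1L) %/% seg_source$grid$bin_size + 1L
    tgt_of <- integer(length(iv))
    for (i in seq_along(iv)) {
      rows <- first_bin[i]:last_bin[i]
      bp <- rowsum(w[rows], tgt_idx[rows])
      tgt_of[i] <- as.integer(rownames(bp)[which.max(bp)])
    }
    tb <- table(factor(mcols(iv)$state, src_states),
                factor(tgt_states[tgt_of], tgt_states))
    counts[] <- as.integer(tb)
  }
  rt <- rowSums(counts)
  exact <- counts / ifelse(rt == 0, NA, rt) * 100
  structure(list(counts = counts, row_totals = rt, row_pct_exact = exact,
                 row_pct = apply_pct_convention(exact, convention),
                 convention = convention, units = units,
                 source = seg_source$cell_type,
                 target = seg_target$cell_type),
            class = "transition_summary")
}

#' Row-percentage arithmetic for transition counts
#'
#' Converts counts in a row to percentages of the row total under a display
#' convention: "nearest" rounds to the nearest integer, "truncate" drops the
#' fractional part (both conventions appear in published transition
#' tables).
#'
#' @param counts numeric vector or matrix of counts.
#' @param total row total (default `sum(counts)` for a vector).
#' @param convention "nearest" or "truncate".
#' @return percentages on the 0-100 scale.
#' @export
row_percentages <- function(counts, total = NULL,
                            convention = c("nearest", "truncate")) {
  convention <- match.arg(convention)
  if (is.null(total)) total <- sum(counts)
  apply_pct_convention(counts / total * 100, convention)
}

apply_pct_convention <- function(pct, convention) {
  switch(convention, nearest = round(pct), truncate = trunc(pct))
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("state transitions: %s -> %s (%s, %s%%)\n",
              x$source, x$target, x$units, x$convention))
  print(x$counts)
  invisible(x)
}

#' Pooled methylation fraction per chromatin state
#'
#' For each state, sum of methylated counts over its covered bins divided by
#' the sum of total counts; states whose bins all lack coverage are NA,
#' flagged via the `"no_coverage_states"` attribute.
#'
#' @param seg a `segmentation`.
#' @param meth a grid-aligned `methyl_track`.
#' @return named numeric vector over the segmentation's vocabulary.
#' @export
methylation_by_state <- function(seg, meth) {
  stopifnot(inherits(seg, "segmentation"), inherits(meth, "methyl_track"))
  if (!identical(seg$grid, meth$grid))
    stop("segmentation and methylation track must share the grid")
  f <- factor(seg$labels, levels = seg$state_names)
  met <- rowsum(as.numeric(meth$met), f)[, 1]
  tot <- rowsum(as.numeric(meth$total), f)[, 1]
  out <- setNames(rep(NA_real_, length(seg$state_names)), seg$state_names)
  out[names(met)] <- ifelse(tot > 0, met / tot, NA_real_)
  attr(out, "no_coverage_states") <- names(out)[is.na(out)]
  out
}

#' Stratify region signal by methylation level
#'
#' Assigns each region a stratum by its pooled methylation fraction
#' (defaults: Low < 0.2, Medium 0.2-0.8, High > 0.8), then reports the
#' per-stratum mean signal and pairwise two-sided Welch t-tests with
#' Benjamini-Hochberg adjustment. Empty strata are reported with NA
#' statistics.
#'
#' @param regions GRanges of regions (e.g. CpG islands).
#' @param meth a `methyl_track`.
#' @param signal numeric vector of per-region signal (same length/order as
#'   `regions`).
#' @param breaks strictly increasing cut points in (0, 1); default
#'   `c(0.2, 0.8)`.
#' @return list with `strata` (per-region assignment), `means`, `n`, and
#'   `tests` (data frame of pairwise comparisons with `p` and `p_adj`).
#' @export
stratify_signal_by_methylation <- function(regions, meth, signal,
                                           breaks = c(0.2, 0.8)) {
  if (length(regions) != length(signal))
    stop("signal must align with regions")
  if (any(diff(breaks) <= 0) || any(breaks <= 0 | breaks >= 1))
    stop("breaks must be strictly increasing within (0, 1)")
  frac <- region_methylation(regions, meth)
  lv <- stratum_labels(length(breaks))
  # boundaries belong to the middle strata: Low is strictly below the first
  # break, the top stratum strictly above the last
  idx <- findInterval(frac, breaks) + 1L
  idx[!is.na(frac) & frac == breaks[length(breaks)]] <- length(breaks)
  strata <- factor(lv[idx], levels = lv)
  means <- tapply(signal, strata, mean)
  n <- tabulate(strata, nbins = length(lv))
  pairs <- utils::combn(lv, 2)
  tests <- data.frame(a = pairs[1, ], b = pairs[2, ],
                      t = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    xa <- signal[strata == pairs[1, i]]
    xb <- signal[strata == pairs[2, i]]
    if (length(xa) >= 2 && length(xb) >= 2 &&
        (stats::var(xa) > 0 || stats::var(xb) > 0)) {
      tt <- t.test(xa, xb)  # Welch
      tests$t[i] <- unname(tt$statistic)
      tests$p[i] <- tt$p.value
    }
  }
  tests$p_adj <- p.adjust(tests$p, method = "BH")
  list(strata = strata, means = means, n = setNames(n, lv), tests = tests)
}

stratum_labels <- function(n_breaks) {
  if (n_breaks == 2L) c("Low", "Medium", "High")
  else paste0("stratum", seq_len(n_breaks + 1L))
}

# pooled methylation fraction of each region over the bins it overlaps
region_methylation <- function(regions, meth) {
  grid <- meth$grid
  bins <- grid_bins(grid)
  hits <- findOverlaps(regions, bins)
  met <- rowsum(as.numeric(meth$met[S4Vectors::subjectHits(hits)]),
                S4Vectors::queryHits(hits))
  tot <- rowsum(as.numeric(meth$total[S4Vectors::subjectHits(hits)]),
                S4Vectors::queryHits(hits))
  out <- rep(NA_real_, length(regions))
  idx <- as.integer(rownames(met))
  out[idx] <- ifelse(tot[, 1] > 0, met[, 1] / tot[, 1], NA_real_)
  out
}
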