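#' Reproducible peaks across replicates
#'
#' Implements the replicate-support rule used for sex-specific peak calling:
#' candidate peaks are the union of replicate peaks passing the score cutoff
#' (scores are MACS-style negative log10 q-values), and a candidate is
#' retained iff it overlaps at least one peak in all but at most `max_absent`
#' of the replicate sets. Retained candidates that overlap each other are
#' merged, carrying the maximum score.
#'
#' @param replicates list of >= 2 scored GRanges (one per replicate).
#' @param min_score minimum score for a peak to enter the candidate universe
#'   (default 0.01).
#' @param max_absent number of replicates a candidate may miss (default 1).
#' @return merged GRanges of reproducible peaks with a `score` column.
#' @export
reproducible_peaks <- function(replicates, min_score = 0.01, max_absent = 1L) {
  if (length(replicates) < 2L) stop("need at least 2 replicate peak sets")
  need <- length(replicates) - max_absent
  cand <- lapply(replicates, function(gr) {
    if (!"score" %in% colnames(mcols(gr))) {
      if (length(gr)) stop("replicate peaks must carry scores")
      mcols(gr)$score <- numeric(0)
    }
    gr[mcols(gr)$score >= min_score]
  })
  universe <- do.call(c, lapply(cand, function(g) {
    mcols(g) <- mcols(g)["score"]; g
  }))
  if (length(universe) == 0L) return(empty_scored())
  support <- rowSums(vapply(replicates, function(gr)
    countOverlaps(universe, gr) > 0L, logical(length(universe))))
  kept <- universe[support >= need]
  if (length(kept) == 0L) return(empty_scored())
  merged <- reduce(kept)
  hits <- findOverlaps(merged, kept)
  mcols(merged)$score <- vapply(
    split(mcols(kept)$score[S4Vectors::subjectHits(hits)],
          S4Vectors::queryHits(hits)),
    max, numeric(1))[as.character(seq_along(merged))]
  sort(merged)
}

#' Iterative SPM-based peak merging
#'
#' ArchR-style iterative merge: peak scores are first normalized within each
#' source set to scores-per-million (SPM_i = score_i * 1e6 / sum of scores in
#' the set). The merge then greedily takes the highest-SPM remaining peak,
#' emits it, discards every peak overlapping it, and repeats, yielding a
#' non-overlapping high-confidence union set. Ties in SPM are broken by
#' (chrom, start) ascending.
#'
#' @param peaksets list of scored GRanges (each a source set; pass a single
#'   set as `list(gr)`).
#' @return non-overlapping sorted GRanges; metadata columns shared by all
#'   source sets are kept and an `spm` column added.
#' @export
iterative_spm_merge <- function(peaksets) {
  if (!length(peaksets)) stop("empty peak set list")
  nonempty <- which(lengths(peaksets) > 0)
  if (!length(nonempty)) return(empty_scored(spm = TRUE))
  common <- Reduce(intersect,
                   lapply(peaksets[nonempty],
                          function(g) colnames(mcols(g))))
  pool <- do.call(c, lapply(nonempty, function(i) {
    gr <- peaksets[[i]]
    if (!"score" %in% colnames(mcols(gr)))
      stop("all peaks must be scored")
    tot <- sum(mcols(gr)$score)
    if (tot <= 0) stop("SPM undefined: source set ", i, " has zero total score")
    out <- gr
    mcols(out) <- mcols(gr)[, common, drop = FALSE]
    mcols(out)$spm <- mcols(gr)$score * 1e6 / tot
    out
  }))
  if (length(pool) == 0L) return(pool)
  ord <- order(-mcols(pool)$spm, as.character(seqnames(pool)), start(pool))
  pool <- pool[ord]
  alive <- rep(TRUE, length(pool))
  keep <- logical(length(pool))
  ov <- findOverlaps(pool, pool)
  ov_by <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  for (i in seq_along(pool)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[ov_by[[as.character(i)]]] <- FALSE
  }
  sort(pool[keep])
}

empty_scored <- function(spm = FALSE) {
  gr <- GRanges()
  mcols(gr)$score <- numeric(0)
  if (spm) mcols(gr)$spm <- numeric(0)
  gr
}

#' Shuffled background regions
#'
#' For each input region, places one random region of the same length on the
#' same chromosome such that outputs are mutually non-overlapping and disjoint
#' from `exclude` (shuffleBed -chrom -noOverlapping semantics).
#'
#' @param regions GRanges to shuffle.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param exclude optional GRanges the output must not touch.
#' @param seed integer seed; placements are deterministic given it.
#' @param max_tries retries per region before giving up (default 1000).
#' @return GRanges of placed regions, in input order.
#' @export
shuffle_background <- function(regions, chrom_sizes, exclude = NULL,
                               seed = 1L, max_tries = 1000L) {
  check_bounds(regions, chrom_sizes)
  ex_chrom <- if (is.null(exclude)) character(0)
              else as.character(seqnames(exclude))
  ex_s0 <- if (is.null(exclude)) integer(0) else start(exclude) - 1L
  ex_e0 <- if (is.null(exclude)) integer(0) else end(exclude)
  clashes <- function(chrom, s0, e0, chs, ss, es)
    any(chs == chrom & ss < e0 & es > s0)
  with_seed(substream(seed, 71L), {
    pl_chrom <- character(0); pl_s0 <- integer(0); pl_e0 <- integer(0)
    out_start <- integer(length(regions))
    for (i in seq_along(regions)) {
      chrom <- as.character(seqnames(regions[i]))
      w <- width(regions[i])
      lim <- chrom_sizes[[chrom]] - w
      if (lim < 0) stop("region ", i, " longer than its chromosome")
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s0 <- floor(runif(1, 0, lim + 1))
        if (clashes(chrom, s0, s0 + w, pl_chrom, pl_s0, pl_e0)) next
        if (clashes(chrom, s0, s0 + w, ex_chrom, ex_s0, ex_e0)) next
        pl_chrom <- c(pl_chrom, chrom)
        pl_s0 <- c(pl_s0, s0); pl_e0 <- c(pl_e0, s0 + w)
        out_start[i] <- s0
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place region ", i, " after ", max_tries,
                    " tries (exclusions too dense?)")
    }
    GRanges(as.character(seqnames(regions)),
            IRanges(out_start + 1L, out_start + width(regions)))
  })
}
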