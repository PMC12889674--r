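#' Feature-count quality filter
#'
#' Retains barcodes whose DNA and RNA feature counts both fall inside the
#' inclusive ranges (defaults 500-30,000 DNA features, 200-30,000 RNA
#' features).
#'
#' @param cells data frame with `dna_feature_count` and `rna_feature_count`.
#' @param dna_range,rna_range inclusive \[lo, hi\] bounds.
#' @return the filtered data frame. Idempotent.
#' @export
qc_filter <- function(cells, dna_range = c(500, 30000),
                      rna_range = c(200, 30000)) {
  if (dna_range[1] > dna_range[2] || rna_range[1] > rna_range[2])
    stop("range lower bound exceeds upper bound")
  keep <- cells$dna_feature_count >= dna_range[1] &
    cells$dna_feature_count <= dna_range[2] &
    cells$rna_feature_count >= rna_range[1] &
    cells$rna_feature_count <= rna_range[2]
  cells[keep, , drop = FALSE]
}

#' Species assignment of barnyard barcodes
#'
#' A barcode is assigned to a species when at least 75% of its reads map to
#' that species' genome (inclusive threshold); otherwise it is a doublet.
#' Zero-read barcodes are unclassifiable.
#'
#' @param cells data frame with `reads_species_a`, `reads_species_b`.
#' @param threshold species-assignment fraction (default 0.75).
#' @return character vector in \{"species-A", "species-B", "doublet",
#'   "unclassifiable"\}.
#' @export
species_mix_classify <- function(cells, threshold = 0.75) {
  tot <- cells$reads_species_a + cells$reads_species_b
  fa <- cells$reads_species_a / tot
  out <- rep("doublet", nrow(cells))
  out[tot == 0] <- "unclassifiable"
  out[tot > 0 & fa >= threshold] <- "species-A"
  out[tot > 0 & (1 - fa) >= threshold] <- "species-B"
  out
}

#' Barcode collision rate from a species mix
#'
#' Cross-species barcodes reveal only the multiplets that paired unlike
#' species; with pool fraction p of species A, that is a fraction 2p(1-p)
#' of all multiplets. The total rate is therefore extrapolated as
#' r = d / (2 p (1 - p)) from the observed cross-species (doublet-labeled)
#' fraction d, capped at 1, with a binomial standard error on d propagated.
#'
#' @param labels classifications from [species_mix_classify()].
#' @param pool_fraction_a p in (0, 1).
#' @return list `rate`, `cross_fraction`, `se` (on the rate scale).
#' @export
collision_rate_estimate <- function(labels, pool_fraction_a = 0.5) {
  p <- pool_fraction_a
  if (p <= 0 || p >= 1) stop("pool_fraction_a must lie in (0, 1)")
  usable <- labels != "unclassifiable"
  n <- sum(usable)
  if (n == 0L) stop("no classifiable barcodes")
  d <- sum(labels[usable] == "doublet") / n
  scale <- 1 / (2 * p * (1 - p))
  se_d <- sqrt(d * (1 - d) / n)
  list(rate = min(1, d * scale), cross_fraction = d, se = se_d * scale)
}

#' Rate-matched doublet removal
#'
#' Removes the ceiling(target_rate * n) barcodes with the highest doublet
#' scores; ties at the cutoff are broken by barcode identifier ascending
#' (the lexicographically smallest tied barcodes are removed first), for
#' determinism.
#'
#' @param scores named numeric vector of doublet scores (names = barcodes).
#' @param target_rate fraction to remove in \[0, 1\].
#' @return list `retained`, `removed` (barcode names).
#' @export
rate_matched_removal <- function(scores, target_rate) {
  if (target_rate < 0 || target_rate > 1)
    stop("target_rate must lie in [0, 1]")
  n <- length(scores)
  k <- ceiling(target_rate * n)
  if (k == 0L) return(list(retained = names(scores), removed = character(0)))
  ord <- order(-scores, names(scores))
  removed <- names(scores)[ord[seq_len(k)]]
  list(retained = setdiff(names(scores), removed), removed = removed)
}

#' ATAC gene-activity scores
#'
#' Per gene, the number of fragments overlapping the gene body extended 2 kb
#' upstream of the strand-aware TSS.
#'
#' @param fragments GRanges of fragments.
#' @param genes GRanges with strand and a `name` (gene id) column; missing
#'   strand is an error.
#' @param upstream bp extension upstream of the TSS (default 2000).
#' @return named integer vector of fragment counts per gene.
#' @export
gene_activity_atac <- function(fragments, genes, upstream = 2000L) {
  str <- as.character(strand(genes))
  if (any(str == "*")) stop("genes must carry strand")
  ext_start <- ifelse(str == "+", pmax(1L, start(genes) - upstream),
                      start(genes))
  ext_end <- ifelse(str == "+", end(genes), end(genes) + upstream)
  ext <- GRanges(seqnames(genes), IRanges(ext_start, ext_end))
  counts <- countOverlaps(ext, fragments)
  setNames(counts, region_ids(genes))
}

#' Methylation-derived gene-activity scores
#'
#' Within each cell group, gene-body methylation fractions are
#' log-transformed (natural log, after a pseudocount of 1 methylated / 2
#' total counts when counts are supplied), z-scored across genes with the
#' population standard deviation, and negated: hypomethylated gene bodies
#' score high. The methylation context is routed by neuron class: neurons
#' other than granule neurons use mCH; non-neurons, immature neurons and
#' granule neurons use mCG. Groups with zero variance get all-zero scores,
#' flagged.
#'
#' @param mcg,mch genes x groups matrices of methylation fractions (> 0).
#' @param group_classes character vector per group in \{"neuron",
#'   "granule-neuron", "immature", "non-neuron"\}.
#' @return list `scores` (genes x groups), `context_used` (per group),
#'   `zero_variance_groups`.
#' @export
gene_activity_methylation <- function(mcg, mch, group_classes) {
  if (ncol(mcg) != length(group_classes) || ncol(mch) != length(group_classes))
    stop("group_classes must label every column")
  use_mch <- group_classes == "neuron"
  scores <- matrix(NA_real_, nrow(mcg), ncol(mcg), dimnames = dimnames(mcg))
  flagged <- character(0)
  for (g in seq_len(ncol(mcg))) {
    f <- if (use_mch[g]) mch[, g] else mcg[, g]
    if (any(f <= 0)) stop("fractions must be positive (apply a pseudocount)")
    lf <- log(f)
    sdp <- sqrt(mean((lf - mean(lf))^2))
    if (sdp == 0) {
      scores[, g] <- 0
      flagged <- c(flagged, colnames(mcg)[g] %||% as.character(g))
    } else scores[, g] <- -(lf - mean(lf)) / sdp
  }
  list(scores = scores,
       context_used = ifelse(use_mch, "mCH", "mCG"),
       zero_variance_groups = flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pseudocounted methylation fraction
#'
#' (met + 1) / (total + 2), keeping the log transform finite at zero
#' counts.
#'
#' @param met,total count vectors.
#' @export
meth_fraction <- function(met, total) (met + 1) / (total + 2)

#' Normalized mutual information of two labelings
#'
#' I(A;B) normalized by the arithmetic mean of the entropies (natural
#' logs). Two single-cluster labelings are defined to agree perfectly
#' (NMI 1).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return value in \[0, 1\]; symmetric and permutation-invariant.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' k-nearest-neighbour label-transfer accuracy
#'
#' Each cell receives the majority label of its k Euclidean nearest
#' neighbours in the embedding, excluding itself; ties go to the
#' lexicographically smallest label. Accuracy is the fraction of cells
#' whose vote matches their own label.
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param labels per-cell labels.
#' @param k neighbours (default 15); must satisfy k < n.
#' @return accuracy in \[0, 1\].
#' @export
knn_label_accuracy <- function(embedding, labels, k = 15L) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(embedding))
  correct <- logical(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])
    nb <- labels[-i][ord[seq_len(k)]]
    tb <- sort(table(nb), decreasing = TRUE)
    vote <- sort(names(tb)[tb == max(tb)])[1]
    correct[i] <- vote == labels[i]
  }
  mean(correct)
}

#' Region specificity of cell subclasses
#'
#' A subclass is region-specific when strictly more than `threshold` of its
#' cells originate from one dominant brain region.
#'
#' @param cells data frame with `subclass` and `region` columns.
#' @param threshold dominance fraction (default 0.75, strict inequality).
#' @return data frame `subclass`, `dominant_region`, `fraction`,
#'   `specific`.
#' @export
region_specificity <- function(cells, threshold = 0.75) {
  sp <- split(cells$region, cells$subclass)
  rows <- lapply(names(sp), function(sc) {
    tb <- sort(table(sp[[sc]]), decreasing = TRUE)
    frac <- tb[1] / sum(tb)
    data.frame(subclass = sc, dominant_region = names(tb)[1],
               fraction = unname(frac),
               specific = unname(frac) > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
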