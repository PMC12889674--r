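#' Annotate cCREs by the chromatin state at their center
#'
#' Each candidate cis-regulatory element is assigned the state of the bin
#' containing its center: floor((start + end) / 2) in 0-based coordinates,
#' or start + summit when a summit offset column is present.
#'
#' @param cres GRanges of cCREs on the segmentation's genome.
#' @param seg a `segmentation`.
#' @param cell_type label recorded in the result (defaults to the
#'   segmentation's).
#' @return data frame `region_id`, `cell_type`, `center` (0-based bp),
#'   `state`, `class` (the state label; Chr-A and Chr-O are the classes of
#'   interest downstream). Attribute `"composition"` holds the per-class
#'   fraction.
#' @export
annotate_cre_state <- function(cres, seg, cell_type = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  if (is.null(cell_type)) cell_type <- seg$cell_type
  ctr <- interval_centers(cres)
  idx <- grid_bin_index(seg$grid, as.character(seqnames(cres)), ctr)
  state <- seg$labels[idx]
  out <- data.frame(region_id = region_ids(cres), cell_type = cell_type,
                    center = ctr, state = state, class = state,
                    stringsAsFactors = FALSE)
  comp <- table(factor(state, levels = seg$state_names))
  attr(out, "composition") <- comp / max(1L, sum(comp))
  out
}

#' Differential region testing on detection counts
#'
#' A per-region two-sided Fisher exact test on the 2x2 table of cells
#' detecting the region versus not, foreground versus background, with
#' Benjamini-Hochberg adjustment over the tested regions. Regions whose
#' foreground detection fraction falls below `min_pct` are excluded before
#' testing. A region passes when its adjusted p-value is below `alpha` and
#' its log2 fold change of detection rates (pseudocount 1 on counts and
#' totals) clears `lfc_min` in the direction requested: `"positive"` keeps
#' foreground-enriched regions only, `"both"` either sign.
#'
#' @param fg_counts,bg_counts per-region detecting-cell counts.
#' @param n_fg_cells,n_bg_cells cell totals (> 0).
#' @param min_pct minimum foreground detection fraction (default 0.01).
#' @param lfc_min minimum |log2 fold change| (default 0.2).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param direction "positive" or "both".
#' @param region_ids optional ids.
#' @return data frame `region_id`, `fg_count`, `bg_count`, `fg_frac`,
#'   `lfc`, `p`, `p_adj`, `tested`, `pass`; `p_adj >= p` always holds.
#' @export
differential_regions <- function(fg_counts, bg_counts, n_fg_cells,
                                 n_bg_cells, min_pct = 0.01, lfc_min = 0.2,
                                 alpha = 0.05,
                                 direction = c("positive", "both"),
                                 region_ids = NULL) {
  direction <- match.arg(direction)
  if (n_fg_cells <= 0 || n_bg_cells <= 0)
    stop("cell totals must be positive")
  if (length(fg_counts) != length(bg_counts))
    stop("count vectors differ in length")
  n <- length(fg_counts)
  if (is.null(region_ids)) region_ids <- sprintf("region%d", seq_len(n))
  fg_frac <- fg_counts / n_fg_cells
  tested <- fg_frac >= min_pct
  lfc <- log2(((fg_counts + 1) / (n_fg_cells + 1)) /
              ((bg_counts + 1) / (n_bg_cells + 1)))
  p <- rep(NA_real_, n)
  for (i in which(tested)) {
    tab <- matrix(c(fg_counts[i], n_fg_cells - fg_counts[i],
                    bg_counts[i], n_bg_cells - bg_counts[i]), 2)
    p[i] <- fisher.test(tab)$p.value
  }
  p_adj <- rep(NA_real_, n)
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  dir_ok <- if (direction == "positive") lfc >= lfc_min
            else abs(lfc) >= lfc_min
  pass <- tested & !is.na(p_adj) & p_adj < alpha & dir_ok
  data.frame(region_id = region_ids, fg_count = fg_counts,
             bg_count = bg_counts, fg_frac = fg_frac, lfc = lfc,
             p = p, p_adj = p_adj, tested = tested, pass = pass,
             stringsAsFactors = FALSE)
}

#' Pairwise center distances of same-chromosome regions
#'
#' All unordered pairs of regions on the same chromosome whose center
#' distance is at most `max_distance` (default 1 Mb). Centers honour summit
#' offsets via the `summit` column.
#'
#' @param regions GRanges.
#' @param max_distance cap in bp.
#' @return numeric vector (multiset) of distances.
#' @export
pairwise_center_distances <- function(regions, max_distance = 1e6) {
  ctr <- interval_centers(regions)
  chroms <- as.character(seqnames(regions))
  out <- lapply(split(ctr, chroms), function(v) {
    v <- sort(v)
    n <- length(v)
    if (n < 2L) return(numeric(0))
    d <- unlist(lapply(seq_len(n - 1L), function(i) {
      dd <- v[(i + 1L):n] - v[i]
      dd[dd <= max_distance]
    }), use.names = FALSE)
    d
  })
  unname(unlist(out))
}

#' Mean signal profile over length-scaled regions
#'
#' deepTools scale-regions semantics: each region is linearly rescaled to
#' `body_length` bp, the track value is averaged within consecutive
#' `bin_size`-bp windows of the scaled body (positions without track data
#' count as zero), minus-strand regions are reversed, and the profile is the
#' per-window mean over all regions.
#'
#' @param regions GRanges (strand honoured).
#' @param score_track GRanges with a `score` column giving the signal, or a
#'   precomputed [IRanges::RleList] of per-bp values.
#' @param body_length scaled region length in bp (default 500).
#' @param bin_size window width in bp (default 10; must divide
#'   `body_length`).
#' @return numeric vector of `body_length / bin_size` window means.
#' @export
scaled_region_profile <- function(regions, score_track, body_length = 500L,
                                  bin_size = 10L) {
  if (length(regions) == 0L) stop("empty region list")
  if (body_length %% bin_size != 0L)
    stop("body_length must be divisible by bin_size")
  n_out <- body_length %/% bin_size
  cov <- if (inherits(score_track, "RleList")) score_track
         else coverage(score_track, weight = mcols(score_track)$score)
  acc <- numeric(n_out)
  for (i in seq_along(regions)) {
    chrom <- as.character(seqnames(regions)[i])
    s <- start(regions)[i]; w <- width(regions)[i]
    vals <- if (chrom %in% names(cov)) {
      v <- cov[[chrom]]
      from <- min(s, length(v) + 1L)
      to <- min(s + w - 1L, length(v))
      out <- numeric(w)
      if (from <= to)
        out[seq_len(to - from + 1L)] <- as.numeric(v[from:to])
      out
    } else numeric(w)  # missing data as zero
    # map each scaled bp j (0-based) to a source bp, then average windows
    src <- floor((seq_len(body_length) - 1L) * w / body_length) + 1L
    scaled <- vals[src]
    if (as.character(strand(regions)[i]) == "-") scaled <- rev(scaled)
    acc <- acc + colMeans(matrix(scaled, nrow = bin_size))
  }
  acc / length(regions)
}

#' Transposable-element subfamily signal matrix
#'
#' Per-TE mean track value, then the unweighted mean over each subfamily's
#' TEs, per cell type. TEs on sex chromosomes are excluded (autosomes-only
#' convention). Subfamily labels come from the `name` column, either plain
#' or as "superfamily:subfamily".
#'
#' @param te_annotation GRanges of TE copies with subfamily labels.
#' @param signal_tracks named list (one per cell type) of score GRanges or
#'   RleLists.
#' @param sex_chroms chromosome names to drop.
#' @return subfamily x cell-type matrix; subfamilies empty after filtering
#'   are absent.
#' @export
te_subfamily_signal <- function(te_annotation, signal_tracks,
                                sex_chroms = c("chrX", "chrY", "X", "Y")) {
  if (!"name" %in% colnames(mcols(te_annotation)))
    stop("TEs must carry subfamily labels in the name column")
  keep <- !as.character(seqnames(te_annotation)) %in% sex_chroms
  te <- te_annotation[keep]
  if (length(te) == 0L) stop("no autosomal TEs left")
  subfam <- sub("^.*:", "", as.character(mcols(te)$name))
  subfams <- sort(unique(subfam))
  out <- matrix(NA_real_, length(subfams), length(signal_tracks),
                dimnames = list(subfams, names(signal_tracks)))
  for (ct in names(signal_tracks)) {
    cov <- signal_tracks[[ct]]
    if (!inherits(cov, "RleList"))
      cov <- coverage(cov, weight = mcols(cov)$score)
    per_te <- vapply(seq_along(te), function(i) {
      chrom <- as.character(seqnames(te)[i])
      if (!chrom %in% names(cov)) return(0)
      v <- cov[[chrom]]
      from <- start(te)[i]; to <- min(end(te)[i], length(v))
      if (from > length(v)) return(0)
      s <- sum(as.numeric(v[from:to]))
      s / width(te)[i]
    }, numeric(1))
    out[, ct] <- tapply(per_te, subfam, mean)[subfams]
  }
  out
}

#' Enhancer-validation metrics for state-annotated regions
#'
#' Entry-level evaluation of chromatin-state predictions against an
#' experimental validation table. For each predicted class (for example
#' Chr-A): TP = predicted (region, cell type) entries whose outcome is
#' positive, FP = predicted entries with a negative outcome; precision =
#' TP / (TP + FP); recall = TP / (total positive entries in the table);
#' specificity = 1 - FP / (N_regions x N_celltypes). Positive outcomes
#' default to \{"positive", "putative"\}. Undefined ratios are NA with the
#' `"undefined"` attribute naming them.
#'
#' @param annotations data frame as from [annotate_cre_state()] (rows for
#'   every tested cell type), with `region_id`, `cell_type`, `class`.
#' @param validation data frame `region_id`, `cell_type`, `outcome` in
#'   \{"positive", "putative", "negative", "untested"\}.
#' @param predict_class class whose entries count as predictions (default
#'   "Chr-A").
#' @param positive_labels outcomes counting as positive.
#' @return named numeric vector `precision`, `recall`, `specificity`, plus
#'   `tp`, `fp`.
#' @export
enhancer_eval <- function(annotations, validation, predict_class = "Chr-A",
                          positive_labels = c("positive", "putative")) {
  if (!nrow(validation)) stop("empty validation table")
  key <- function(df) paste(df$region_id, df$cell_type, sep = "\r")
  tested <- validation[validation$outcome != "untested", , drop = FALSE]
  pred <- annotations[annotations$class == predict_class, , drop = FALSE]
  m <- match(key(pred), key(tested))
  outc <- tested$outcome[m[!is.na(m)]]
  tp <- sum(outc %in% positive_labels)
  fp <- sum(outc == "negative")
  total_pos <- sum(tested$outcome %in% positive_labels)
  n_regions <- length(unique(validation$region_id))
  n_ct <- length(unique(validation$cell_type))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (total_pos > 0) tp / total_pos else 0
  specificity <- 1 - fp / (n_regions * n_ct)
  out <- c(precision = precision, recall = recall,
           specificity = specificity, tp = tp, fp = fp)
  undef <- names(out)[is.na(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Modal-class grouping of regions across cell types
#'
#' A region's overall group is its most frequent class across the tested
#' cell types; ties resolve toward Chr-A (then alphabetically).
#'
#' @param annotations data frame with `region_id`, `class`.
#' @return named character vector keyed by region id.
#' @export
region_major_class <- function(annotations) {
  vapply(split(annotations$class, annotations$region_id), function(cl) {
    tb <- sort(table(cl), decreasing = TRUE)
    top <- names(tb)[tb == max(tb)]
    if ("Chr-A" %in% top) "Chr-A" else sort(top)[1]
  }, character(1))
}

#' Overlap enrichment odds ratio
#'
#' 2x2 contingency of universe regions by membership in the query set versus
#' overlap with validated positives; OR = ad / bc with the Haldane-Anscombe
#' 0.5 correction when any cell is zero (flagged), and a two-sided Fisher
#' exact p-value.
#'
#' @param query_regions GRanges (the predicted set; matched to universe rows
#'   by overlap).
#' @param validated_positives GRanges of validated regions.
#' @param universe GRanges of all evaluable regions.
#' @return list `or`, `p`, `table`, `corrected` (logical).
#' @export
overlap_odds_ratio <- function(query_regions, validated_positives, universe) {
  if (length(universe) == 0L) stop("empty universe")
  in_query <- countOverlaps(universe, query_regions) > 0
  hits_val <- countOverlaps(universe, validated_positives) > 0
  a <- sum(in_query & hits_val); b <- sum(in_query & !hits_val)
  cc <- sum(!in_query & hits_val); d <- sum(!in_query & !hits_val)
  tab <- matrix(c(a, cc, b, d), 2,
                dimnames = list(c("query", "rest"),
                                c("validated", "not")))
  corrected <- any(tab == 0)
  or <- if (corrected) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  p <- fisher.test(tab)$p.value
  list(or = or, p = p, table = tab, corrected = corrected)
}
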