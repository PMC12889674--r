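#' The eight descriptive chromatin states
#'
#' Active (Chr-A), poised (Chr-Po), primed (Chr-Pr), open-only (Chr-O),
#' repressed (Chr-R), Polycomb heterochromatin (Hc-P), H3K9me3
#' heterochromatin (Hc-H) and not-determined (ND).
#'
#' @export
CHROMATIN_STATES_8 <- c("Chr-A", "Chr-Po", "Chr-Pr", "Chr-O",
                        "Chr-R", "Hc-P", "Hc-H", "ND")

#' Emission-vector agreement between a query and a full model
#'
#' For every state of the full model, the maximum Pearson correlation of its
#' emission vector with any query-model state; the mean and median of these
#' per-state maxima summarize how completely the query represents the full
#' model. A query identical to the full model scores 1. Zero-variance
#' emission vectors (which cannot occur with clamped emissions) correlate as
#' 0 and are flagged.
#'
#' @param full_model,query_model `bhmm` objects (or lists with an `emissions`
#'   matrix) over the same marks.
#' @return list with `per_state_max`, `mean`, `median`, and
#'   `zero_variance_flag`.
#' @export
emission_match_score <- function(full_model, query_model) {
  Ef <- emissions_of(full_model); Eq <- emissions_of(query_model)
  if (ncol(Ef) != ncol(Eq)) stop("mark sets differ")
  zv_f <- apply(Ef, 1, function(v) stats::var(v) == 0)
  zv_q <- apply(Eq, 1, function(v) stats::var(v) == 0)
  cc <- matrix(0, nrow(Ef), nrow(Eq))
  ok_f <- which(!zv_f); ok_q <- which(!zv_q)
  if (length(ok_f) && length(ok_q))
    cc[ok_f, ok_q] <- stats::cor(t(Ef[ok_f, , drop = FALSE]),
                          t(Eq[ok_q, , drop = FALSE]))
  per_state_max <- apply(cc, 1, max)
  list(per_state_max = per_state_max,
       mean = mean(per_state_max), median = stats::median(per_state_max),
       zero_variance_flag = any(zv_f) || any(zv_q))
}

emissions_of <- function(m) {
  E <- if (inherits(m, "bhmm") || is.list(m)) m$emissions else m
  as.matrix(E)
}

#' Cluster-separation ratio of a model's emission vectors
#'
#' K-means (25 restarts, seeded) on the full model's emission vectors with
#' `k` clusters; returns the between-cluster sum of squares over the total
#' sum of squares (the fraction of emission variance a k-cluster grouping
#' explains). k = 1 gives 0; k at least the number of distinct vectors
#' gives 1.
#'
#' @param full_model a `bhmm` (or emissions matrix).
#' @param k number of clusters.
#' @param seed seed for the k-means restarts.
#' @return ratio in \[0, 1\].
#' @export
separation_ratio <- function(full_model, k, seed = 1L) {
  E <- emissions_of(full_model)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(0)
  uniq <- unique(E)
  tss <- sum(scale(E, scale = FALSE)^2)
  if (tss == 0) return(1)
  if (k >= nrow(uniq)) return(1)  # every distinct vector its own cluster
  with_seed(substream(seed, 31L), {
    km <- kmeans(E, centers = k, nstart = 25L)
    1 - km$tot.withinss / km$totss
  })
}

#' Choose the number of chromatin states
#'
#' Two-criterion selection against a designated full model: a candidate
#' passes when (1) its emission-correlation summary (the mean of the
#' per-full-state maxima by default; the median is co-reported and may be
#' selected on instead) exceeds `corr_threshold` and (2) the full model's
#' cluster-separation ratio at k = the candidate's state count reaches
#' `sep_threshold` of the full model's own (maximal) separation. The chosen
#' model is the smallest passing candidate; absence of one is a reported
#' outcome, not an error.
#'
#' @param candidates named or unnamed list of `bhmm` candidate models.
#' @param full_model the full (redundant) reference model.
#' @param corr_threshold default 0.99 (0.85 is the "acceptable" level).
#' @param sep_threshold default 0.95 of the full model's separation.
#' @param summary `"mean"` (default) or `"median"`. The mean reacts to a
#'   single unrepresented full-model state, which the median of many
#'   per-state maxima does not; both are always reported.
#' @param seed seed for the k-means restarts.
#' @return a `selection_report`: data frame with per-candidate `n_states`,
#'   `corr_mean`, `corr_median`, `separation`, `pass_corr`, `pass_sep`,
#'   `pass`; attribute `chosen` (state count or NA).
#' @export
select_state_number <- function(candidates, full_model,
                                corr_threshold = 0.99, sep_threshold = 0.95,
                                summary = c("mean", "median"), seed = 1L) {
  summary <- match.arg(summary)
  if (!length(candidates)) stop("candidate list is empty")
  rows <- lapply(candidates, function(m) {
    ms <- emission_match_score(full_model, m)
    k <- nrow(emissions_of(m))
    sep <- separation_ratio(full_model, k, seed = seed)
    data.frame(n_states = k, corr_mean = ms$mean, corr_median = ms$median,
               separation = sep)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$n_states), , drop = FALSE]
  stat <- if (summary == "median") rep$corr_median else rep$corr_mean
  rep$pass_corr <- stat > corr_threshold
  rep$pass_sep <- rep$separation >= sep_threshold
  rep$pass <- rep$pass_corr & rep$pass_sep
  chosen <- if (any(rep$pass)) min(rep$n_states[rep$pass]) else NA_integer_
  structure(rep, chosen = chosen,
            thresholds = c(corr = corr_threshold, sep = sep_threshold),
            summary = summary, class = c("selection_report", "data.frame"))
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "state-number selection (%s correlation > %.2f, separation >= %.2f)\n",
    attr(x, "summary"), attr(x, "thresholds")["corr"],
    attr(x, "thresholds")["sep"]))
  print.data.frame(round_df(x), row.names = FALSE)
  ch <- attr(x, "chosen")
  cat(if (is.na(ch)) "no candidate passes both criteria\n"
      else sprintf("chosen: %d states\n", ch))
  invisible(x)
}

round_df <- function(df, digits = 4) {
  df[] <- lapply(df, function(c) if (is.numeric(c)) round(c, digits) else c)
  as.data.frame(df)
}

#' The packaged 18-to-8 state consolidation map
#'
#' The consolidation of an 18-state model into the eight descriptive states,
#' keyed by the original state identifiers: \{3,4,5,9,12,13\} active,
#' \{6,8\} poised, \{2\} primed, \{11\} open, \{7,10,14\} repressed,
#' \{15,16\} Polycomb heterochromatin, \{17\} H3K9me3 heterochromatin,
#' \{0,18\} not determined.
#'
#' @return named character vector: names are original state ids, values
#'   descriptive state names.
#' @export
state_map_18to8 <- function() {
  c(`0` = "ND", `2` = "Chr-Pr", `3` = "Chr-A", `4` = "Chr-A", `5` = "Chr-A",
    `6` = "Chr-Po", `7` = "Chr-R", `8` = "Chr-Po", `9` = "Chr-A",
    `10` = "Chr-R", `11` = "Chr-O", `12` = "Chr-A", `13` = "Chr-A",
    `14` = "Chr-R", `15` = "Hc-P", `16` = "Hc-P", `17` = "Hc-H",
    `18` = "ND")
}

#' Read / write a state mapping file
#'
#' Two-column TSV: state_id, descriptive_name.
#'
#' @param path file path.
#' @export
read_state_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", colClasses = "character",
                          col.names = c("state_id", "name"))
  setNames(df$name, df$state_id)
}

#' @rdname read_state_map
#' @param mapping named character vector (names = state ids).
#' @export
write_state_map <- function(mapping, path) {
  utils::write.table(data.frame(names(mapping), unname(mapping)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Consolidate learned states into descriptive states
#'
#' Relabels a segmentation through a total state mapping and re-estimates
#' the consolidated emission matrix from the binarized data (via
#' [recompute_emissions()]).
#'
#' @param seg a `segmentation` whose labels are learned state ids.
#' @param mapping named character vector mapping every learned state id to a
#'   descriptive name (e.g. [state_map_18to8()]).
#' @param data the `binarized_matrix` the segmentation was decoded from.
#' @param state_names vocabulary of the consolidated segmentation; defaults
#'   to the 8 descriptive states present in the mapping.
#' @return list with `segmentation` (relabeled) and `emissions`
#'   (consolidated states x marks).
#' @export
consolidate_states <- function(seg, mapping, data, state_names = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  unmapped <- setdiff(unique(seg$labels), names(mapping))
  if (length(unmapped))
    stop("unmapped state id(s): ", paste(unmapped, collapse = ", "))
  if (is.null(state_names)) {
    state_names <- CHROMATIN_STATES_8[CHROMATIN_STATES_8 %in% mapping]
    if (!length(state_names)) state_names <- unique(unname(mapping))
  }
  new_seg <- segmentation(seg$grid, unname(mapping[seg$labels]),
                          state_names, cell_type = seg$cell_type)
  list(segmentation = new_seg,
       emissions = recompute_emissions(new_seg, data))
}

#' Heuristic descriptive-state labeling of learned states
#'
#' Suggests a mapping from learned states to the eight descriptive states by
#' nearest preset emission archetype (Euclidean distance). Consolidation in
#' practice also weighs coverage patterns and gene activity, so this is a
#' starting suggestion, never applied silently: pass its result to
#' [consolidate_states()] explicitly.
#'
#' @param model a `bhmm` over the marks of [preset_emissions_8()].
#' @param archetypes optional states x marks archetype matrix.
#' @return named character vector keyed by the model's state names.
#' @export
suggest_state_labels <- function(model, archetypes = NULL) {
  if (is.null(archetypes)) archetypes <- preset_emissions_8()
  E <- emissions_of(model)
  if (ncol(E) != ncol(archetypes)) stop("mark sets differ")
  idx <- apply(E, 1, function(v)
    which.min(colSums((t(archetypes) - v)^2)))
  setNames(rownames(archetypes)[idx], model$state_names)
}
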