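#' Preset emission archetypes for the eight descriptive states
#'
#' Hand-set Bernoulli emission parameters over the five assayed marks (ATAC,
#' H3K27ac, H3K27me3, H3K4me1, H3K9me3), chosen to qualitatively mirror the
#' consolidated chromatin-state scheme: active chromatin high on ATAC /
#' H3K27ac / H3K4me1, poised chromatin co-presenting H3K4me1 and H3K27me3
#' with accessibility, primed chromatin H3K4me1-only, open chromatin
#' ATAC-only, repressed chromatin H3K27me3 plus one active mark, Polycomb
#' heterochromatin H3K27me3-only, H3K9me3 heterochromatin H3K9me3-only, and
#' ND with essentially no marks (a faint ATAC-leaning gradient keeps the
#' vector non-constant so Pearson correlations stay defined, mirroring the
#' slight open-chromatin bias of Tn5-based assays). These are package
#' constants for simulation, not measured values. Every pair of states
#' differs by at least 0.3 in some mark.
#'
#' @return 8 x 5 matrix with state and mark dimnames.
#' @export
preset_emissions_8 <- function() {
  marks <- c("ATAC", "H3K27ac", "H3K27me3", "H3K4me1", "H3K9me3")
  E <- rbind(
    `Chr-A`  = c(0.90, 0.90, 0.05, 0.80, 0.05),
    `Chr-Po` = c(0.50, 0.40, 0.70, 0.80, 0.05),
    `Chr-Pr` = c(0.05, 0.05, 0.05, 0.80, 0.05),
    `Chr-O`  = c(0.90, 0.05, 0.05, 0.05, 0.05),
    `Chr-R`  = c(0.10, 0.05, 0.80, 0.50, 0.05),
    `Hc-P`   = c(0.05, 0.05, 0.85, 0.05, 0.10),
    `Hc-H`   = c(0.05, 0.05, 0.05, 0.05, 0.85),
    `ND`     = c(0.03, 0.02, 0.02, 0.02, 0.01))
  colnames(E) <- marks
  E
}

# per-state Beta(alpha, beta) shapes for mCG fractions: active chromatin
# hypomethylated, constitutive heterochromatin hypermethylated
preset_meth_params_8 <- function() {
  cbind(alpha = c(2, 3, 5, 4, 6, 5, 8, 7),
        beta = c(8, 5, 5, 6, 4, 5, 2, 3))
}

#' Build a ground-truth generative model
#'
#' Assembles the generative model behind the synthetic cohorts: a hidden
#' Markov chain over chromatin states with Bernoulli mark emissions,
#' per-state Beta laws for methylation fractions, and peak-noise parameters.
#' With the default 8 states and 5 marks, the preset descriptive-state
#' archetypes are used; other shapes get seeded random (row-stochastic /
#' unit-interval) parameters.
#'
#' @param n_states K (default 8).
#' @param n_marks M (default 5).
#' @param seed integer seed; identical arguments and seed give an identical
#'   model.
#' @param overrides named list overriding any of `initial`, `transitions`,
#'   `emissions`, `meth_params`, `state_names`, `dropout`, `jitter`.
#'   Non-stochastic `initial`/`transitions` are rejected.
#' @return an object of class `ground_truth_model`.
#' @export
build_ground_truth <- function(n_states = 8L, n_marks = 5L, seed = 1L,
                               overrides = list()) {
  K <- as.integer(n_states); M <- as.integer(n_marks)
  if (K < 1L || M < 1L) stop("n_states and n_marks must be >= 1")
  preset <- (K == 8L && M == 5L)
  model <- with_seed(substream(seed, 1L), {
    if (preset) {
      E <- preset_emissions_8()
      mp <- preset_meth_params_8()
      states <- rownames(E); marks <- colnames(E)
    } else {
      E <- matrix(runif(K * M, 0.02, 0.98), K, M)
      mp <- cbind(alpha = runif(K, 1, 8), beta = runif(K, 1, 8))
      states <- paste0("S", seq_len(K))
      marks <- paste0("mark", seq_len(M))
      dimnames(E) <- list(states, marks)
    }
    A <- matrix(if (K > 1) 0.05 / (K - 1) else 0, K, K)
    diag(A) <- if (K > 1) 0.95 else 1
    list(n_states = K, n_marks = M, state_names = states, mark_names = marks,
         initial = rep(1 / K, K), transitions = A, emissions = E,
         meth_params = mp, dropout = 0.1, jitter = 50L)
  })
  for (nm in names(overrides)) {
    if (!nm %in% names(model)) stop("unknown override: ", nm)
    model[[nm]] <- overrides[[nm]]
  }
  validate_ground_truth(model)
  structure(model, class = "ground_truth_model")
}

validate_ground_truth <- function(m) {
  K <- m$n_states
  if (abs(sum(m$initial) - 1) > 1e-9 || any(m$initial < 0))
    stop("initial must be a probability vector")
  if (!is.matrix(m$transitions) || any(dim(m$transitions) != K) ||
      any(m$transitions < 0) ||
      any(abs(rowSums(m$transitions) - 1) > 1e-9))
    stop("transitions must be a K x K row-stochastic matrix")
  if (any(m$emissions < 0 | m$emissions > 1))
    stop("emissions must lie in [0, 1]")
  if (any(m$meth_params <= 0)) stop("Beta shapes must be positive")
  if (m$dropout < 0 || m$dropout > 1) stop("dropout must lie in [0, 1]")
  if (m$jitter < 0) stop("jitter must be >= 0")
  invisible(m)
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("ground_truth_model: %d states (%s), %d marks\n",
              x$n_states, paste(x$state_names, collapse = ", "), x$n_marks))
  invisible(x)
}

#' Simulate one cell type's tracks
#'
#' Draws the hidden state path from the model's Markov chain (restarting at
#' chromosome starts), the binary mark matrix from the per-state Bernoulli
#' emissions, and a methylation track whose per-bin fraction follows the
#' state's Beta law with Poisson coverage. Zero-coverage bins are carried as
#' missing (total 0), not as zero methylation.
#'
#' @param model a `ground_truth_model`.
#' @param grid a `bin_grid`.
#' @param seed integer seed.
#' @param coverage_mean Poisson mean of per-bin methylation coverage
#'   (default 20).
#' @param cell_type label.
#' @return list with `path` (integer state indices), `states` (labels),
#'   `data` (a `binarized_matrix`) and `meth` (a [methyl_track()]).
#' @export
simulate_cell_type_tracks <- function(model, grid, seed = 1L,
                                      coverage_mean = 20, cell_type = "cell") {
  stopifnot(inherits(model, "ground_truth_model"), inherits(grid, "bin_grid"))
  if (grid$total_bins < 1L) stop("grid is empty")
  with_seed(substream(seed, 2L), {
    K <- model$n_states
    path <- integer(grid$total_bins)
    for (rows in chrom_row_ranges(grid)) {
      path[rows[1]] <- sample.int(K, 1, prob = model$initial)
      for (t in rows[-1])
        path[t] <- sample.int(K, 1, prob = model$transitions[path[t - 1L], ])
    }
    V <- matrix(rbinom(grid$total_bins * model$n_marks, 1,
                       model$emissions[path, , drop = FALSE]),
                nrow = grid$total_bins)
    colnames(V) <- model$mark_names
    total <- rpois(grid$total_bins, coverage_mean)
    frac <- rbeta(grid$total_bins, model$meth_params[path, "alpha"],
                  model$meth_params[path, "beta"])
    met <- rbinom(grid$total_bins, total, frac)
    list(path = path, states = model$state_names[path],
         data = binarized_matrix(grid, V, model$mark_names, cell_type),
         meth = methyl_track(grid, met, total))
  })
}

#' Replicate peak sets with dropout and boundary jitter
#'
#' Converts maximal runs of present bins of one binary mark column into
#' bp intervals, then emulates replicate-level peak calling: each replicate
#' independently drops every interval with probability `dropout` and
#' perturbs both boundaries by at most `jitter` bp (clipped to chromosome
#' bounds). Scores are positive draws.
#'
#' @param binary_track 0/1 vector over the grid's bins (one mark column).
#' @param grid a `bin_grid`.
#' @param n_replicates number of replicates (>= 1).
#' @param dropout per-interval drop probability in \[0, 1\].
#' @param jitter maximal boundary perturbation in bp (>= 0).
#' @param seed integer seed.
#' @return list of scored GRanges, one per replicate.
#' @export
simulate_replicate_peaks <- function(binary_track, grid, n_replicates = 2L,
                                     dropout = 0.1, jitter = 0L, seed = 1L) {
  stopifnot(inherits(grid, "bin_grid"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (jitter < 0) stop("jitter must be >= 0")
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  lab <- ifelse(binary_track == 1L, "on", "off")
  seg <- segmentation(grid, lab, c("off", "on"))
  base <- seg_intervals(seg, "on")
  with_seed(substream(seed, 3L), {
    lapply(seq_len(n_replicates), function(r) {
      n <- length(base)
      if (n == 0L) return(empty_scored())
      keep <- runif(n) >= dropout
      gr <- base[keep]
      if (length(gr) == 0L) return(empty_scored())
      lens <- grid$chrom_sizes[as.character(seqnames(gr))]
      j1 <- sample(-jitter:jitter, length(gr), replace = TRUE)
      j2 <- sample(-jitter:jitter, length(gr), replace = TRUE)
      s0 <- pmax(0, start(gr) - 1L + j1)
      e0 <- pmin(unname(lens), end(gr) + j2)
      bad <- s0 >= e0
      s0[bad] <- start(gr[bad]) - 1L; e0[bad] <- end(gr[bad])
      out <- GRanges(seqnames(gr), IRanges(s0 + 1L, e0))
      mcols(out)$score <- runif(length(out), 1, 100)
      sort(out)
    })
  })
}

#' Simulate a species-mixing (barnyard) pool
#'
#' Each barcode is a singlet of species A (probability `frac_species_a`) or
#' B, or — with probability `multiplet_rate` — a multiplet of two
#' independently drawn cells. Per-species read counts are drawn so singlets
#' carry 98% of reads from their own species in expectation (ambient
#' contamination 2%), comfortably above the 75% species-assignment rule.
#' Truth labels are stored for estimator validation.
#'
#' @param n_barcodes pool size.
#' @param frac_species_a proportion of species-A cells in (0, 1).
#' @param multiplet_rate true multiplet probability in \[0, 1).
#' @param reads_per_cell mean reads contributed by one cell (default 2000).
#' @param seed integer seed.
#' @return data frame: `barcode`, `reads_species_a`, `reads_species_b`,
#'   `true_type` ("singlet-A", "singlet-B", "multiplet"),
#'   `true_cross` (logical: multiplet pairing unlike species).
#' @export
simulate_species_mix <- function(n_barcodes, frac_species_a = 0.5,
                                 multiplet_rate = 0.05,
                                 reads_per_cell = 2000, seed = 1L) {
  if (frac_species_a <= 0 || frac_species_a >= 1)
    stop("frac_species_a must lie in (0, 1)")
  if (multiplet_rate < 0 || multiplet_rate >= 1)
    stop("multiplet_rate must lie in [0, 1)")
  with_seed(substream(seed, 4L), {
    n <- as.integer(n_barcodes)
    is_mult <- runif(n) < multiplet_rate
    own_frac <- 0.98
    draw_cell <- function(m) {
      # m: logical, cell is species A
      tot <- rpois(length(m), reads_per_cell)
      a_frac <- ifelse(m, own_frac, 1 - own_frac)
      a <- rbinom(length(m), tot, a_frac)
      cbind(a = a, b = tot - a)
    }
    c1 <- runif(n) < frac_species_a
    c2 <- runif(n) < frac_species_a
    r1 <- draw_cell(c1)
    r2 <- draw_cell(c2)
    reads_a <- r1[, "a"] + ifelse(is_mult, r2[, "a"], 0L)
    reads_b <- r1[, "b"] + ifelse(is_mult, r2[, "b"], 0L)
    data.frame(
      barcode = sprintf("BC%06d", seq_len(n)),
      reads_species_a = reads_a,
      reads_species_b = reads_b,
      true_type = ifelse(!is_mult, ifelse(c1, "singlet-A", "singlet-B"),
                         "multiplet"),
      true_cross = is_mult & (c1 != c2),
      stringsAsFactors = FALSE)
  })
}

#' Simulate an enhancer-validation outcome table
#'
#' Emulates reporter-assay outcomes: a region is experimentally positive in
#' a cell type iff the activity rule holds (by default, the chromatin state
#' at the region center is Chr-A in that cell type's segmentation), with
#' each outcome independently flipped with probability `flip_noise`.
#' Entries can be left untested.
#'
#' @param cre_set GRanges of tested regions (names or `name` column used as
#'   region ids).
#' @param segmentations named list of `segmentation` objects, one per cell
#'   type.
#' @param active_state state label that defines a positive (default
#'   "Chr-A").
#' @param flip_noise outcome flip probability in \[0, 1\].
#' @param untested_frac fraction of entries marked untested (default 0).
#' @param seed integer seed.
#' @return data frame `region_id`, `cell_type`, `outcome` in
#'   \{"positive", "negative", "untested"\}.
#' @export
simulate_validation_table <- function(cre_set, segmentations,
                                      active_state = "Chr-A",
                                      flip_noise = 0, untested_frac = 0,
                                      seed = 1L) {
  if (!length(segmentations) || is.null(names(segmentations)))
    stop("segmentations must be a named list")
  ids <- region_ids(cre_set)
  with_seed(substream(seed, 5L), {
    out <- do.call(rbind, lapply(names(segmentations), function(ct) {
      ann <- annotate_cre_state(cre_set, segmentations[[ct]], cell_type = ct)
      pos <- ann$state == active_state
      flip <- runif(length(pos)) < flip_noise
      outcome <- ifelse(xor(pos, flip), "positive", "negative")
      outcome[runif(length(pos)) < untested_frac] <- "untested"
      data.frame(region_id = ids, cell_type = ct, outcome = outcome,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

region_ids <- function(gr) {
  mc <- mcols(gr)
  if ("name" %in% colnames(mc)) return(as.character(mc$name))
  if (!is.null(names(gr)) && all(nzchar(names(gr)))) return(names(gr))
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' Nested model family with a known number of emission archetypes
#'
#' Builds the candidate family used to validate state-number selection:
#' exactly `k0` distinct emission archetypes exist (the 8 descriptive-state
#' presets by default). A candidate with K states carries the first
#' min(K, k0) archetypes; candidates larger than `k0`, and the full
#' reference model, pad with jittered duplicates of well-separated
#' archetypes (the near-degenerate ND vector is never duplicated, since a
#' noise-dominated copy of an almost-constant vector carries no correlation
#' signal). Only candidates with K >= k0 represent every archetype, so a
#' sound selector must choose `k0`.
#'
#' @param seed integer seed for the duplicate jitter.
#' @param k_range candidate state counts (default 4:12).
#' @param n_full states in the full reference model (default 12).
#' @param k0 number of true archetypes (default 8).
#' @param jitter_sd jitter on duplicated archetypes (default 0.01).
#' @return list with `candidates` (list of emission-matrix models, named
#'   "K<k>") and `full`.
#' @export
nested_selection_family <- function(seed = 1L, k_range = 4:12,
                                    n_full = 12L, k0 = 8L,
                                    jitter_sd = 0.01) {
  arch <- preset_emissions_8()[seq_len(k0), , drop = FALSE]
  dup_pool <- seq_len(min(k0, 7L))  # skip the near-constant ND archetype
  with_seed(substream(seed, 41L), {
    pad <- function(K) {
      idx <- c(seq_len(min(K, k0)),
               if (K > k0) sample(dup_pool, K - k0, replace = TRUE))
      E <- arch[idx, , drop = FALSE]
      if (K > k0) {
        extra <- (k0 + 1):K
        E[extra, ] <- pmin(pmax(
          E[extra, , drop = FALSE] +
            matrix(stats::rnorm(length(extra) * ncol(E), 0, jitter_sd),
                   length(extra)), 0.001), 0.999)
      }
      rownames(E) <- NULL
      list(emissions = E)
    }
    cands <- lapply(k_range, pad)
    names(cands) <- paste0("K", k_range)
    list(candidates = cands, full = pad(n_full))
  })
}

#' Simulate a multi-cell-type synthetic cohort
#'
#' Convenience wrapper tying the generators together: one ground-truth
#' model, one grid, and per cell type a hidden path, binarized matrix,
#' replicate peak sets per mark, and a methylation track.
#'
#' @param model a `ground_truth_model`.
#' @param grid a `bin_grid`.
#' @param cell_types character vector of cell-type labels.
#' @param n_replicates replicate peak sets per mark (default 2).
#' @param seed integer seed.
#' @return list of per-cell-type lists (`path`, `states`, `data`, `meth`,
#'   `replicate_peaks`), plus `model`, `grid`, `seed`.
#' @export
simulate_cohort <- function(model, grid, cell_types = c("typeA", "typeB"),
                            n_replicates = 2L, seed = 1L) {
  ct_list <- lapply(seq_along(cell_types), function(i) {
    tr <- simulate_cell_type_tracks(model, grid,
                                    seed = substream(seed, 200L + i),
                                    cell_type = cell_types[i])
    tr$replicate_peaks <- lapply(seq_len(model$n_marks), function(m)
      simulate_replicate_peaks(tr$data$values[, m], grid, n_replicates,
                               dropout = model$dropout,
                               jitter = model$jitter,
                               seed = substream(seed, 300L + 10L * i + m)))
    names(tr$replicate_peaks) <- model$mark_names
    tr
  })
  names(ct_list) <- cell_types
  list(cell_types = ct_list, model = model, grid = grid, seed = seed)
}
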