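---
title: "Chromatin-state modeling and regulatory-genome annotation with epistate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state modeling and regulatory-genome annotation with epistate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistate)
```

## The model

`epistate` annotates the regulatory genome of one or more cell types from
binarized chromatin tracks. Its core is a hidden Markov model over a binned
genome: each bin carries a hidden chromatin state $s_t \in \{1,\dots,K\}$,
and conditional on the state the $M$ assayed marks (chromatin accessibility
and histone modifications) are independent Bernoulli draws,

$$P(v_{t} \mid s_t = k) \;=\; \prod_{m=1}^{M} E_{km}^{\,v_{tm}}
  (1 - E_{km})^{1 - v_{tm}},$$

with emission matrix $E \in [0,1]^{K \times M}$, row-stochastic transition
matrix $A$, and initial distribution $\pi$. This is the model class of
ChromHMM. Chromosomes are treated as independent sequences: the chain is
re-initialized from $\pi$ at every chromosome start, matching the
per-chromosome independence of genome segmentation tools.

Key modeling assumptions worth keeping in mind:

* **Conditional independence of marks given the state.** Co-occurrence
  structure between marks is carried entirely by the states; within a state,
  marks do not interact.
* **Binary presence calls.** Signal strength is discarded at binarization;
  a bin either shows a mark or it does not (any 1-bp overlap with a peak
  sets the bin, the BinarizeBed convention).
* **First-order Markov dependence along the genome** at a fixed bin size
  (default 200 bp, ChromHMM's convention; the bin size is a parameter of
  `bin_genome()`).

## Fitting, decoding, re-estimation

`hmm_fit()` maximizes the likelihood by Baum–Welch EM with log-space
forward–backward recursions (no scaling-factor variant; the log-space form
is uniformly robust at these problem sizes). Numerical choices:

* Emissions are clamped to $[10^{-6}, 1 - 10^{-6}]$ after every M-step, so
  no emission log-probability is ever $-\infty$ and Pearson correlations
  between emission vectors are always defined.
* Initialization is a quantile heuristic: bins are ranked by their total
  mark count and split into $K$ equal groups; group-wise mark frequencies,
  plus a small seeded uniform jitter ($\pm 0.05$), seed $E$. $A$ starts
  sticky (0.9 on the diagonal), $\pi$ uniform. EM only guarantees a local
  optimum, so `n_restarts` (default 3) independently jittered starts are
  fitted and the best log-likelihood kept. On well-separated synthetic data
  a single restart finds the global basin in most runs but not all; three
  restarts were sufficient in every seeded experiment in the test suite.
* Convergence is declared when the log-likelihood gain drops below `tol`
  (default $10^{-3}$) or after `max_iter` (default 200) iterations. The
  per-iteration log-likelihood trace is stored in `train_log` and is
  non-decreasing up to the clamping.

`predict()` / `viterbi_segment()` decodes the most probable state path per
chromosome; ties are broken toward the lower state index so decoding is
deterministic. One property of optimal decoding deserves a note: on
degenerate data whose emission scores are identical in every bin (for
example, all marks absent everywhere), the optimal path is *almost*
constant — it may hop once from the best initial state into the state with
the best self-transition and then stay. The test suite asserts exactly
that, rather than strict constancy.

`recompute_emissions()` re-estimates the emission matrix of any
segmentation as the per-state mark frequencies of the binarized data.
States with no assigned bins get an `NA` row and are flagged rather than
silently zeroed.

## Choosing the number of states and consolidating

`select_state_number()` implements a two-criterion procedure against a
deliberately redundant "full" model:

1. **Emission correlation.** For every full-model state, the maximum
   Pearson correlation of its emission vector over the query model's
   states; a query that represents every full state well scores near 1.
   Correlations above 0.85 are conventionally acceptable and above 0.99
   satisfactory. Both the mean and the median of the per-state maxima are
   reported. **The selection default is the mean**: with a redundant full
   model, a query missing one archetype degrades only one or two of the
   per-state maxima, which the median of a dozen values simply cannot see;
   the mean reacts to every unrepresented state. The median remains
   co-reported and can be selected on (`summary = "median"`) for users who
   prefer the stricter-sounding ">0.99 median" convention.
2. **Cluster separation.** k-means (25 restarts, seeded) on the full
   model's emission vectors with $k$ equal to the candidate's state count;
   the criterion is the between-cluster over total sum of squares
   (BSS/TSS), required to reach 95% of the full model's own separation.
   The full model's own separation — clustering its $K_{full}$ vectors
   into $K_{full}$ singletons — is exactly 1, so the reference is taken as
   1. This is the only reading of the construction under which the
   statistic varies with $k$; clustering each query's own vectors with
   $k =$ its own state count is identically 1 and discriminates nothing.
   When $k$ at least equals the number of *distinct* vectors the ratio is
   returned as exactly 1 without invoking `kmeans()` (duplicates are free).

The chosen model is the smallest candidate passing both criteria; if none
passes, the report says so rather than erroring.

`consolidate_states()` maps learned states onto the eight descriptive
states — active (Chr-A), poised (Chr-Po), primed (Chr-Pr), open-only
(Chr-O), repressed (Chr-R), Polycomb heterochromatin (Hc-P), H3K9me3
heterochromatin (Hc-H) and not-determined (ND) — and re-estimates the
consolidated emissions from the data. The mapping is always an explicit
input (`state_map_18to8()` ships the canonical 18-state assignment, also
as `inst/extdata/state_map_18to8.tsv`): consolidation in practice weighs
coverage heatmaps and gene activity, judgments that cannot be reproduced
from emissions alone, so `suggest_state_labels()` (nearest emission
archetype) is offered as a starting point but never applied silently.

## Cross-cell-type statistics

* `conservation_proportion()` follows the best-single-overlap rule: for
  each maximal same-state interval of the reference cell type, only the
  one most-overlapping same-state interval of the comparator contributes,
  and the proportion is summed overlap over summed reference length. A
  reference interval covered by two disjoint comparator intervals of 40%
  each therefore scores 0.4, not 0.8. Comparisons are in bp space, so
  segmentations of different bin sizes are comparable.
* `state_variation()` is the population variance (divide by $n$) of the
  conservation proportions over a fixed comparator set — the comparators
  are the population of interest, not a sample from one.
* `transition_summary()` counts *intervals*: each maximal source-state
  interval is assigned the target state covering the plurality of its
  bases (ties toward the earlier vocabulary state). Interval units match
  how region counts are reported in practice; bin-level accounting is
  available via `units = "bins"`. Row percentages are kept exact and
  displayed under a convention: `"nearest"` rounding by default,
  `"truncate"` optionally — published transition tables mix both (a row of
  44.12% prints as 44 under either; 42.69% prints as 42 only under
  truncation), so `row_percentages()` exposes the choice.
* `methylation_by_state()` pools counts ($\sum \text{met} / \sum
  \text{total}$) rather than averaging per-bin fractions, so
  high-coverage bins carry their evidence; zero-coverage states are
  flagged missing. `stratify_signal_by_methylation()` cuts regions at
  mCG fractions 0.2 and 0.8 (Low strictly below 0.2, High strictly above
  0.8, boundaries belong to Medium) and compares strata with Welch
  t-tests — the safer unequal-variance default where only "t test" is
  conventional — under Benjamini–Hochberg correction.

## cCRE annotation and enhancer evaluation

`annotate_cre_state()` assigns each candidate cis-regulatory element the
state of the bin containing its center, $\lfloor(start+end)/2\rfloor$, or
its summit when a summit offset is recorded. `differential_regions()`
substitutes a per-region two-sided Fisher exact test on detection counts
for external single-cell differential testers: only the thresholds
(adjusted $p < 0.05$, $|\log_2 FC| \ge 0.2$ on pseudocounted detection
rates, `min_pct = 0.01`, direction `"positive"` for activating marks and
`"both"` for repressive ones) are prescribed by the procedure being
reproduced, and an exact test honors them without further dependencies.

`enhancer_eval()` scores predictions at the (region, cell type) entry
level: precision $= TP/(TP+FP)$, recall $= TP / \text{all positive
entries}$, and specificity $= 1 - FP/(N_{regions} \times N_{celltypes})$.
Entry-level units are the only ones under which the specificity
denominator is coherent. Putative outcomes count as positive by default
(configurable). `overlap_odds_ratio()` reports $ad/bc$ with the
Haldane–Anscombe 0.5 correction (flagged) when a cell is zero, with a
two-sided Fisher exact p-value.

`scaled_region_profile()` reproduces scale-regions semantics: regions are
linearly rescaled to 500 bp, averaged in 10-bp windows (50 output bins),
positions without track data count as zero, and minus-strand regions are
reversed.

## The synthetic-epigenome generator

Every downstream stage is exercised on cohorts with known ground truth.
`build_ground_truth()` assembles a generative model whose defaults are the
study conditions of the test suite:

* **Emissions**: hand-set archetypes for the eight descriptive states over
  ATAC, H3K27ac, H3K27me3, H3K4me1, H3K9me3 (`preset_emissions_8()`), with
  every pair of states at least 0.3 apart in some mark. The ND row is
  nearly, but not exactly, flat (0.03 ATAC down to 0.01 H3K9me3): an
  exactly constant vector has undefined Pearson correlation, and the faint
  ATAC lean mirrors the open-chromatin bias of Tn5-based assays.
* **Transitions**: sticky, 0.95 self-transition, remainder uniform —
  chromatin states form multi-bin domains.
* **Methylation**: per-state Beta laws for the mCG fraction (active
  chromatin hypomethylated, constitutive heterochromatin hypermethylated),
  binomial counts at Poisson coverage (mean 20). Zero-coverage bins are
  carried as missing, never as zero methylation.
* **Peak noise**: replicate peak sets are derived from the binary track's
  maximal runs with per-interval dropout (default 0.1) and boundary jitter
  (default 50 bp), emulating replicate-level peak calling.
* **Species mixing**: barnyard pools draw each barcode as a singlet or,
  with the multiplet rate, as a pair of independently drawn cells; singlets
  carry 98% own-species reads in expectation, comfortably above the 75%
  assignment rule, so classification noise does not confound the estimator
  being tested.

Randomness is controlled by one integer seed expanded into fixed per-
operation substreams, so adding one simulation to a cohort never shifts
the draws of the others, and any operation re-run with the same seed is
bit-identical.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level noise and mappability artifacts,
copy-number and blacklist regions, mark-specific peak shapes (narrow vs
broad), spatial covariation of methylation with CpG density, doublet
*score* generation (scores are inputs; only rate-matched removal is in
scope), and any violation of the conditional-independence assumption
itself. Recovery results on these cohorts demonstrate correctness of the
algorithms under the model, not robustness to real-data misspecification.

## Problem sizes and validation design

The bundled experiments use 50,000 bins (two chromosomes, 200-bp bins) for
parameter recovery — at that size empirical per-state mark frequencies sit
within 0.03 of the generating emissions, EM recovers emissions to within
0.05 in the max norm after best-match alignment, and Viterbi decoding
exceeds 90% accuracy against the true path. State-number selection is
validated on constructed nested families (`nested_selection_family()`)
with exactly eight archetypes: duplicated states are jittered copies of
well-separated archetypes (the near-degenerate ND vector is never
duplicated, since a noise-dominated copy of an almost-constant vector
carries no correlation signal). The species-mixing estimator
$\hat r = d / (2p(1-p))$ — the standard correction for unobserved
same-species collisions, standing in for the cited extrapolation method —
is validated at $n = 20{,}000$ barcodes over 50 replicates. Exact-test
agreement is checked against full hypergeometric enumeration on complete
small-margin table sets plus seeded samples of larger tables.

## Known limitations

* No Gaussian or count emissions; no stacked multi-cell-type joint model;
  no posterior-probability export.
* Equivalence with the ChromHMM binaries is not claimed — the model class
  and criteria are the same, but ChromHMM's "information" initialization
  is unpublished detail and is replaced by the quantile heuristic above.
* The reproducible-peak rule takes its candidate universe as the union of
  replicate peaks passing the score threshold; whether candidates should
  instead come from pooled calls is not specified by the convention being
  followed, and the threshold ("negative log10 q-value of at least 0.01")
  is applied literally to the score field, with the threshold exposed so
  users may substitute q ≤ 0.01 semantics.
* `region_major_class()` resolves ties toward Chr-A; the grouping rule for
  multi-cell-type regions is otherwise unstated in the conventions being
  reproduced.
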