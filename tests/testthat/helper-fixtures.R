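suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# small grid shared by many tests
tiny_grid <- function(sizes = c(chr1 = 2000, chr2 = 1000), bin = 200)
  bin_genome(sizes, bin)

# segmentation from an explicit label vector
seg_from <- function(labels, grid, states = NULL, cell = "cell")
  segmentation(grid, labels, states, cell)

# random scored peaks on one chromosome
random_peaks <- function(n, chrom_len = 10000, max_w = 400, chrom = "chr1") {
  s0 <- sample.int(chrom_len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  peak_set(rep(chrom, n), s0, pmin(s0 + w, chrom_len),
           score = runif(n, 0.5, 50))
}

# random multi-state segmentation
random_segmentation <- function(grid, states, cell = "cell") {
  seg_from(sample(states, grid$total_bins, replace = TRUE), grid,
           states, cell)
}
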