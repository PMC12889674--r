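cells_df <- function(dna, rna) {
  data.frame(barcode = sprintf("b%02d", seq_along(dna)),
             dna_feature_count = dna, rna_feature_count = rna)
}

test_that("feature-count filter is inclusive at its bounds and idempotent", {
  cells <- cells_df(c(1000, 400, 500, 30000, 30001),
                    c(500, 500, 200, 200, 200))
  out <- qc_filter(cells)
  expect_equal(out$barcode, c("b01", "b03", "b04"))
  expect_equal(qc_filter(out), out)
  expect_error(qc_filter(cells, dna_range = c(10, 5)), "exceeds")
})

test_that("species assignment uses an inclusive 75% rule", {
  cells <- data.frame(reads_species_a = c(80, 60, 75, 25, 0, 0),
                      reads_species_b = c(20, 40, 25, 75, 100, 0))
  expect_equal(species_mix_classify(cells),
               c("species-A", "doublet", "species-A", "species-B",
                 "species-B", "unclassifiable"))
})

test_that("collision rate extrapolates d/(2pq) and recovers the truth", {
  # closed form
  labels <- c(rep("doublet", 50), rep("species-A", 475),
              rep("species-B", 475))
  est <- collision_rate_estimate(labels, 0.5)
  expect_equal(est$rate, 0.05 / 0.5)
  expect_equal(collision_rate_estimate(rep("species-A", 10), 0.5)$rate, 0)
  expect_error(collision_rate_estimate(labels, 1), "pool_fraction_a")
  # estimator recovery on the generator
  tab <- simulate_species_mix(20000, 0.5, 0.08, seed = 10)
  lab <- species_mix_classify(tab)
  est2 <- collision_rate_estimate(lab, 0.5)
  expect_true(abs(est2$rate - 0.08) < 0.01)
})

test_that("collision estimator is unbiased across replicate simulations", {
  ests <- vapply(1:50, function(i) {
    tab <- simulate_species_mix(5000, 0.5, 0.08, seed = 1000 + i)
    collision_rate_estimate(species_mix_classify(tab), 0.5)$rate
  }, numeric(1))
  mc_se <- stats::sd(ests) / sqrt(50)
  expect_true(abs(mean(ests) - 0.08) < 3 * mc_se + 1e-3)
})

test_that("rate-matched removal takes the top scores with a deterministic tie rule", {
  sc <- setNames(c(0.9, 0.8, 0.1, 0.2, 0.5, 0.3, 0.05, 0.15, 0.25, 0.35,
                   0.45, 0.55, 0.65, 0.02, 0.03, 0.04, 0.06, 0.07, 0.08,
                   0.09, 0.11, 0.12, 0.13, 0.14, 0.16, 0.17, 0.18, 0.19,
                   0.21, 0.22, 0.23, 0.24, 0.26, 0.27, 0.28, 0.29, 0.31,
                   0.32, 0.33, 0.34, 0.36, 0.37, 0.38, 0.39, 0.41, 0.42,
                   0.43, 0.44, 0.46, 0.47, 0.48, 0.52, 0.53, 0.54, 0.56,
                   0.57, 0.58, 0.59, 0.61, 0.62, 0.63, 0.64, 0.66, 0.67,
                   0.68, 0.69, 0.71, 0.72, 0.73, 0.74, 0.76, 0.77, 0.78,
                   0.79, 0.81, 0.82, 0.83, 0.84, 0.86, 0.87, 0.88, 0.89,
                   0.91, 0.92, 0.93, 0.94, 0.96, 0.97, 0.98, 0.99, 0.01,
                   0.51, 0.85, 0.95, 0.75, 0.7, 0.6, 0.4, 0.3001, 0.1001),
                 sprintf("bc%03d", 1:100))
  out <- rate_matched_removal(sc, 0.05)
  expect_equal(length(out$removed), 5L)
  expect_equal(sort(sc[out$removed]), sort(sc, decreasing = TRUE)[5:1],
               ignore_attr = TRUE)
  expect_equal(rate_matched_removal(sc, 0)$removed, character(0))
  # equal scores: lexicographically smallest barcodes go first
  eq <- setNames(rep(0.5, 20), sprintf("bc%02d", 20:1))
  out_eq <- rate_matched_removal(eq, 0.1)
  expect_equal(sort(out_eq$removed), c("bc01", "bc02"))
})

test_that("ATAC gene activity counts fragments in body plus 2kb upstream", {
  genes <- GRanges("chr1", IRanges(c(5001, 9001), width = 1000),
                   strand = c("+", "-"), name = c("g1", "g2"))
  frags <- GRanges("chr1", IRanges(c(5500,   # g1 body
                                     4500,   # 1kb upstream of g1 TSS
                                     2500,   # beyond 2kb upstream
                                     10500,  # g2 "upstream" (right side)
                                     9500),  # g2 body
                                   width = 50))
  act <- gene_activity_atac(frags, genes)
  expect_equal(unname(act["g1"]), 2L)
  expect_equal(unname(act["g2"]), 2L)
  nos <- GRanges("chr1", IRanges(1, 10), name = "x")
  expect_error(gene_activity_atac(frags, nos), "strand")
})

test_that("methylation gene activity is the negated z-score of log fractions", {
  mcg <- cbind(grp1 = exp(1:3))
  mch <- cbind(grp1 = exp(c(3, 2, 1)))
  out <- gene_activity_methylation(mcg, mch, "non-neuron")
  sdp <- sqrt(2 / 3)
  expect_equal(unname(out$scores[, 1]), -(c(1, 2, 3) - 2) / sdp)
  expect_equal(out$context_used, "mCG")
  # neurons route to mCH; granule neurons and immature to mCG
  out_n <- gene_activity_methylation(mcg, mch, "neuron")
  expect_equal(out_n$context_used, "mCH")
  expect_equal(unname(out_n$scores[, 1]), -(c(3, 2, 1) - 2) / sdp)
  out_g <- gene_activity_methylation(mcg, mch, "granule-neuron")
  expect_equal(out_g$context_used, "mCG")
  # scores sum to zero when sd > 0; constant fractions flag zero variance
  expect_equal(sum(out$scores), 0, tolerance = 1e-9)
  const <- cbind(grp1 = rep(exp(1), 4))
  out_c <- gene_activity_methylation(const, const, "non-neuron")
  expect_equal(unname(out_c$scores[, 1]), rep(0, 4))
  expect_equal(out_c$zero_variance_groups, "grp1")
})

test_that("NMI matches hand-computed contingency cases and its invariances", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c("a", "a", "b", "b"), c("x", "y", "x", "y")), 0)
  expect_equal(nmi(rep("a", 5), rep("b", 5)), 1)  # single vs single cluster
  # symmetry and label-permutation invariance
  set.seed(3)
  la <- sample(letters[1:4], 500, replace = TRUE)
  lb <- sample(letters[1:3], 500, replace = TRUE)
  expect_equal(nmi(la, lb), nmi(lb, la))
  perm <- setNames(c("z", "q", "w", "k"), letters[1:4])
  expect_equal(nmi(perm[la], lb), nmi(la, lb))
  # independent labels at large n: near zero
  la2 <- sample(1:3, 10000, replace = TRUE)
  lb2 <- sample(1:3, 10000, replace = TRUE)
  expect_lt(nmi(la2, lb2), 0.01)
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("kNN label accuracy votes over Euclidean neighbours excluding self", {
  set.seed(8)
  emb <- rbind(matrix(rnorm(200, 0), ncol = 2),
               matrix(rnorm(200, 10), ncol = 2))
  labels <- rep(c("a", "b"), each = 100)
  expect_equal(knn_label_accuracy(emb, labels, k = 15), 1)
  expect_error(knn_label_accuracy(emb, labels, k = 200), "smaller")
  # brute-force agreement on a small mixed instance
  emb2 <- matrix(rnorm(80), ncol = 2)
  lab2 <- sample(c("a", "b"), 40, replace = TRUE)
  got <- knn_label_accuracy(emb2, lab2, k = 5)
  correct <- logical(40)
  for (i in 1:40) {
    d2 <- colSums((t(emb2) - emb2[i, ])^2)
    d2[i] <- Inf
    nb <- lab2[order(d2)[1:5]]
    tb <- sort(table(nb), decreasing = TRUE)
    correct[i] <- sort(names(tb)[tb == max(tb)])[1] == lab2[i]
  }
  expect_equal(got, mean(correct))
})

test_that("region specificity requires strictly more than 75% dominance", {
  cells <- data.frame(
    subclass = c(rep("s1", 10), rep("s2", 10), rep("s3", 4)),
    region = c(rep("PFC", 8), "HC", "HC",       # 80% -> specific
               rep("PFC", 5), rep("HC", 5),     # 50% -> not
               rep("PFC", 3), "HC"))            # 75% exactly -> not
  out <- region_specificity(cells)
  expect_equal(out$specific[out$subclass == "s1"], TRUE)
  expect_equal(out$specific[out$subclass == "s2"], FALSE)
  expect_equal(out$specific[out$subclass == "s3"], FALSE)
  expect_equal(out$dominant_region[out$subclass == "s1"], "PFC")
})
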