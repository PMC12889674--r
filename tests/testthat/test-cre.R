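test_that("cCRE centers resolve to the right bin, honouring floor and summit", {
  g <- bin_genome(c(chr1 = 1000), 200)
  seg <- seg_from(c("Chr-A", "Chr-O", "ND", "ND", "Chr-A"), g,
                  c("Chr-A", "Chr-O", "ND"))
  # [100,300): center 200 -> bin 2 (Chr-O)
  ann <- annotate_cre_state(peak_set("chr1", 100, 300), seg)
  expect_equal(ann$center, 200)
  expect_equal(ann$state, "Chr-O")
  # [0,3): center 1 (floor)
  ann2 <- annotate_cre_state(peak_set("chr1", 0, 3), seg)
  expect_equal(ann2$center, 1)
  # summit offset overrides the center
  pk <- peak_set("chr1", 100, 300, summit = 350)
  ann3 <- annotate_cre_state(pk, seg)
  expect_equal(ann3$center, 450)
  expect_equal(ann3$state, "ND")
  expect_error(annotate_cre_state(peak_set("chrX", 0, 10), seg), "unknown")
})

test_that("center-state annotation matches brute-force bin lookup", {
  set.seed(17)
  g <- bin_genome(c(chr1 = 10000, chr2 = 6000), 300)
  seg <- random_segmentation(g, c("Chr-A", "Chr-O", "ND"))
  n <- 300
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  len <- ifelse(chrom == "chr1", 10000, 6000)
  s0 <- floor(runif(n, 0, len - 200))
  cres <- GRanges(chrom, IRanges(s0 + 1, s0 + sample(50:200, n, TRUE)))
  ann <- annotate_cre_state(cres, seg)
  for (i in seq_len(n)) {
    ctr <- (s0[i] + end(cres)[i]) %/% 2
    # brute force: walk bins of that chromosome
    off <- if (chrom[i] == "chr1") 0 else ceiling(10000 / 300)
    expect_equal(ann$state[i], seg$labels[off + ctr %/% 300 + 1])
  }
})

test_that("differential testing filters, tests exactly and honours direction", {
  # min_pct exclusion
  out <- differential_regions(c(0, 30), c(5, 5), 1000, 100)
  expect_false(out$tested[1])
  expect_true(out$tested[2])
  # Fisher p equals hypergeometric enumeration
  out2 <- differential_regions(30, 5, 100, 100)
  expect_equal(out2$p, oracle_fisher_p(30, 70, 5, 95), tolerance = 1e-9)
  expect_true(out2$p_adj >= out2$p - 1e-12)
  # direction: bg-enriched regions pass only under "both"
  fg <- c(5, 60); bg <- c(60, 5)
  pos <- differential_regions(fg, bg, 100, 100, direction = "positive")
  both <- differential_regions(fg, bg, 100, 100, direction = "both")
  expect_equal(pos$pass, c(FALSE, TRUE))
  expect_equal(both$pass, c(TRUE, TRUE))
  # identical groups yield no passers
  set.seed(5)
  k <- rbinom(50, 80, 0.3)
  same <- differential_regions(k, k, 80, 80, alpha = 0.5)
  expect_equal(sum(same$pass), 0L)
  expect_error(differential_regions(1, 1, 0, 10), "positive")
})

test_that("pairwise center distances equal the brute-force multiset", {
  # hand cases
  expect_equal(pairwise_center_distances(
    peak_set("chr1", c(0, 250), c(200, 450))), 250)
  expect_equal(length(pairwise_center_distances(
    peak_set(c("chr1", "chr2"), c(0, 0), c(200, 200)))), 0L)
  # random oracle with the distance cap
  set.seed(23)
  n <- 200
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  s0 <- sample.int(3e6, n)
  regions <- GRanges(chrom, IRanges(s0 + 1, s0 + 100))
  got <- sort(pairwise_center_distances(regions, max_distance = 1e6))
  ctr <- s0 + 50  # floor((s0 + s0 + 100) / 2)
  want <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (chrom[i] == chrom[j] && abs(ctr[i] - ctr[j]) <= 1e6)
      want <- c(want, abs(ctr[i] - ctr[j]))
  expect_equal(got, sort(want))
})

test_that("scaled profiles average to 50 bins with missing data as zero", {
  regions <- GRanges("chr1", IRanges(c(101, 1001), width = c(250, 700)))
  # constant track value c -> profile all c
  track <- GRanges("chr1", IRanges(1, 5000), score = 2.5)
  prof <- scaled_region_profile(regions, track)
  expect_equal(length(prof), 50L)
  expect_equal(prof, rep(2.5, 50))
  # no track at all -> all zeros
  none <- GRanges(); mcols(none)$score <- numeric(0)
  prof0 <- scaled_region_profile(regions, none)
  expect_equal(prof0, rep(0, 50))
  # minus-strand regions are reversed
  asc <- GRanges("chr1", IRanges(1, 1000), score = 1)
  half <- GRanges("chr1", IRanges(1, 500), score = 1)  # left half only
  fwd <- GRanges("chr1", IRanges(1, 1000), strand = "+")
  rev <- GRanges("chr1", IRanges(1, 1000), strand = "-")
  pf <- scaled_region_profile(fwd, half)
  pr <- scaled_region_profile(rev, half)
  expect_equal(pr, rev(pf))
  expect_true(all(pf[1:25] == 1) && all(pf[26:50] == 0))
  expect_error(scaled_region_profile(GRanges(), track), "empty")
  # region order is irrelevant
  expect_equal(scaled_region_profile(regions, track),
               scaled_region_profile(rev(regions), track))
})

test_that("TE subfamily signal is the mean of per-TE means, autosomes only", {
  te <- GRanges(c("chr1", "chr1", "chrX"), IRanges(c(1, 201, 1), width = 100),
                name = c("LINE:L1Md", "LINE:L1Md", "LINE:L1Md"))
  tr <- GRanges("chr1", IRanges(c(1, 201), width = 100), score = c(1, 3))
  m <- te_subfamily_signal(te, list(ct1 = tr))
  expect_equal(unname(m["L1Md", "ct1"]), 2)  # chrX copy excluded
  one <- te_subfamily_signal(te[1], list(ct1 = tr))
  expect_equal(unname(one["L1Md", "ct1"]), 1)
  # brute-force group-by average on random input
  set.seed(41)
  n <- 60
  s0 <- sample(seq(0, 9000, 100), n)
  fam <- sample(c("a", "b", "c"), n, replace = TRUE)
  te2 <- GRanges("chr1", IRanges(s0 + 1, s0 + 100),
                 name = paste0("X:", fam))
  sig <- GRanges("chr1", IRanges(seq(1, 9901, 100), width = 100),
                 score = runif(100))
  m2 <- te_subfamily_signal(te2, list(ct = sig))
  cov <- coverage(sig, weight = sig$score)$chr1
  per_te <- vapply(seq_len(n), function(i)
    mean(as.numeric(cov[(s0[i] + 1):(s0[i] + 100)])), numeric(1))
  for (f in c("a", "b", "c"))
    expect_equal(unname(m2[f, "ct"]), mean(per_te[fam == f]))
})

test_that("enhancer metrics follow the three closed-form definitions", {
  # 2 regions x 3 cell types; Chr-A predictions: one true one false positive
  ann <- data.frame(region_id = c("r1", "r1", "r2"),
                    cell_type = c("ct1", "ct2", "ct1"),
                    class = c("Chr-A", "Chr-A", "Chr-O"))
  val <- data.frame(
    region_id = rep(c("r1", "r2"), each = 3),
    cell_type = rep(c("ct1", "ct2", "ct3"), 2),
    outcome = c("positive", "negative", "untested",
                "positive", "untested", "untested"))
  m <- enhancer_eval(ann, val, "Chr-A")
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["recall"]), 0.5)    # TP = 1 of 2 positives
  expect_equal(unname(m["specificity"]), 1 - 1 / 6)
  # all predictions positive -> precision 1
  val2 <- val; val2$outcome <- "positive"
  expect_equal(unname(enhancer_eval(ann, val2, "Chr-A")["precision"]), 1)
  # zero predictions: precision missing, recall 0, specificity 1
  m0 <- enhancer_eval(ann[0, ], val, "Chr-A")
  expect_true(is.na(m0["precision"]))
  expect_equal(unname(m0["recall"]), 0)
  expect_equal(unname(m0["specificity"]), 1)
  expect_error(enhancer_eval(ann, val[0, ]), "empty")
})

test_that("noise-free validation from the segmentations scores perfectly", {
  g <- bin_genome(c(chr1 = 20000), 200)
  set.seed(51)
  segs <- list(ct1 = random_segmentation(g, c("Chr-A", "Chr-O", "ND"), "ct1"),
               ct2 = random_segmentation(g, c("Chr-A", "Chr-O", "ND"), "ct2"))
  s0 <- seq(0, 19000, 500)
  cres <- peak_set("chr1", s0, s0 + 300, name = sprintf("r%02d", seq_along(s0)))
  vt <- simulate_validation_table(cres, segs, flip_noise = 0, seed = 4)
  ann <- do.call(rbind, lapply(names(segs), function(ct)
    annotate_cre_state(cres, segs[[ct]], cell_type = ct)))
  m <- enhancer_eval(ann, vt, "Chr-A", positive_labels = "positive")
  expect_equal(unname(m["precision"]), 1)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["specificity"]), 1)
})

test_that("overlap odds ratios use ad/bc with correction and exact p", {
  # build a universe realizing the table [[10,5],[2,20]]
  mk <- function(n, offset) {
    s0 <- offset + seq(0, by = 1000, length.out = n)
    GRanges("chr1", IRanges(s0 + 1, s0 + 100))
  }
  a <- mk(10, 0); b <- mk(5, 1e5); cc <- mk(2, 2e5); d <- mk(20, 3e5)
  universe <- c(a, b, cc, d)
  query <- c(a, b)
  validated <- c(a, cc)
  out <- overlap_odds_ratio(query, validated, universe)
  expect_equal(out$or, 20)
  expect_false(out$corrected)
  expect_equal(out$p, oracle_fisher_p(10, 5, 2, 20), tolerance = 1e-9)
  # a zero cell triggers the Haldane-Anscombe correction, flagged
  out0 <- overlap_odds_ratio(query, c(a, b), universe)
  expect_true(out0$corrected)
  expect_true(is.finite(out0$or))
  expect_error(overlap_odds_ratio(query, validated, GRanges()), "empty")
})
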