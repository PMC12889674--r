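test_that("state coverage partitions the genome", {
  g <- bin_genome(c(chr1 = 2000), 200)
  seg <- seg_from(c(rep("Chr-A", 4), rep("ND", 6)), g, c("Chr-A", "ND"))
  cov <- state_coverage(seg)
  expect_equal(cov$fraction[cov$state == "Chr-A"], 0.4)
  expect_equal(sum(cov$fraction), 1)
  # constant segmentation: fraction 1
  seg1 <- seg_from(rep("Chr-A", 10), g, c("Chr-A", "ND"))
  expect_equal(state_coverage(seg1)$fraction, c(1, 0))
  # random partitions always sum to 1
  set.seed(2)
  for (r in 1:5) {
    segr <- random_segmentation(tiny_grid(), c("a", "b", "c"))
    expect_equal(sum(state_coverage(segr)$fraction), 1)
  }
})

test_that("conservation proportion follows the best-single-overlap rule", {
  g <- bin_genome(c(chr1 = 1000), 100)
  ref <- seg_from(rep("A", 10), g, c("A", "B"))
  expect_equal(conservation_proportion(ref, ref, "A"), 1)
  # ref [0,1000) vs other [500,1000) -> 0.5
  oth <- seg_from(c(rep("B", 5), rep("A", 5)), g, c("A", "B"))
  expect_equal(conservation_proportion(ref, oth, "A"), 0.5)
  # ref [0,1000), other {[0,400), [600,1000)}: only the larger single
  # overlap counts
  oth2 <- seg_from(c(rep("A", 4), rep("B", 2), rep("A", 4)), g, c("A", "B"))
  expect_equal(conservation_proportion(ref, oth2, "A"), 0.4)
  # absent state: 0, flagged
  ref_b <- conservation_proportion(ref, oth, "B")
  expect_equal(as.numeric(ref_b), 0)
  expect_true(isTRUE(attr(ref_b, "no_reference_intervals")))
})

test_that("conservation matches the brute-force scan on random instances", {
  set.seed(31)
  g <- bin_genome(c(chr1 = 4000, chr2 = 2000), 100)
  for (rep in 1:200) {
    s1 <- random_segmentation(g, c("A", "B", "C"))
    s2 <- random_segmentation(g, c("A", "B", "C"))
    st <- sample(c("A", "B", "C"), 1)
    got <- as.numeric(conservation_proportion(s1, s2, st))
    iv1 <- seg_intervals(s1, st); iv2 <- seg_intervals(s2, st)
    df1 <- data.frame(chrom = as.character(seqnames(iv1)),
                      start0 = start(iv1) - 1L, end0 = end(iv1))
    df2 <- data.frame(chrom = as.character(seqnames(iv2)),
                      start0 = start(iv2) - 1L, end0 = end(iv2))
    expect_equal(got, oracle_conservation(df1, df2))
  }
})

test_that("state variation is the population variance of conservation", {
  g <- bin_genome(c(chr1 = 1000), 100)
  ref <- seg_from(rep("A", 10), g, c("A", "B"))
  # comparators giving conservation 0.2 and 0.8
  c1 <- seg_from(c(rep("A", 2), rep("B", 8)), g, c("A", "B"))
  c2 <- seg_from(c(rep("A", 8), rep("B", 2)), g, c("A", "B"))
  expect_equal(state_variation(ref, list(c1, c2), "A"), 0.09)
  expect_equal(state_variation(ref, list(ref, ref), "A"), 0)
  expect_error(state_variation(ref, list(c1), "A"), "at least 2")
  # compositional: equals direct recomputation
  set.seed(7)
  comp <- lapply(1:3, function(i) random_segmentation(g, c("A", "B")))
  p <- vapply(comp, function(s)
    as.numeric(conservation_proportion(ref, s, "A")), numeric(1))
  expect_equal(state_variation(ref, comp, "A"), mean((p - mean(p))^2))
})

test_that("transition summary counts source intervals by plurality target", {
  g <- bin_genome(c(chr1 = 2000), 200)
  src <- seg_from(c("A", "A", "A", "B", "B", "A", "A", "B", "B", "B"), g,
                  c("A", "B"))
  # identity: diagonal counts equal interval counts
  ts <- transition_summary(src, src)
  expect_equal(sum(ts$counts), 4)  # 4 maximal intervals
  expect_equal(ts$counts["A", "B"] + ts$counts["B", "A"], 0L)
  # plurality assignment: interval [0,600) sees target A,A,B -> A
  tgt <- seg_from(c("A", "A", "B", "B", "B", "B", "B", "B", "B", "B"), g,
                  c("A", "B"))
  ts2 <- transition_summary(src, tgt)
  expect_equal(unname(ts2$counts["A", "A"]), 1L)
  expect_equal(unname(ts2$counts["A", "B"]), 1L)
  # totals conserved on random inputs
  set.seed(12)
  for (r in 1:5) {
    a <- random_segmentation(g, c("A", "B", "C"))
    b <- random_segmentation(g, c("A", "B", "C"))
    tt <- transition_summary(a, b)
    expect_equal(sum(tt$counts), length(seg_intervals(a)))
    nz <- tt$row_totals > 0
    expect_true(all(abs(rowSums(tt$row_pct_exact)[nz] - 100) < 0.01))
  }
})

test_that("row percentages reproduce printed oligodendrocyte transition figures", {
  # printed counts: of 636,708 OPC Chr-A regions 280,913 changed state;
  # Oligo holds 833,506 Chr-A of which 355,795 shared, 207,191 from
  # primed, 177,255 from ND
  expect_equal(row_percentages(280913, 636708, "nearest"), 44)
  expect_equal(row_percentages(207191, 833506, "nearest"), 25)
  expect_equal(row_percentages(177255, 833506, "nearest"), 21)
  expect_equal(row_percentages(355795, 833506, "truncate"), 42)
})

test_that("methylation by state pools counts rather than averaging bins", {
  g <- bin_genome(c(chr1 = 400), 200)
  seg <- seg_from(c("A", "A"), g, c("A", "B"))
  mt <- methyl_track(g, c(5, 0), c(10, 30))
  out <- methylation_by_state(seg, mt)
  expect_equal(unname(out["A"]), 5 / 40)  # pooled, not mean(0.5, 0)
  expect_true("B" %in% attr(out, "no_coverage_states"))
  # uniform fraction is preserved; brute-force equality on random input
  set.seed(9)
  g2 <- tiny_grid()
  seg2 <- random_segmentation(g2, c("A", "B", "C"))
  tot <- rpois(g2$total_bins, 20)
  met <- rbinom(g2$total_bins, tot, 0.5)
  mt2 <- methyl_track(g2, met, tot)
  out2 <- methylation_by_state(seg2, mt2)
  for (st in c("A", "B", "C")) {
    rows <- seg2$labels == st
    expect_equal(unname(out2[st]), sum(met[rows]) / sum(tot[rows]))
  }
  # invariance under bin subdivision of the same counts
  g_half <- bin_genome(c(chr1 = 2000, chr2 = 1000), 100)
  seg_half <- seg_from(rep(seg2$labels, each = 2), g_half, c("A", "B", "C"))
  mt_half <- methyl_track(g_half,
                          as.vector(rbind(met, 0L)),
                          as.vector(rbind(tot, 0L)))
  expect_equal(methylation_by_state(seg_half, mt_half), out2)
})

test_that("methylation stratification cuts at the break points and tests pairwise", {
  g <- bin_genome(c(chr1 = 1200), 200)
  mt <- methyl_track(g, c(1, 4, 10, 19, 2, 17), rep(20, 6))
  regions <- grid_bins(g)  # one region per bin
  sig <- c(1, 1.2, 3, 9.5, 0.8, 10)
  out <- stratify_signal_by_methylation(regions, mt, sig)
  expect_equal(as.character(out$strata),
               c("Low", "Medium", "Medium", "High", "Low", "High"))
  expect_equal(unname(out$means["Low"]), 0.9)
  expect_equal(unname(out$means["High"]), 9.75)
  expect_equal(nrow(out$tests), 3L)
  # empty strata are reported missing
  mt_low <- methyl_track(g, rep(1, 6), rep(20, 6))
  out2 <- stratify_signal_by_methylation(regions, mt_low, sig)
  expect_equal(unname(out2$n[c("Medium", "High")]), c(0L, 0L))
  expect_true(all(is.na(out2$tests$p)))
})

test_that("BH adjustment agrees with an explicit step-up implementation", {
  set.seed(44)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})
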