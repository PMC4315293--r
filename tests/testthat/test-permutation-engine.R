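test_that("placement is reproducible, length-preserving and uniform", {
  g <- toy_genome(1e7)
  p1 <- permute_intervals(1e6, g, n_iter = 1000, seed = 99)
  p2 <- permute_intervals(1e6, g, n_iter = 1000, seed = 99)
  expect_identical(start(p1), start(p2))
  expect_true(all(width(p1) == 1e6))
  expect_true(all(start(p1) >= 1 & end(p1) <= 1e7))
  # uniform start over [1, 9e6 + 1]
  ks <- suppressWarnings(ks.test(start(p1), "punif", 1, 9e6 + 1))
  expect_gt(ks$p.value, 0.01)

  expect_error(permute_intervals(1e6, g, n_iter = 0, seed = 1))
  expect_error(permute_intervals(2e7, g, n_iter = 1, seed = 1),
               "longest mappable stretch")
})

test_that("placements stay inside mappable sequence", {
  g <- mappable_genome(c(chrA = 1e6, chrB = 5e5),
                       GRanges(c("chrA", "chrA"),
                               IRanges(c(200001, 700001), c(300000, 750000))))
  p <- permute_intervals(c(5e4, 2e4), g, n_iter = 500, seed = 3)
  # no placement may touch an excluded gap
  expect_equal(sum(countOverlaps(p, g$excluded)), 0)
  # both chromosomes get used, roughly in proportion to mappable bp
  tab <- table(seqnames(p))
  expect_gt(tab[["chrB"]], 0.2 * length(p) * (5e5 / 1.35e6))
})

test_that("overlap scores match the per-bp bitmap oracle", {
  len <- 1e5
  set.seed(7)
  for (rep in 1:5) {
    fs <- sample.int(len - 500, 30); fe <- pmin(len, fs + sample.int(2000, 30))
    rs <- sample.int(len - 5000, 10); re <- rs + sample.int(5000, 10)
    regions <- GRanges("chrT", IRanges(rs, re))
    features <- GRanges("chrT", IRanges(fs, fe))
    fmask <- bitmap(fs, fe, len)
    frac <- score_overlap(regions, features, "fraction_of_span")$per_region
    bool <- score_overlap(regions, features, "boolean")$per_region
    longest <- score_overlap(regions, features, "longest_feature_bp")$per_region
    for (i in 1:10) {
      rmask <- bitmap(rs[i], re[i], len)
      expect_equal(frac[i], sum(fmask & rmask) / sum(rmask))
      expect_equal(bool[i], as.numeric(any(fmask & rmask)))
      touching <- which(fs <= re[i] & fe >= rs[i])
      expect_equal(longest[i],
                   if (length(touching)) max(fe[touching] - fs[touching] + 1) else 0)
    }
  }
})

test_that("length-weighted mean scores average the signal over covered bp", {
  seg <- GRanges("chrT", IRanges(c(1, 501), c(500, 1000)))
  seg$score <- c(10, 20)
  region <- GRanges("chrT", IRanges(1, 1000))
  expect_equal(score_overlap(region, kind = "length_weighted_mean",
                             signal = seg)$per_region, 15)
  # uncovered region reports NA, never silent zero
  far <- GRanges("chrT", IRanges(5000, 6000))
  expect_true(is.na(score_overlap(far, kind = "length_weighted_mean",
                                  signal = seg)$per_region))
  expect_error(score_overlap(region, kind = "length_weighted_mean"), "signal")
})

test_that("empirical p-values follow the add-one rule and never reach 0", {
  expect_equal(empirical_p(10, rep(1, 9999), "enriched"), 1 / 10000)
  expect_equal(empirical_p(1, rep(1, 99), "enriched"), 1)
  expect_equal(empirical_p(0, rep(1, 99), "depleted"), 1 / 100)
  expect_gt(empirical_p(Inf, rnorm(100), "enriched"), 0)
})

test_that("enrichment saturates at 1 when features tile the genome", {
  g <- toy_genome(1e6)
  features <- GRanges("chrT", IRanges(1, 1e6))
  regions <- classify_regions(merge_to_regions(
    cnv_calls("chrT", c(1e4, 5e5), c(2e4, 5.2e5), "deletion"), max_gap = 0))
  res <- enrichment_test(regions, features, "fraction_of_span", g,
                         n_iter = 99, seed = 2)
  expect_equal(res$actual, 1)
  expect_true(all(res$iterations == 1))
  expect_equal(res$p_emp, 1)
})

test_that("planted enrichment is detected with high significance", {
  # features cover 10% of the genome; CNVs placed inside them at ~8x the
  # uniform rate
  g <- toy_genome(1e7)
  features <- GRanges("chrT", IRanges(seq(1, 9e6 + 1, by = 1e6), width = 1e5))
  set.seed(17)
  inside <- sample(start(features), 25, TRUE) + sample.int(5e4, 25)
  outside <- sample.int(9.9e6, 5)
  cnvs <- cnv_calls("chrT", c(inside, outside), c(inside, outside) + 2e4, "deletion")
  regions <- merge_to_regions(cnvs, max_gap = 0)
  res <- enrichment_test(regions, features, "fraction_of_span", g,
                         n_iter = 999, seed = 5)
  expect_lt(res$p_emp, 0.01)
  expect_equal(res$direction, "enriched")
  # fixed seed reproduces the full result bit-for-bit
  res2 <- enrichment_test(regions, features, "fraction_of_span", g,
                          n_iter = 999, seed = 5)
  expect_identical(res$iterations, res2$iterations)
  expect_identical(res$p_emp, res2$p_emp)
})

test_that("clustering significance agrees with exact enumeration for two intervals", {
  # two intervals on one toy chromosome, k = 2, gap 0: exact merge
  # probability by enumeration over both uniform starts
  N <- 10000; L1 <- 400; L2 <- 250
  n1 <- N - L1 + 1; n2 <- N - L2 + 1
  hits <- 0
  for (s1 in seq_len(n1)) {
    lo <- max(1, s1 - L2); hi <- min(n2, s1 + L1)
    hits <- hits + (hi - lo + 1)
  }
  p_exact <- hits / (as.numeric(n1) * n2)
  g <- toy_genome(N)
  cnvs <- cnv_calls("chrT", c(1, 5000), c(L1, 5000 + L2 - 1), "deletion")
  cs <- clustering_significance(cnvs, g, max_gap = 0, k = 2,
                                n_iter = 4000, seed = 8)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(cs$p_ge_k - p_exact), 4 * mc_se + 1 / 4000)
})

test_that("clustering significance floors when k exceeds the CNV count", {
  g <- toy_genome(1e6)
  cnvs <- cnv_calls("chrT", c(1, 2000), c(1000, 3000), "deletion")
  cs <- clustering_significance(cnvs, g, max_gap = 100, k = 5,
                                n_iter = 200, seed = 4)
  expect_equal(cs$p_ge_k, 1 / 201)
})

test_that("TU permutation reports saturated and empty CNV overlap correctly", {
  g <- toy_genome(1e7)
  tus <- GRanges("chrT", IRanges(c(1e5, 2e6, 6e6), width = c(5e4, 2e5, 1e6)),
                 strand = "+")
  bins <- c(0, 1e5, 5e5, 2e6)
  all_cnvs <- cnv_calls("chrT", start(tus), end(tus), "deletion")
  res_all <- permute_tus(tus, g, all_cnvs, n_iter = 49, seed = 1, length_bins = bins)
  expect_equal(res_all$actual_pct[res_all$n_tus > 0],
               rep(100, sum(res_all$n_tus > 0)))
  no_cnvs <- cnv_calls("chrT", 9.9e6, 9.95e6, "deletion")
  res_none <- permute_tus(tus, g, no_cnvs, n_iter = 49, seed = 1, length_bins = bins)
  expect_equal(res_none$actual_pct[res_none$n_tus > 0],
               rep(0, sum(res_none$n_tus > 0)))
  expect_error(permute_tus(tus, g, all_cnvs, n_iter = 9, seed = 1,
                           length_bins = c(0, 1e5)), "cover")
})
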