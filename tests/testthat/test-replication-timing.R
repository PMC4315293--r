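step_track <- function(values, seg_len = 100, chrom = "chrT",
                       source = "repli_seq_score") {
  n <- length(values)
  gr <- GRanges(chrom, IRanges(start = (seq_len(n) - 1) * seg_len + 1,
                               width = seg_len))
  gr$score <- values
  timing_track(gr, source = source)
}

test_that("probe projection follows the midpoint rule", {
  probes <- data.frame(chrom = "chrT", position = c(100, 300),
                       ratio = c(1, -1))
  tr <- project_probes(probes, c(chrT = 400))
  expect_equal(start(tr$segments), c(1, 201))
  expect_equal(end(tr$segments), c(200, 400))
  expect_equal(tr$segments$score, c(1, -1))
  expect_error(project_probes(data.frame(chrom = "chrT", position = 5,
                                         ratio = 0.2), c(chrT = 400)),
               ">= 2 probes")
  expect_error(project_probes(data.frame(chrom = "chrT",
                                         position = c(10, 10),
                                         ratio = c(1, 2)), c(chrT = 400)),
               "duplicate")
})

test_that("probe projection equals nearest-probe brute force", {
  set.seed(13)
  for (rep in 1:3) {
    pos <- sort(sample.int(9000, 50))
    pos <- pos[!duplicated(pos)]
    val <- rnorm(length(pos))
    tr <- project_probes(data.frame(chrom = "chrT", position = pos,
                                    ratio = val), c(chrT = 10000))
    # tiling is exact and disjoint
    expect_equal(sum(width(tr$segments)), 10000)
    at <- sample.int(10000, 300)
    got <- vapply(at, function(p) {
      i <- findOverlaps(GRanges("chrT", IRanges(p, p)), tr$segments,
                        select = "first")
      tr$segments$score[i]
    }, 0)
    want <- vapply(at, oracle_nearest_probe, 0, probe_pos = pos, probe_val = val)
    expect_equal(got, want)
  }
})

test_that("interval timing is the bp-weighted mean and flags missing coverage", {
  tr <- step_track(rep(70, 10))
  expect_equal(interval_timing(GRanges("chrT", IRanges(1, 1000)), tr), 70)
  half <- step_track(c(rep(20, 5), rep(80, 5)))
  expect_equal(interval_timing(GRanges("chrT", IRanges(1, 1000)), half), 50)
  expect_true(is.na(interval_timing(GRanges("chrT", IRanges(5000, 5100)), half)))

  set.seed(14)
  vals <- rnorm(100, 50, 10)
  tr2 <- step_track(vals)
  for (rep in 1:20) {
    s <- sample.int(9000, 1); e <- s + sample.int(900, 1)
    got <- interval_timing(GRanges("chrT", IRanges(s, e)), tr2)
    by_bp <- vals[ceiling(seq(s, e) / 100)]
    expect_equal(got, mean(by_bp), tolerance = 1e-9)
  }
})

test_that("interval timing of a union is the length-weighted mean of parts", {
  set.seed(15)
  tr <- step_track(rnorm(50, 0, 1))
  a <- GRanges("chrT", IRanges(101, 900))
  b <- GRanges("chrT", IRanges(901, 2100))
  ta <- interval_timing(a, tr); tb <- interval_timing(b, tr)
  tu <- interval_timing(GRanges("chrT", IRanges(101, 2100)), tr)
  expect_equal(tu, (ta * 800 + tb * 1200) / 2000, tolerance = 1e-12)
})

test_that("late segments use a strict below-threshold rule and merge runs", {
  tr <- step_track(c(-1.0, -0.5, -0.9), source = "repli_chip_log2ratio")
  late <- late_segments(tr, "repli_chip_below")
  expect_length(late, 2)
  expect_equal(start(late), c(1, 201))
  # exactly -0.8 is not late ("below" is strict)
  tr2 <- step_track(c(-0.8, -0.81), source = "repli_chip_log2ratio")
  late2 <- late_segments(tr2, "repli_chip_below")
  expect_equal(start(late2), 101)
  # all-early track yields the empty set
  expect_length(late_segments(step_track(rep(0.5, 4),
                                         source = "repli_chip_log2ratio"),
                              "repli_chip_below"), 0)
  # adjacent qualifying segments merge
  tr3 <- step_track(c(-1, -1, 0, -1), source = "repli_chip_log2ratio")
  expect_length(late_segments(tr3, "repli_chip_below"), 2)
  expect_error(late_segments(step_track(rep(1, 3)), "repli_chip_below"),
               "repli_chip")
})

test_that("late segmentation matches a brute-force scan and nests by cutoff", {
  set.seed(16)
  for (rep in 1:4) {
    vals <- rnorm(80, -0.5, 0.6)
    tr <- step_track(vals, source = "repli_chip_log2ratio")
    late <- late_segments(tr, "repli_chip_below")
    runs <- rle(vals < -0.8)
    expect_length(late, sum(runs$values))
    # permissive cutoffs contain strict ones
    strict <- late_segments(tr, "threshold", cutoff = -1.2)
    loose <- late_segments(tr, "threshold", cutoff = -0.4)
    expect_equal(sum(width(GenomicRanges::setdiff(strict, loose))), 0)
  }
})

test_that("timing histograms normalize to 100 and conserve bp", {
  g <- toy_genome(10000)
  set.seed(17)
  tr <- step_track(rnorm(100, 50, 15))
  tus <- GRanges("chrT", IRanges(c(1001, 5001), width = c(2000, 1000)),
                 strand = "+")
  tus$rpkm <- c(2, 1)
  out <- stratify_timing_by_transcription(g, tus, tr, n_hist_bins = 20)
  for (s in unique(out$stratum)) {
    expect_equal(sum(out$percent[out$stratum == s]), 100, tolerance = 1e-6)
  }
  summ <- attr(out, "summary")
  expect_equal(summ$bp[summ$stratum == "transcribed"] +
                 summ$bp[summ$stratum == "untranscribed"],
               g$mappable_bp)
  # with no TUs the genome and untranscribed traces coincide
  none <- stratify_timing_by_transcription(g, GRanges(), tr, n_hist_bins = 20)
  expect_equal(none$percent[none$stratum == "genome"],
               none$percent[none$stratum == "untranscribed"])
  expect_true(all(is.na(none$percent[none$stratum == "transcribed"])))
})

test_that("timing by TU length bins medians correctly and omits empty bins", {
  tr <- step_track(rep(60, 200), seg_len = 1000)
  tus <- GRanges("chrT", IRanges(c(1, 50001, 120001),
                                 width = c(30000, 150000, 50000)))
  out <- timing_by_tu_length(tus, tr, bin_width = 2e5)
  expect_equal(out$median_timing, 60) # flat field -> flat profile
  # empty length bins are absent rather than zero-filled
  tus2 <- GRanges("chrT", IRanges(c(1, 100001), width = c(10000, 90000)))
  out2 <- timing_by_tu_length(tus2, tr, bin_width = 2e4)
  expect_false(any(out2$n_tus == 0))
  expect_lt(nrow(out2), 5)
})

test_that("expression strata each normalize to 100 and a single stratum
           reproduces the transcribed trace", {
  g <- toy_genome(10000)
  set.seed(18)
  tr <- step_track(rnorm(100, 0, 1))
  tus <- GRanges("chrT", IRanges(c(501, 4001, 8001), width = c(1000, 2000, 500)))
  tus$rpkm <- c(0.5, 5, 50)
  strat <- timing_by_expression(tus, tr, probs = c(0, 0.5, 1), n_hist_bins = 10)
  for (s in unique(strat$stratum)) {
    expect_equal(sum(strat$percent[strat$stratum == s]), 100, tolerance = 1e-6)
  }
  single <- timing_by_expression(tus, tr, probs = c(0, 1), n_hist_bins = 10)
  full <- stratify_timing_by_transcription(g, tus, tr, n_hist_bins = 10)
  expect_equal(single$percent,
               full$percent[full$stratum == "transcribed"])
})
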