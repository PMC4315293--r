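# A toy track with rectangular signal blocks is enough to exercise the
# chaining logic; generator-based recovery is covered in the acceptance
# suite.
block_track <- function(len_bins = 1000, bin_size = 1e3, blocks = list(),
                        background = 0, strand = "+", total = 1e6) {
  v <- rep(background, len_bins)
  for (b in blocks) v[b$from:b$to] <- b$level
  coverage_track(list(chrT = v), bin_size, strand, total_reads = total)
}

test_that("rpkm follows its defining arithmetic and rejects degenerate input", {
  expect_equal(rpkm(1000, 1e3, 1e6), 1000)
  expect_equal(rpkm(0, 5e3, 1e7), 0)
  expect_equal(rpkm(250, 5e3, 2e7), 2.5)
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 1e3, 0), "total")
})

test_that("fixed and quantile thresholds behave as configured", {
  tr <- block_track(blocks = list(list(from = 100, to = 200, level = 50)))
  expect_equal(determine_threshold(tr, "fixed", value = 0.05), 0.05)
  expect_error(determine_threshold(tr, "fixed"), "positive")
  zero <- block_track()
  expect_error(determine_threshold(zero, "quantile"), "all-zero")
})

test_that("mixture threshold lands between well-separated log-RPKM modes", {
  # bimodal synthetic log10-RPKM: modes near -3 and 1 (sigma 0.5)
  set.seed(55)
  lr <- c(rnorm(4000, -3, 0.5), rnorm(2000, 1, 0.5))
  counts <- 10^lr * 1 * (1e6 / 1e6) # bin 1 kb, total 1e6 -> rpkm == count
  tr <- coverage_track(list(chrT = counts), 1e3, "+", total_reads = 1e6)
  th <- determine_threshold(tr, "mixture")
  expect_gt(log10(th), -3 + 0.7)
  expect_lt(log10(th), 1 - 0.7)
  # analytic equal-posterior crossing for these parameters:
  # (2/3) N(-3, 0.5) == (1/3) N(1, 0.5)  =>  x = (log(2) - 16) / 16
  expect_lt(abs(log10(th) - (log(2) - 16) / 16), 0.3)
})

test_that("TU calling chains blocks, bridges short gaps and drops short spans", {
  # one 500-bin block of supra-threshold signal -> one TU of 500 kb
  tr <- block_track(blocks = list(list(from = 101, to = 600, level = 100)))
  tus <- call_tus(tr, threshold = 1)
  expect_length(tus, 1)
  expect_equal(width(tus), 500e3)
  expect_equal(start(tus), 100e3 + 1)
  expect_equal(as.character(strand(tus)), "+")

  # two blocks split by a gap longer than max_internal_gap
  tr2 <- block_track(blocks = list(list(from = 101, to = 200, level = 100),
                                   list(from = 261, to = 360, level = 100)))
  expect_length(call_tus(tr2, 1, max_internal_gap = 1e4), 2)
  # the same layout with a bridgeable gap gives one TU spanning the gap
  tr3 <- block_track(blocks = list(list(from = 101, to = 200, level = 100),
                                   list(from = 206, to = 305, level = 100)))
  tus3 <- call_tus(tr3, 1, max_internal_gap = 1e4)
  expect_length(tus3, 1)
  expect_equal(width(tus3), 205e3)

  # spans below min_length are dropped
  tr4 <- block_track(blocks = list(list(from = 101, to = 105, level = 100)))
  expect_length(call_tus(tr4, 1, min_length = 1e4), 0)
})

test_that("raising the threshold never increases called bp", {
  set.seed(66)
  v <- rpois(2000, 0.2) + rep(c(0, 8, 0, 3, 0), each = 400)
  tr <- coverage_track(list(chrT = v), 1e3, "-", total_reads = 1e6)
  called_bp <- vapply(c(0.5, 1, 2, 4, 8) * rpkm(1, 1e3, 1e6), function(th) {
    sum(width(call_tus(tr, th)))
  }, 0)
  expect_true(all(diff(called_bp) <= 0))
})

test_that("TU calling is idempotent on its own output mask", {
  set.seed(77)
  v <- rpois(3000, 0.1) + rep(c(0, 12, 0), c(1200, 600, 1200))
  tr <- coverage_track(list(chrT = v), 1e3, "+", total_reads = 1e6)
  th <- 5 * rpkm(1, 1e3, 1e6)
  tus <- call_tus(tr, th)
  # rebuild a track equal to the output mask (level above threshold inside
  # TUs, zero elsewhere) and re-call
  mask <- rep(0, 3000)
  for (i in seq_along(tus)) {
    mask[(start(tus)[i] - 1) / 1e3 + 1:((width(tus)[i]) / 1e3)] <- 10
  }
  tr2 <- coverage_track(list(chrT = mask), 1e3, "+", total_reads = tr$total_reads)
  tus2 <- call_tus(tr2, th)
  expect_equal(granges(tus2), granges(tus))
})

test_that("strands are called independently and may overlap in genome space", {
  plus <- block_track(blocks = list(list(from = 101, to = 400, level = 50)),
                      strand = "+")
  minus <- block_track(blocks = list(list(from = 301, to = 700, level = 50)),
                       strand = "-")
  tp <- call_tus(plus, 1); tm <- call_tus(minus, 1)
  expect_equal(as.character(strand(tp)), "+")
  expect_equal(as.character(strand(tm)), "-")
  ov <- GenomicRanges::intersect(granges(tp), granges(tm), ignore.strand = TRUE)
  expect_gt(sum(width(ov)), 0) # genome-space overlap is allowed
})

test_that("length-class summaries match a brute-force filter", {
  g <- toy_genome(1e7)
  tus <- GRanges("chrT", IRanges(c(1, 2e6, 5e6), width = c(6e5, 5e4, 1.2e6)),
                 strand = "+")
  cls <- tu_length_classes(tus, g, cutoffs = c(1e5, 5e5, 1e6))
  expect_equal(cls$n_tus, c(2, 2, 1))
  expect_equal(cls$fraction_of_genome[2], (6e5 + 1.2e6) / 1e7)
  empty <- tu_length_classes(GRanges(), g)
  expect_true(all(empty$n_tus == 0) && all(empty$fraction_of_genome == 0))

  set.seed(88)
  w <- round(rlnorm(200, log(8e4), 1))
  tus2 <- GRanges("chrT", IRanges(seq(1, by = 4e4, length.out = 200), width = w))
  cls2 <- tu_length_classes(tus2, g)
  expect_equal(cls2$n_tus, vapply(c(1e5, 5e5, 1e6), function(cut) sum(w > cut), 0L))
})

test_that("merging coverage tracks sums counts and library totals", {
  a <- block_track(blocks = list(list(from = 1, to = 10, level = 5)), total = 1e6)
  b <- block_track(blocks = list(list(from = 5, to = 14, level = 3)), total = 2e6)
  m <- merge_coverage(a, b)
  expect_equal(m$total_reads, 3e6)
  expect_equal(m$counts$chrT[5], 8)
  expect_equal(m$counts$chrT[12], 3)
})

test_that("coverage bedGraph round-trips through the readers", {
  skip_if_not_installed("rtracklayer")
  set.seed(99)
  v_plus <- rpois(500, 0.5); v_minus <- rpois(500, 0.5)
  tp <- coverage_track(list(chrT = v_plus), 1e3, "+", total_reads = 1e6)
  tm <- coverage_track(list(chrT = v_minus), 1e3, "-", total_reads = 1e6)
  d <- withr::local_tempdir()
  write_coverage_bedgraph(tp, file.path(d, "p.bedgraph"))
  write_coverage_bedgraph(tm, file.path(d, "m.bedgraph"))
  back <- read_coverage_bedgraph(file.path(d, "p.bedgraph"),
                                 file.path(d, "m.bedgraph"),
                                 c(chrT = 5e5), 1e3,
                                 total_reads = c(1e6, 1e6))
  expect_equal(back$plus$counts$chrT, v_plus)
  expect_equal(back$minus$counts$chrT, v_minus)
})
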