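## Randomized-placement Monte Carlo: the null model for CNV clustering and
## feature-enrichment statistics. Placement law: chromosome drawn with
## probability proportional to its mappable bp, then a uniform start among the
## mappable slots on that chromosome that fit the interval entirely; placed
## intervals may overlap each other. Chromosomes with no fitting slot are
## redrawn (rejection), capped at 1e4 rounds.

# Per-chromosome table of mappable intervals (1-based starts and widths).
slot_table <- function(genome) {
  m <- genome$mappable
  split(data.frame(start = GenomicRanges::start(m),
                   width = GenomicRanges::width(m)),
        as.character(GenomicRanges::seqnames(m)))
}

#' Randomly place intervals in the mappable genome
#'
#' Draws `n_iter` independent placements of each input width under the
#' package's placement law (see Details in [enrichment_test()]): chromosome
#' proportional to mappable bp, uniform start among mappable slots that fit
#' the whole interval.
#'
#' @param widths Numeric vector of interval lengths in bp.
#' @param genome A [mappable_genome()].
#' @param n_iter Number of placements per width (>= 1).
#' @param seed Integer RNG seed; the same seed reproduces placements exactly.
#' @return `GRanges` of `n_iter * length(widths)` placements with metadata
#'   columns `iter` and `interval` (index into `widths`).
#' @export
permute_intervals <- function(widths, genome, n_iter, seed,
                              max_attempts = 1e4) {
  stopifnot(n_iter >= 1, length(widths) >= 1, all(widths >= 1))
  slots <- slot_table(genome)
  max_slot <- max(vapply(slots, function(s) max(s$width), 0))
  if (any(widths > max_slot)) {
    stop("interval ", which(widths > max_slot)[1], " (",
         max(widths), " bp) exceeds the longest mappable stretch (",
         max_slot, " bp)")
  }
  chrom_bp <- vapply(slots, function(s) sum(s$width), 0)
  chroms <- names(slots)
  set.seed(as.integer(seed))
  out_chrom <- character(0); out_start <- numeric(0)
  out_iter <- integer(0); out_idx <- integer(0)
  for (j in seq_along(widths)) {
    L <- widths[j]
    # per-chromosome valid-start structure for this width
    valid <- lapply(slots, function(s) {
      v <- pmax(0, s$width - L + 1)
      keep <- v > 0
      list(start = s$start[keep], cum = cumsum(v[keep]), total = sum(v))
    })
    total <- vapply(valid, `[[`, 0, "total")
    ch <- sample(chroms, n_iter, replace = TRUE, prob = chrom_bp)
    attempt <- 0
    while (any(bad <- total[ch] == 0)) {
      attempt <- attempt + 1
      if (attempt > max_attempts) {
        stop("could not place interval ", j, " after ", max_attempts, " attempts")
      }
      ch[bad] <- sample(chroms, sum(bad), replace = TRUE, prob = chrom_bp)
    }
    start <- numeric(n_iter)
    for (c in unique(ch)) {
      sel <- which(ch == c)
      vc <- valid[[c]]
      u <- floor(runif(length(sel)) * vc$total) + 1
      i <- findInterval(u - 0.5, c(0, vc$cum))
      start[sel] <- vc$start[i] + (u - c(0, vc$cum)[i]) - 1
    }
    out_chrom <- c(out_chrom, ch)
    out_start <- c(out_start, start)
    out_iter <- c(out_iter, seq_len(n_iter))
    out_idx <- c(out_idx, rep.int(j, n_iter))
  }
  gr <- GenomicRanges::GRanges(out_chrom,
                               IRanges::IRanges(start = out_start,
                                                width = rep(widths[out_idx])),
                               seqinfo = genome$seqinfo)
  gr$iter <- out_iter
  gr$interval <- out_idx
  gr
}

#' Score overlap of regions with a feature set
#'
#' The overlap scores used throughout the enrichment analyses:
#' * `boolean` — 1 if the region overlaps any feature, else 0 (group value:
#'   fraction of regions overlapping);
#' * `fraction_of_span` — overlapped bp / region span bp;
#' * `longest_feature_bp` — length of the longest individual feature
#'   intersecting the region (0 if none);
#' * `length_weighted_mean` — bp-weighted mean of a signal track over the
#'   region span (requires `signal`; `NA` where the region has no covered bp).
#'
#' @param regions `GRanges` of query regions.
#' @param features `GRanges` of features (strand ignored).
#' @param kind Score kind, see above.
#' @param signal For `length_weighted_mean`: a [timing_track()] or a
#'   `GRanges` with a numeric `score` column.
#' @return List with `per_region` (numeric vector) and `group` (mean of the
#'   per-region scores, `NA` values dropped).
#' @export
score_overlap <- function(regions,
                          features = NULL,
                          kind = c("boolean", "fraction_of_span",
                                   "longest_feature_bp", "length_weighted_mean"),
                          signal = NULL) {
  kind <- match.arg(kind)
  n <- length(regions)
  if (kind == "length_weighted_mean") {
    if (is.null(signal)) stop("length_weighted_mean requires a signal track")
    seg <- if (is(signal, "timing_track")) signal$segments else signal
    per <- weighted_signal_mean(regions, seg)
  } else {
    if (is.null(features)) stop("kind '", kind, "' requires a feature set")
    per <- numeric(n)
    if (kind == "boolean") {
      per <- as.numeric(GenomicRanges::countOverlaps(
        regions, features, ignore.strand = TRUE) > 0)
    } else if (kind == "fraction_of_span") {
      red <- GenomicRanges::reduce(features, ignore.strand = TRUE)
      hits <- GenomicRanges::findOverlaps(regions, red, ignore.strand = TRUE)
      if (length(hits)) {
        ov <- GenomicRanges::width(IRanges::pintersect(
          GenomicRanges::granges(regions)[S4Vectors::queryHits(hits)],
          GenomicRanges::granges(red)[S4Vectors::subjectHits(hits)],
          ignore.strand = TRUE))
        agg <- rowsum(ov, S4Vectors::queryHits(hits))
        per[as.integer(rownames(agg))] <- agg[, 1]
      }
      per <- per / GenomicRanges::width(regions)
    } else { # longest_feature_bp
      hits <- GenomicRanges::findOverlaps(regions, features, ignore.strand = TRUE)
      if (length(hits)) {
        w <- GenomicRanges::width(features)[S4Vectors::subjectHits(hits)]
        agg <- tapply(w, S4Vectors::queryHits(hits), max)
        per[as.integer(names(agg))] <- agg
      }
    }
  }
  list(per_region = per, group = mean(per, na.rm = TRUE))
}

# bp-weighted mean of a piecewise-constant signal over each query interval.
weighted_signal_mean <- function(query, segments) {
  n <- length(query)
  hits <- GenomicRanges::findOverlaps(query, segments, ignore.strand = TRUE)
  out <- rep(NA_real_, n)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::granges(query)[qh],
      GenomicRanges::granges(segments)[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    val <- segments$score[S4Vectors::subjectHits(hits)]
    num <- rowsum(ov * val, qh)
    den <- rowsum(ov, qh)
    out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  }
  out
}

#' Empirical Monte-Carlo p-value with add-one correction
#'
#' `p = (1 + #\{iterations at least as extreme as actual\}) / (n_iter + 1)`;
#' never 0 by construction. `tie_break = "randomized"` instead returns the
#' exchangeable-rank p-value (uniform ties broken at random), which is exactly
#' discrete-uniform under the null and is the form used for calibration
#' checks of discrete statistics.
#'
#' @param actual Observed statistic.
#' @param iterations Vector of null-simulated statistics.
#' @param direction `"enriched"` (large values extreme) or `"depleted"`.
#' @param tie_break `"conservative"` (default) or `"randomized"`.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(actual, iterations,
                        direction = c("enriched", "depleted"),
                        tie_break = c("conservative", "randomized")) {
  direction <- match.arg(direction)
  tie_break <- match.arg(tie_break)
  n <- length(iterations)
  if (direction == "depleted") {
    actual <- -actual
    iterations <- -iterations
  }
  if (tie_break == "conservative") {
    (1 + sum(iterations >= actual)) / (n + 1)
  } else {
    r <- sum(iterations > actual)
    t <- sum(iterations == actual)
    (r + sample.int(t + 1, 1)) / (n + 1)
  }
}

#' Feature-enrichment permutation test for CNV regions
#'
#' Compares the actual group overlap score of `regions` with the
#' distribution of the same score over `n_iter` randomized placements of
#' equally sized intervals in the mappable genome.
#'
#' @inheritParams score_overlap
#' @param genome A [mappable_genome()]; the placement space.
#' @param n_iter Number of simulation iterations (default 1000).
#' @param seed Integer RNG seed.
#' @param direction `"auto"` (one-sided in the observed direction, chosen by
#'   the sign of actual minus iteration median), `"enriched"` or
#'   `"depleted"`.
#' @return A `permutation_result`: list with `actual`, `iterations`,
#'   `n_iter`, `seed`, `p_emp`, `direction`, `kind`, `n_regions`.
#' @export
enrichment_test <- function(regions, features = NULL,
                            kind = "fraction_of_span",
                            genome, n_iter = 1000, seed = 1,
                            direction = c("auto", "enriched", "depleted"),
                            signal = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(regions) >= 1)
  actual <- score_overlap(regions, features, kind, signal = signal)$group
  placed <- permute_intervals(GenomicRanges::width(regions), genome,
                              n_iter = n_iter, seed = seed)
  per <- score_overlap(placed, features, kind, signal = signal)$per_region
  iters <- as.numeric(tapply(per, placed$iter, mean, na.rm = TRUE))
  if (direction == "auto") {
    direction <- if (actual >= median(iters)) "enriched" else "depleted"
  }
  structure(
    list(actual = actual, iterations = iters, n_iter = n_iter, seed = seed,
         p_emp = empirical_p(actual, iters, direction),
         direction = direction, kind = kind, n_regions = length(regions)),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %d regions, %d iterations)\n  actual = %.4g, iteration median = %.4g\n  %s, p_emp = %.4g\n",
    x$kind, x$n_regions, x$n_iter, x$actual, median(x$iterations),
    x$direction, x$p_emp))
  invisible(x)
}

#' Enrichment tests stratified by region class
#'
#' Runs [enrichment_test()] separately for each `region_class` group
#' (singleton / cluster / hotspot) present in `regions`.
#'
#' @inheritParams enrichment_test
#' @return Named list of `permutation_result`, one per class.
#' @export
enrichment_test_by_class <- function(regions, features = NULL,
                                     kind = "fraction_of_span",
                                     genome, n_iter = 1000, seed = 1,
                                     direction = "auto", signal = NULL) {
  if (is.null(regions$region_class)) stop("regions must be classified first")
  groups <- split(seq_along(regions), droplevels(regions$region_class))
  res <- lapply(seq_along(groups), function(i) {
    enrichment_test(regions[groups[[i]]], features, kind, genome,
                    n_iter = n_iter, seed = seed + i - 1,
                    direction = direction, signal = signal)
  })
  names(res) <- names(groups)
  res
}

#' Significance of CNV clustering by random placement
#'
#' Places the individual CNV calls (lengths preserved) at random in the
#' mappable genome `n_iter` times, merges each placement with the same
#' `max_gap` chaining rule as the actual data, and asks how often the random
#' sets produce at least one region with `k` or more members.
#'
#' @param cnvs `GRanges` of (size-filtered) CNV calls.
#' @param genome A [mappable_genome()].
#' @param max_gap Merge gap in bp (default 750 kb).
#' @param k Member-count threshold defining a hotspot (default 5).
#' @param n_iter,seed Monte Carlo settings.
#' @return List with `p_ge_k` (add-one fraction of iterations with a >= k
#'   region), `observed_max`, `observed_n_regions`, and the per-iteration
#'   statistics `iter_max` and `iter_n_regions`.
#' @export
clustering_significance <- function(cnvs, genome, max_gap = 750e3, k = 5,
                                    n_iter = 1000, seed = 1) {
  stopifnot(k >= 2, n_iter >= 1)
  obs <- merge_to_regions(cnvs, max_gap)
  placed <- permute_intervals(GenomicRanges::width(cnvs), genome,
                              n_iter = n_iter, seed = seed)
  # merge all iterations at once on composite iteration x chromosome keys
  key <- paste(placed$iter, as.character(GenomicRanges::seqnames(placed)), sep = "|")
  gr <- GenomicRanges::GRanges(key, IRanges::ranges(placed))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1, with.revmap = TRUE)
  counts <- lengths(red$revmap)
  reg_iter <- as.integer(sub("\\|.*", "", as.character(GenomicRanges::seqnames(red))))
  iter_max <- as.integer(tapply(counts, factor(reg_iter, levels = seq_len(n_iter)), max))
  iter_n_regions <- as.integer(tabulate(reg_iter, nbins = n_iter))
  list(p_ge_k = (1 + sum(iter_max >= k)) / (n_iter + 1),
       observed_max = max(obs$n_cnvs),
       observed_n_regions = length(obs),
       iter_max = iter_max,
       iter_n_regions = iter_n_regions,
       n_iter = n_iter, seed = seed, k = k, max_gap = max_gap)
}

#' TU-permutation test of CNV correspondence by TU length
#'
#' The reciprocal of the region permutation: transcription units are binned
#' by length, and for each bin the actual percentage of TUs overlapping at
#' least one CNV is compared with randomly placed TUs of the same lengths.
#'
#' @param tus `GRanges` of transcription units.
#' @param genome A [mappable_genome()].
#' @param cnvs `GRanges` of CNV calls.
#' @param n_iter,seed Monte Carlo settings.
#' @param length_bins Numeric bp edges covering the TU length range.
#' @return `data.frame` per bin: `bin_left`, `bin_right`, `n_tus`,
#'   `actual_pct`, `perm_mean_pct`, `perm_q025`, `perm_q975`, `p_emp`.
#' @export
permute_tus <- function(tus, genome, cnvs, n_iter = 1000, seed = 1,
                        length_bins) {
  w <- GenomicRanges::width(tus)
  stopifnot(length(length_bins) >= 2)
  if (min(w) < min(length_bins) || max(w) > max(length_bins)) {
    stop("length_bins must cover the TU length range")
  }
  bin <- cut(w, length_bins, include.lowest = TRUE, right = TRUE)
  actual_hit <- GenomicRanges::countOverlaps(tus, cnvs, ignore.strand = TRUE) > 0
  actual_pct <- tapply(actual_hit, bin, function(h) 100 * mean(h))
  placed <- permute_intervals(w, genome, n_iter = n_iter, seed = seed)
  hit <- GenomicRanges::countOverlaps(placed, cnvs, ignore.strand = TRUE) > 0
  pbin <- bin[placed$interval]
  # per (iteration, bin) percentage
  perm <- tapply(hit, list(placed$iter, pbin), function(h) 100 * mean(h))
  lev <- levels(bin)
  out <- data.frame(
    bin_left = length_bins[-length(length_bins)],
    bin_right = length_bins[-1],
    n_tus = as.integer(table(bin)),
    actual_pct = as.numeric(actual_pct))
  out$perm_mean_pct <- vapply(lev, function(l) mean(perm[, l], na.rm = TRUE), 0)
  out$perm_q025 <- vapply(lev, function(l) quantile(perm[, l], 0.025, na.rm = TRUE, names = FALSE), 0)
  out$perm_q975 <- vapply(lev, function(l) quantile(perm[, l], 0.975, na.rm = TRUE, names = FALSE), 0)
  out$p_emp <- vapply(seq_along(lev), function(i) {
    if (out$n_tus[i] == 0) return(NA_real_)
    empirical_p(out$actual_pct[i], perm[, lev[i]][!is.na(perm[, lev[i]])], "enriched")
  }, 0)
  out
}
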