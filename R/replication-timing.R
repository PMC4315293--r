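#' Construct a replication-timing track
#'
#' A piecewise-constant replication-timing signal over genomic segments.
#' Two source conventions are supported: `repli_seq_score` (weighted-average
#' S-phase timing score; higher = earlier replication) and
#' `repli_chip_log2ratio` (early/late log2 ratio at array probes projected to
#' segments; higher = earlier).
#'
#' @param segments `GRanges` with a numeric `score` metadata column;
#'   segments must not overlap.
#' @param source `"repli_seq_score"` or `"repli_chip_log2ratio"`.
#' @return Object of class `timing_track`.
#' @export
timing_track <- function(segments, source = c("repli_seq_score",
                                              "repli_chip_log2ratio")) {
  source <- match.arg(source)
  stopifnot(is(segments, "GRanges"), !is.null(segments$score))
  segments <- GenomicRanges::sort(segments, ignore.strand = TRUE)
  if (length(segments) > 1) {
    ov <- GenomicRanges::findOverlaps(segments, drop.self = TRUE,
                                      ignore.strand = TRUE)
    if (length(ov)) stop("timing segments must not overlap")
  }
  structure(list(segments = segments, source = source), class = "timing_track")
}

#' @export
print.timing_track <- function(x, ...) {
  cat(sprintf("timing_track (%s): %d segments, %.3g bp covered\n",
              x$source, length(x$segments),
              sum(GenomicRanges::width(x$segments))))
  invisible(x)
}

#' Project probe-level timing ratios onto the genome
#'
#' Nearest-probe step-function projection: each inter-probe midpoint splits
#' the space between two probes, so a probe's ratio covers from the previous
#' midpoint to the next; terminal probes extend to the chromosome ends.
#'
#' @param probes `data.frame` with columns `chrom`, `position` (bp, 1-based)
#'   and `ratio`; at least two probes per chromosome, strictly increasing
#'   positions.
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param source Track source label (default `"repli_chip_log2ratio"`).
#' @return A [timing_track()] covering each probed chromosome end to end.
#' @export
project_probes <- function(probes, chrom_sizes,
                           source = "repli_chip_log2ratio") {
  stopifnot(all(c("chrom", "position", "ratio") %in% names(probes)))
  segs <- lapply(split(probes, probes$chrom), function(p) {
    chrom <- p$chrom[1]
    if (!chrom %in% names(chrom_sizes)) stop("unknown chromosome: ", chrom)
    p <- p[order(p$position), ]
    if (nrow(p) < 2) stop("need >= 2 probes on chromosome ", chrom)
    if (anyDuplicated(p$position)) stop("duplicate probe positions on ", chrom)
    mid <- floor((p$position[-nrow(p)] + p$position[-1]) / 2)
    start <- c(1, mid + 1)
    end <- c(mid, chrom_sizes[[chrom]])
    data.frame(chrom = chrom, start = start, end = end, score = p$ratio)
  })
  df <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$score <- df$score
  timing_track(gr, source = source)
}

#' Read a timing track from a bedGraph file
#'
#' @param path bedGraph of timing values over segments.
#' @param source Track source convention (see [timing_track()]).
#' @return A `timing_track`.
#' @export
read_timing_bedgraph <- function(path, source = "repli_seq_score") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read bedGraph files")
  }
  timing_track(rtracklayer::import(path, format = "bedGraph"), source = source)
}

#' Length-weighted mean replication timing of intervals
#'
#' @param iv `GRanges` of query intervals.
#' @param track A [timing_track()].
#' @return Numeric vector: bp-weighted mean timing per interval, `NA` where
#'   an interval has no timing coverage (never silently 0).
#' @export
interval_timing <- function(iv, track) {
  stopifnot(is(track, "timing_track"))
  weighted_signal_mean(iv, track$segments)
}

#' Classify late-replicating segments
#'
#' Maximal runs of timing segments satisfying a lateness rule, with adjacent
#' qualifying segments merged. For Repli-chip log ratios the published rule
#' is "ratio below -0.8" (strict `<`); for Repli-seq scores lateness is a
#' score below a cutoff (precomputed external segmentations can instead be
#' supplied directly as a `GRanges` wherever a `LateSegmentSet` is accepted).
#'
#' @param track A [timing_track()].
#' @param rule `"repli_chip_below"` (requires a `repli_chip_log2ratio`
#'   track) or `"threshold"` (any source).
#' @param cutoff Lateness cutoff (default -0.8, the Repli-chip convention).
#' @return `GRanges` of merged late segments (class attribute
#'   `late_segment_set`).
#' @export
late_segments <- function(track, rule = c("repli_chip_below", "threshold"),
                          cutoff = -0.8) {
  rule <- match.arg(rule)
  stopifnot(is(track, "timing_track"))
  if (rule == "repli_chip_below" && track$source != "repli_chip_log2ratio") {
    stop("rule 'repli_chip_below' requires a repli_chip_log2ratio track")
  }
  late <- track$segments[track$segments$score < cutoff]
  out <- GenomicRanges::reduce(GenomicRanges::granges(late), min.gapwidth = 1)
  S4Vectors::metadata(out) <- list(rule = rule, cutoff = cutoff)
  out
}

# bp-weighted histogram of a piecewise signal restricted to a region set;
# returns percentages summing to 100 (or all-NA when the stratum is empty).
bp_weighted_hist <- function(track, regions, breaks) {
  seg <- track$segments
  if (length(regions) == 0) {
    return(rep(NA_real_, length(breaks) - 1))
  }
  red <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(seg, red, ignore.strand = TRUE)
  if (!length(hits)) return(rep(NA_real_, length(breaks) - 1))
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::granges(seg)[S4Vectors::queryHits(hits)],
    GenomicRanges::granges(red)[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  v <- seg$score[S4Vectors::queryHits(hits)]
  bin <- cut(v, breaks, include.lowest = TRUE)
  bp <- tapply(w, bin, sum, default = 0)
  100 * as.numeric(bp) / sum(w)
}

#' Replication-timing distributions for transcribed vs untranscribed genome
#'
#' Splits the mappable genome into its transcribed (TU-covered) and
#' untranscribed complements and returns, per stratum, the bp-weighted
#' distribution of timing values normalized to 100%.
#'
#' @param genome A [mappable_genome()].
#' @param tus `GRanges` of TUs (strand ignored; overlapping TUs are fused).
#' @param track A [timing_track()].
#' @param n_hist_bins Number of equal-width histogram bins over the track's
#'   value range (default 40).
#' @return `data.frame` with columns `stratum` (`genome`, `transcribed`,
#'   `untranscribed`), `bin_left`, `bin_right`, `percent`. The attribute
#'   `summary` holds per-stratum aggregate bp and, when `tus` carry an
#'   `rpkm` column, the bp-weighted mean TU RPKM of the transcribed stratum.
#' @export
stratify_timing_by_transcription <- function(genome, tus, track,
                                             n_hist_bins = 40) {
  rng <- range(track$segments$score)
  breaks <- seq(rng[1], rng[2], length.out = n_hist_bins + 1)
  transcribed <- GenomicRanges::intersect(
    GenomicRanges::reduce(GenomicRanges::granges(tus), ignore.strand = TRUE),
    genome$mappable, ignore.strand = TRUE)
  untranscribed <- GenomicRanges::setdiff(genome$mappable, transcribed,
                                          ignore.strand = TRUE)
  strata <- list(genome = genome$mappable, transcribed = transcribed,
                 untranscribed = untranscribed)
  out <- do.call(rbind, lapply(names(strata), function(s) {
    data.frame(stratum = s,
               bin_left = breaks[-length(breaks)],
               bin_right = breaks[-1],
               percent = bp_weighted_hist(track, strata[[s]], breaks))
  }))
  summ <- data.frame(
    stratum = names(strata),
    bp = vapply(strata, function(g) sum(GenomicRanges::width(g)), 0))
  if (!is.null(tus$rpkm) && length(tus)) {
    summ$mean_rpkm <- c(NA, sum(tus$rpkm * GenomicRanges::width(tus)) /
                          sum(GenomicRanges::width(tus)), NA)
  }
  attr(out, "summary") <- summ
  out
}

#' Median replication timing by TU length bin
#'
#' Stratifies TUs into fixed-width length bins (default 200 kb) and reports
#' the median per-TU mean timing in each occupied bin; TUs without timing
#' coverage are excluded. Empty bins are omitted, not zero-filled.
#'
#' @param tus `GRanges` of TUs.
#' @param track A [timing_track()].
#' @param bin_width Length-bin width in bp (default 200 kb).
#' @return `data.frame` per occupied bin: `bin_left`, `bin_right`, `n_tus`,
#'   `median_timing`; attribute `genome_median` gives the bp-weighted
#'   genome-wide median timing reference.
#' @export
timing_by_tu_length <- function(tus, track, bin_width = 2e5) {
  stopifnot(bin_width > 0)
  t_tu <- interval_timing(tus, track)
  ok <- !is.na(t_tu)
  w <- GenomicRanges::width(tus)[ok]
  t_tu <- t_tu[ok]
  bin <- floor((w - 1) / bin_width)
  agg <- tapply(t_tu, bin, median)
  cnt <- table(bin)
  lev <- as.numeric(names(agg))
  seg_w <- GenomicRanges::width(track$segments)
  ord <- order(track$segments$score)
  cum <- cumsum(seg_w[ord]) / sum(seg_w)
  genome_median <- track$segments$score[ord][which(cum >= 0.5)[1]]
  out <- data.frame(bin_left = lev * bin_width,
                    bin_right = (lev + 1) * bin_width,
                    n_tus = as.integer(cnt),
                    median_timing = as.numeric(agg))
  attr(out, "genome_median") <- genome_median
  out[order(out$bin_left), ]
}

#' Timing distributions of the transcribed genome by transcription intensity
#'
#' Partitions TU bp by TU RPKM quantile strata and returns a bp-weighted
#' timing histogram per stratum, each normalized to 100%.
#'
#' @param tus `GRanges` of TUs with an `rpkm` metadata column.
#' @param track A [timing_track()].
#' @param probs Increasing RPKM quantile edges defining the strata (default
#'   quartiles `c(0, .25, .5, .75, 1)`).
#' @param n_hist_bins Histogram bins over the timing range.
#' @return `data.frame` with `stratum` (quantile interval label),
#'   `bin_left`, `bin_right`, `percent`.
#' @export
timing_by_expression <- function(tus, track, probs = c(0, 0.25, 0.5, 0.75, 1),
                                 n_hist_bins = 40) {
  stopifnot(!is.null(tus$rpkm), all(diff(probs) > 0))
  rng <- range(track$segments$score)
  breaks <- seq(rng[1], rng[2], length.out = n_hist_bins + 1)
  edges <- quantile(tus$rpkm, probs, names = FALSE)
  stratum <- cut(tus$rpkm, unique(edges), include.lowest = TRUE)
  do.call(rbind, lapply(levels(stratum), function(s) {
    sel <- GenomicRanges::granges(tus)[!is.na(stratum) & stratum == s]
    data.frame(stratum = s,
               bin_left = breaks[-length(breaks)],
               bin_right = breaks[-1],
               percent = bp_weighted_hist(track, sel, breaks))
  }))
}
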