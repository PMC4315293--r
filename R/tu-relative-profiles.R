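## Percent-coordinate ("metagene") transform: positions are expressed as the
## percentage distance along a transcription unit, TSS = 0%, TES = 100%,
## strand-aware (on the minus strand genomic decrease is percent increase).
## Flanking positions map below 0% / above 100% by design.

#' Map a genomic position to TU-relative percent coordinates
#'
#' @param pos Genomic bp position(s).
#' @param tu A single-TU `GRanges` (length 1) with strand.
#' @return Percent coordinate(s): 0 at the TSS, 100 at the TES.
#' @examples
#' tu <- GenomicRanges::GRanges("chr1:1001-2000:-")
#' to_relative(1250, tu) # 75
#' @export
to_relative <- function(pos, tu) {
  stopifnot(length(tu) == 1)
  s <- GenomicRanges::start(tu); e <- GenomicRanges::end(tu)
  L <- e - s + 1
  if (as.character(GenomicRanges::strand(tu)) == "-") {
    100 * (e - pos) / L
  } else {
    100 * (pos - s) / L
  }
}

#' Inverse of [to_relative()]
#'
#' @param percent Percent coordinate(s).
#' @param tu A single-TU `GRanges` (length 1).
#' @return Genomic bp position(s) (possibly fractional; round as needed).
#' @export
from_relative <- function(percent, tu) {
  stopifnot(length(tu) == 1)
  s <- GenomicRanges::start(tu); e <- GenomicRanges::end(tu)
  L <- e - s + 1
  if (as.character(GenomicRanges::strand(tu)) == "-") {
    e - percent * L / 100
  } else {
    s + percent * L / 100
  }
}

#' CNV crossing profile in TU-relative coordinates
#'
#' For every (CNV, TU) pair in which the CNV intersects the TU span extended
#' by `flank_percent` of the TU length on each side, the CNV span is mapped
#' to percent coordinates and increments every grid point it crosses.
#' Deletions and duplications are profiled separately. A CNV intersecting
#' several eligible TUs contributes to each alignment (set
#' `multi_tu = "once"` to count each CNV only at its largest-overlap TU).
#'
#' @param cnvs `GRanges` of CNV calls with a `cnv_type` column.
#' @param tus `GRanges` of TUs with strand.
#' @param length_min,length_max TU length window in bp selecting the aligned
#'   subset (e.g. `5e5, Inf` for large TUs; `5e4, 2e5` for small ones).
#' @param flank_percent Flank extent in percent of TU length on each side
#'   (default 100: one TU length).
#' @param grid_step Grid spacing in percent (default 1).
#' @param multi_tu `"each"` (default) or `"once"`.
#' @return `data.frame` with columns `percent`, `deletions`, `duplications`
#'   (integer crossing counts); attribute `n_tus` is the aligned TU count.
#' @export
cnv_crossing_profile <- function(cnvs, tus, length_min = 5e5,
                                 length_max = Inf, flank_percent = 100,
                                 grid_step = 1,
                                 multi_tu = c("each", "once")) {
  multi_tu <- match.arg(multi_tu)
  w <- GenomicRanges::width(tus)
  sel <- tus[w >= length_min & w <= length_max]
  if (!length(sel)) stop("no TUs in the requested length window")
  grid <- seq(-flank_percent, 100 + flank_percent, by = grid_step)
  del <- integer(length(grid)); dup <- integer(length(grid))
  ext <- GenomicRanges::resize(GenomicRanges::granges(sel),
                               width = round(GenomicRanges::width(sel) *
                                               (1 + 2 * flank_percent / 100)),
                               fix = "center")
  hits <- GenomicRanges::findOverlaps(cnvs, ext, ignore.strand = TRUE)
  if (multi_tu == "once" && length(hits)) {
    ovw <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::granges(cnvs)[S4Vectors::queryHits(hits)],
      GenomicRanges::granges(ext)[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    keep <- unlist(lapply(split(seq_along(hits), S4Vectors::queryHits(hits)),
                          function(i) i[which.max(ovw[i])]), use.names = FALSE)
    hits <- hits[sort(keep)]
  }
  for (h in seq_along(hits)) {
    ci <- S4Vectors::queryHits(hits)[h]
    ti <- S4Vectors::subjectHits(hits)[h]
    tu <- sel[ti]
    # map the CNV's half-open boundaries so a CNV covering the last
    # transcribed base reaches the 100% grid point
    cs <- GenomicRanges::start(cnvs)[ci]; ce <- GenomicRanges::end(cnvs)[ci]
    pts <- if (as.character(GenomicRanges::strand(tu)) == "-") {
      c(cs - 1, ce)
    } else {
      c(cs, ce + 1)
    }
    p <- sort(to_relative(pts, tu))
    cross <- grid >= p[1] & grid <= p[2]
    if (cnvs$cnv_type[ci] == "deletion") del <- del + cross else dup <- dup + cross
  }
  out <- data.frame(percent = grid, deletions = del, duplications = dup)
  attr(out, "n_tus") <- length(sel)
  out
}

#' Replication timing along one TU, rescaled to its own min-max range
#'
#' Samples the timing track on a percent-coordinate grid across the TU and
#' rescales by the minimum and maximum timing within the TU body (0-100%),
#' so 0 marks the latest and 1 the earliest point of the unit regardless of
#' its absolute timing.
#'
#' @param tu A single-TU `GRanges` (length 1).
#' @param track A [timing_track()].
#' @param grid_step Grid spacing in percent.
#' @param flank_percent Flank extent in percent (default 0: TU body only).
#' @return `data.frame` with `percent` and `value` in `[0,1]` inside the
#'   body, or `NULL` when the TU has fewer than two distinct covered timing
#'   values (degenerate; excluded from aggregation).
#' @export
relative_timing <- function(tu, track, grid_step = 1, flank_percent = 0) {
  stopifnot(length(tu) == 1)
  grid <- seq(-flank_percent, 100 + flank_percent, by = grid_step)
  pos <- round(from_relative(grid, tu))
  # the 100% point is the half-open end, one past the last transcribed base;
  # clamp body samples inside the unit
  body_idx <- grid >= 0 & grid <= 100
  pos[body_idx] <- pmin(pmax(pos[body_idx], GenomicRanges::start(tu)),
                        GenomicRanges::end(tu))
  chrom <- as.character(GenomicRanges::seqnames(tu))
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  hits <- GenomicRanges::findOverlaps(pts, track$segments, select = "first",
                                      ignore.strand = TRUE)
  vals <- ifelse(is.na(hits), NA_real_, track$segments$score[hits])
  body <- vals[grid >= 0 & grid <= 100]
  body <- body[!is.na(body)]
  if (length(unique(body)) < 2) return(NULL)
  lo <- min(body); hi <- max(body)
  data.frame(percent = grid, value = (vals - lo) / (hi - lo))
}

#' Aggregate relative replication timing over a TU length stratum
#'
#' @inheritParams cnv_crossing_profile
#' @param track A [timing_track()].
#' @return `data.frame` with `percent`, `mean`, `median`, `n_tus`
#'   (contributing TUs per grid point); TUs with degenerate (constant or
#'   uncovered) timing are excluded and counted in the attribute
#'   `n_excluded`.
#' @export
aggregate_relative_timing <- function(tus, track, length_min = 5e5,
                                      length_max = Inf, grid_step = 1,
                                      flank_percent = 0) {
  w <- GenomicRanges::width(tus)
  sel <- tus[w >= length_min & w <= length_max]
  if (!length(sel)) stop("no TUs in the requested length window")
  profiles <- lapply(seq_along(sel), function(i) {
    relative_timing(sel[i], track, grid_step = grid_step,
                    flank_percent = flank_percent)
  })
  keep <- !vapply(profiles, is.null, TRUE)
  if (!any(keep)) stop("no TU has non-degenerate timing coverage")
  mat <- do.call(cbind, lapply(profiles[keep], `[[`, "value"))
  grid <- profiles[keep][[1]]$percent
  out <- data.frame(
    percent = grid,
    mean = rowMeans(mat, na.rm = TRUE),
    median = apply(mat, 1, median, na.rm = TRUE),
    n_tus = rowSums(!is.na(mat)))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Fraction of CNVs with an endpoint inside a TU
#'
#' An endpoint counts when its bp position lies within any TU span; the
#' fraction is over the supplied CNVs (pass the member calls of singleton
#' regions to reproduce the singleton statistic).
#'
#' @param cnvs `GRanges` of CNV calls.
#' @param tus `GRanges` of TUs (strand ignored).
#' @return Fraction in `[0,1]` of CNVs with >= 1 endpoint inside a TU.
#' @export
endpoint_in_tu_fraction <- function(cnvs, tus) {
  if (!length(cnvs)) return(NA_real_)
  ends <- c(GenomicRanges::GRanges(GenomicRanges::seqnames(cnvs),
                                   IRanges::IRanges(GenomicRanges::start(cnvs), width = 1)),
            GenomicRanges::GRanges(GenomicRanges::seqnames(cnvs),
                                   IRanges::IRanges(GenomicRanges::end(cnvs), width = 1)))
  hit <- GenomicRanges::countOverlaps(ends, tus, ignore.strand = TRUE) > 0
  n <- length(cnvs)
  mean(hit[seq_len(n)] | hit[n + seq_len(n)])
}
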