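#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s) in the span.
#' @param length_bp Span length in bp (> 0).
#' @param total Total mapped reads in the library (> 0).
#' @return RPKM value(s): `count / (length_bp/1e3) / (total/1e6)`.
#' @examples
#' rpkm(1000, 1e3, 1e6) # 1000
#' @export
rpkm <- function(count, length_bp, total) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total <= 0)) stop("total mapped reads must be positive")
  count / (length_bp / 1e3) / (total / 1e6)
}

#' Construct a strand-specific binned coverage track
#'
#' Nascent-RNA (e.g. Bru-seq) read counts in fixed-width bins tiling each
#' chromosome, one track per strand.
#'
#' @param counts Named list (by chromosome) of non-negative numeric vectors
#'   of per-bin read counts.
#' @param bin_size Bin width in bp.
#' @param strand `"+"` or `"-"`.
#' @param total_reads Total mapped reads of the library (defaults to the sum
#'   of `counts`; pass the library total explicitly when the track is a
#'   subset).
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(counts, bin_size, strand = c("+", "-"),
                           total_reads = NULL) {
  strand <- match.arg(strand)
  stopifnot(is.list(counts), !is.null(names(counts)), bin_size >= 1)
  if (any(vapply(counts, function(x) any(x < 0), TRUE))) {
    stop("bin counts must be non-negative")
  }
  if (is.null(total_reads)) total_reads <- sum(vapply(counts, sum, 0))
  structure(list(counts = counts, bin_size = bin_size, strand = strand,
                 total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s strand): %d chromosome(s), %d-bp bins, %.3g mapped reads\n",
              x$strand, length(x$counts), x$bin_size, x$total_reads))
  invisible(x)
}

#' Merge coverage tracks (e.g. untreated + treated libraries)
#'
#' Sums per-bin counts and totals of same-strand, same-binning tracks.
#'
#' @param ... Two or more `coverage_track`s.
#' @return A merged `coverage_track`.
#' @export
merge_coverage <- function(...) {
  tracks <- list(...)
  stopifnot(length(tracks) >= 2)
  t1 <- tracks[[1]]
  for (t in tracks[-1]) {
    stopifnot(t$strand == t1$strand, t$bin_size == t1$bin_size,
              identical(names(t$counts), names(t1$counts)))
    t1$counts <- Map(`+`, t1$counts, t$counts)
    t1$total_reads <- t1$total_reads + t$total_reads
  }
  t1
}

# Per-bin RPKM vectors for a track.
track_rpkm <- function(track) {
  lapply(track$counts, rpkm, length_bp = track$bin_size,
         total = track$total_reads)
}

# Evaluate an expression under a temporary RNG state.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Determine the RPKM threshold separating active transcription from noise
#'
#' `mixture` fits a two-component Gaussian mixture to the log10 RPKM of
#' nonzero bins and returns the signal/noise posterior-equality crossing
#' between the component means — an empirical stand-in for a transcription
#' threshold chosen from the bin intensity distribution. If the mixture
#' degenerates (one component preferred by BIC, or no crossing between the
#' means), it falls back to `quantile` with a warning.
#'
#' @param track A `coverage_track` (or list of tracks; bins are pooled).
#' @param method `"mixture"`, `"quantile"` or `"fixed"`.
#' @param quantile_p Genome-wide RPKM quantile for `method = "quantile"`
#'   (default 0.95, over all bins including zeros).
#' @param value Threshold for `method = "fixed"`.
#' @param max_bins Cap on nonzero bins used for the mixture fit (subsampled
#'   deterministically if exceeded).
#' @return RPKM threshold (positive scalar).
#' @export
determine_threshold <- function(track, method = c("mixture", "quantile", "fixed"),
                                quantile_p = 0.95, value = NULL,
                                max_bins = 5e4) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || value <= 0) stop("fixed method requires a positive value")
    return(value)
  }
  tracks <- if (is(track, "coverage_track")) list(track) else track
  r <- unlist(lapply(tracks, function(t) unlist(track_rpkm(t), use.names = FALSE)),
              use.names = FALSE)
  if (!length(r) || all(r == 0)) stop("coverage track is empty (all-zero)")
  if (method == "quantile") {
    th <- quantile(r, quantile_p, names = FALSE)
    if (th <= 0) th <- min(r[r > 0])
    return(th)
  }
  # log RPKM of nonzero bins, with half-unit uniform dithering of the counts
  # so that low-count Poisson atoms do not present the Gaussian fit with
  # discrete spikes; a local RNG keeps the result deterministic without
  # disturbing the caller's random stream
  lr <- local_rng(20240601, {
    unlist(lapply(tracks, function(t) {
      k <- rpkm(1, t$bin_size, t$total_reads)
      cnt <- unlist(t$counts, use.names = FALSE)
      cnt <- cnt[cnt > 0]
      if (all(cnt == round(cnt))) { # integer read counts: dither the atoms
        cnt <- cnt + runif(length(cnt), -0.5, 0.5)
      }
      log10(cnt * k)
    }), use.names = FALSE)
  })
  if (length(lr) > max_bins) {
    lr <- lr[round(seq(1, length(lr), length.out = max_bins))]
  }
  fit <- tryCatch(
    Mclust(lr, G = 1:2, verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G < 2) {
    warning("log-RPKM distribution is unimodal; falling back to quantile threshold")
    return(determine_threshold(track, "quantile", quantile_p = quantile_p))
  }
  mu <- fit$parameters$mean
  sd2 <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd2) == 1) sd2 <- rep(sd2, 2)
  pro <- fit$parameters$pro
  lo <- which.min(mu); hi <- which.max(mu)
  post_diff <- function(x) {
    pro[hi] * dnorm(x, mu[hi], sd2[hi]) - pro[lo] * dnorm(x, mu[lo], sd2[lo])
  }
  cross <- tryCatch(
    uniroot(post_diff, lower = mu[lo], upper = mu[hi])$root,
    error = function(e) NULL)
  if (is.null(cross)) {
    warning("no posterior crossing between mixture means; falling back to quantile threshold")
    return(determine_threshold(track, "quantile", quantile_p = quantile_p))
  }
  10^cross
}

#' Call transcription units from binned coverage
#'
#' Per strand, bins with RPKM at or above `threshold` are chained into
#' contiguous spans; sub-threshold runs no longer than `max_internal_gap`
#' are bridged (coverage dropouts inside a unit), and spans shorter than
#' `min_length` are dropped. The reported TU RPKM is computed over the full
#' called span, introns included, as appropriate for nascent-RNA signal.
#'
#' @param track A `coverage_track` (single strand).
#' @param threshold RPKM calling threshold (> 0).
#' @param max_internal_gap Maximum bridged sub-threshold run, bp (default
#'   10 kb).
#' @param min_length Minimum TU length, bp (default 10 kb).
#' @return `GRanges` of transcription units on the track's strand with
#'   metadata columns `rpkm` and `n_bins`.
#' @export
call_tus <- function(track, threshold, max_internal_gap = 1e4,
                     min_length = 1e4) {
  stopifnot(is(track, "coverage_track"), threshold > 0)
  bs <- track$bin_size
  gap_bins <- floor(max_internal_gap / bs)
  rpkm_by_chrom <- track_rpkm(track)
  out <- list()
  for (chrom in names(track$counts)) {
    r <- rpkm_by_chrom[[chrom]]
    mask <- r >= threshold
    if (!any(mask)) next
    # bridge short sub-threshold runs strictly inside the masked span
    runs <- rle(mask)
    if (gap_bins > 0 && length(runs$lengths) > 2) {
      inner <- which(!runs$values &
                       runs$lengths <= gap_bins &
                       seq_along(runs$values) > 1 &
                       seq_along(runs$values) < length(runs$values))
      runs$values[inner] <- TRUE
      runs <- rle(inverse.rle(runs))
    }
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- runs$values & (runs$lengths * bs >= min_length)
    if (!any(keep)) next
    for (i in which(keep)) {
      b0 <- starts[i]; b1 <- ends[i]
      cnt <- sum(track$counts[[chrom]][b0:b1])
      span_bp <- (b1 - b0 + 1) * bs
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = (b0 - 1) * bs + 1, end = b1 * bs,
        rpkm = rpkm(cnt, span_bp, track$total_reads),
        n_bins = b1 - b0 + 1)
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    gr$rpkm <- numeric(0); gr$n_bins <- integer(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = track$strand)
  gr$rpkm <- df$rpkm
  gr$n_bins <- df$n_bins
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Strand-aware TSS/TES positions of TUs
#'
#' @param tus `GRanges` of TUs with strand.
#' @return `data.frame` with columns `tss` and `tes` in bp (start of the
#'   first transcribed base; on the minus strand the TSS is the interval
#'   end).
#' @export
tu_endpoints <- function(tus) {
  minus <- as.character(GenomicRanges::strand(tus)) == "-"
  data.frame(
    tss = ifelse(minus, GenomicRanges::end(tus), GenomicRanges::start(tus)),
    tes = ifelse(minus, GenomicRanges::start(tus), GenomicRanges::end(tus)))
}

#' TU length-class summary
#'
#' Counts and genome fractions of TUs above standard length cutoffs.
#'
#' @param tus `GRanges` of TUs.
#' @param genome A [mappable_genome()] supplying the mappable bp denominator.
#' @param cutoffs Length cutoffs in bp (strict >).
#' @return `data.frame` per stratum: `cutoff_bp`, `n_tus`, `fraction_of_tus`,
#'   `total_bp`, `fraction_of_genome`.
#' @export
tu_length_classes <- function(tus, genome, cutoffs = c(1e5, 5e5, 1e6)) {
  w <- GenomicRanges::width(tus)
  n_tot <- length(tus)
  do.call(rbind, lapply(cutoffs, function(cut) {
    sel <- w > cut
    data.frame(cutoff_bp = cut,
               n_tus = sum(sel),
               fraction_of_tus = if (n_tot) sum(sel) / n_tot else 0,
               total_bp = sum(w[sel]),
               fraction_of_genome = sum(w[sel]) / genome$mappable_bp)
  }))
}

#' Read strand-specific coverage from bedGraph files
#'
#' Loads per-bin read counts from one bedGraph per strand. Records must be
#' aligned to a fixed `bin_size` grid; partial trailing bins are accepted.
#' Requires the rtracklayer package.
#'
#' @param plus_path,minus_path bedGraph paths (0-based half-open, value =
#'   read count in the bin).
#' @param chrom_sizes Named chromosome lengths; bins tile each chromosome.
#' @param bin_size Bin width in bp.
#' @param total_reads Optional per-strand library totals (numeric length 2,
#'   plus then minus); defaults to the track sums.
#' @return List with `plus` and `minus` `coverage_track`s.
#' @export
read_coverage_bedgraph <- function(plus_path, minus_path, chrom_sizes,
                                   bin_size, total_reads = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read bedGraph files")
  }
  load_one <- function(path, strand, total) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    counts <- lapply(names(chrom_sizes), function(chrom) {
      n_bins <- ceiling(chrom_sizes[[chrom]] / bin_size)
      v <- numeric(n_bins)
      sel <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
      if (length(sel)) {
        b <- (GenomicRanges::start(sel) - 1) / bin_size
        if (any(b != floor(b))) stop("bedGraph records not aligned to the bin grid in ", path)
        v[b + 1] <- sel$score
      }
      v
    })
    names(counts) <- names(chrom_sizes)
    coverage_track(counts, bin_size, strand, total_reads = total)
  }
  list(plus = load_one(plus_path, "+", if (is.null(total_reads)) NULL else total_reads[1]),
       minus = load_one(minus_path, "-", if (is.null(total_reads)) NULL else total_reads[2]))
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path. Zero bins are omitted.
#' @export
write_coverage_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$counts)) {
    v <- track$counts[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", chrom,
                       (nz - 1) * track$bin_size, nz * track$bin_size, v[nz]),
               con)
  }
  invisible(path)
}
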