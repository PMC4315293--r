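#' @importFrom methods is
#' @importFrom mclust Mclust mclustBIC
#' @importFrom stats median quantile setNames dnorm qnorm uniroot runif
#'   rnorm rlnorm rpois cor
#' @importFrom utils read.delim write.table head tail
NULL

#' Construct a mappable-genome model
#'
#' A `MappableGenome` bundles the chromosome sizes of an assembly with the
#' intervals excluded from analysis (assembly gaps, unmappable sequence).
#' All permutation statistics in this package sample placements from the
#' mappable space, i.e. the complement of `excluded`.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp, or a
#'   two-column data frame (chrom, size).
#' @param excluded A [GenomicRanges::GRanges] of excluded intervals (may be
#'   empty, unsorted or overlapping; it is reduced internally). Coordinates
#'   must fall within the declared chromosome bounds.
#' @return An object of class `MappableGenome` with elements `chrom_sizes`
#'   (named numeric), `excluded` (reduced `GRanges`), `mappable` (`GRanges`
#'   complement of `excluded`) and `mappable_bp` (total mappable bp).
#' @examples
#' g <- mappable_genome(c(chr1 = 1e6), GenomicRanges::GRanges("chr1:1000-2000"))
#' g$mappable_bp
#' @export
mappable_genome <- function(chrom_sizes, excluded = GenomicRanges::GRanges()) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  }
  if (is.null(names(chrom_sizes)) || anyNA(chrom_sizes) || any(chrom_sizes <= 0)) {
    stop("chrom_sizes must be a named vector of positive lengths")
  }
  if (anyDuplicated(names(chrom_sizes))) stop("duplicated chromosome names")
  stopifnot(is(excluded, "GRanges"))
  if (length(excluded)) {
    bad <- !as.character(GenomicRanges::seqnames(excluded)) %in% names(chrom_sizes)
    if (any(bad)) stop("excluded intervals on unknown chromosome: ",
                       paste(unique(as.character(GenomicRanges::seqnames(excluded))[bad]), collapse = ", "))
    ends <- GenomicRanges::end(excluded)
    lim <- chrom_sizes[as.character(GenomicRanges::seqnames(excluded))]
    if (any(GenomicRanges::start(excluded) < 1) || any(ends > lim)) {
      stop("excluded intervals extend beyond chromosome bounds")
    }
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                              seqlengths = as.integer(chrom_sizes))
  excluded <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(excluded), IRanges::ranges(excluded), seqinfo = si)
  excluded <- GenomicRanges::reduce(GenomicRanges::sort(excluded))
  mappable <- GenomicRanges::gaps(excluded)
  mappable <- mappable[GenomicRanges::strand(mappable) == "*"]
  structure(
    list(chrom_sizes = chrom_sizes,
         excluded = excluded,
         mappable = mappable,
         mappable_bp = sum(chrom_sizes) - sum(GenomicRanges::width(excluded)),
         seqinfo = si),
    class = "MappableGenome")
}

#' @export
print.MappableGenome <- function(x, ...) {
  cat(sprintf("MappableGenome: %d chromosome(s), %.0f bp total, %.0f bp mappable (%.1f%%)\n",
              length(x$chrom_sizes), sum(x$chrom_sizes), x$mappable_bp,
              100 * x$mappable_bp / sum(x$chrom_sizes)))
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return Named numeric vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes file must have two columns")
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of `GRanges` on input (and back on output by
#' [write_bed()]). Strand is taken from column 6 when present. Records are
#' validated line by line and re-sorted by (chromosome, start).
#'
#' @param path Path to a tab-separated BED file without header.
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo] carried onto the result.
#' @return A sorted `GRanges`; column 4 (name) and 5 (score) are kept as
#'   metadata columns when present.
#' @export
read_bed <- function(path, seqinfo = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(GenomicRanges::GRanges(seqinfo = seqinfo))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED record (fewer than 3 fields) at line ", which(nf < 3)[1])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) stop("non-numeric coordinates at line ", which(bad)[1])
  if (any(start0 < 0)) stop("negative start at line ", which(start0 < 0)[1])
  empty <- start0 >= end0
  if (any(empty)) {
    stop("empty or inverted interval (start >= end) at line ", which(empty)[1])
  }
  strand <- if (all(nf >= 6)) vapply(fields, `[[`, "", 6L) else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = strand)
  if (all(nf >= 4)) gr$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5)) gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates. Extra
#' columns beyond BED6 can be appended with `extra_cols`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param extra_cols Character vector of metadata column names appended after
#'   the first six BED columns.
#' @export
write_bed <- function(gr, path, extra_cols = character()) {
  n <- length(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    name = if (!is.null(gr$name)) gr$name else rep(".", n),
    score = if (!is.null(gr$score)) gr$score else rep(0, n),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  for (cn in extra_cols) df[[cn]] <- S4Vectors::mcols(gr)[[cn]]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise intersection length of two intervals
#'
#' Returns the number of shared bp between parallel intervals: 0 when the
#' chromosomes differ or the intervals only abut.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Numeric vector of intersection lengths in bp.
#' @export
intersect_len <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) == as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1
  ifelse(same, pmax(0, ov), 0)
}

#' Restrict intervals to the mappable genome
#'
#' Subtracts the genome's excluded intervals from `gr`, returning the sorted
#' disjoint mappable sub-intervals.
#'
#' @param gr A `GRanges` of query intervals.
#' @param genome A [mappable_genome()] object.
#' @return `GRanges` of mappable pieces of `gr`.
#' @export
subtract_excluded <- function(gr, genome) {
  stopifnot(is(genome, "MappableGenome"))
  unknown <- !as.character(GenomicRanges::seqnames(gr)) %in% names(genome$chrom_sizes)
  if (any(unknown)) {
    stop("unknown chromosome: ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[unknown]), collapse = ", "))
  }
  gr2 <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr), IRanges::ranges(gr),
                                seqinfo = genome$seqinfo)
  res <- GenomicRanges::intersect(gr2, genome$mappable, ignore.strand = TRUE)
  GenomicRanges::sort(res)
}
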