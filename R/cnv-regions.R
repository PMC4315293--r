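#' Read a CNV call table
#'
#' Expects a tab-separated file with a header and columns `chrom`, `start`,
#' `end`, `type`, `sample`, `condition` (additional columns are kept as
#' metadata). Coordinates are BED-style 0-based half-open. `type` must be
#' `deletion` or `duplication`.
#'
#' @param path Path to the TSV.
#' @return A `GRanges` with metadata columns `cnv_type`, `sample_id`,
#'   `condition`.
#' @export
read_cnv_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type", "sample", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CNV table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("empty or inverted CNV interval at data row ", bad[1])
  cnv_calls(chrom = df$chrom, start = df$start + 1, end = df$end,
            cnv_type = df$type, sample_id = df$sample, condition = df$condition)
}

#' Construct a set of CNV calls
#'
#' @param chrom,start,end Interval coordinates (1-based closed, `GRanges`
#'   convention; [read_cnv_calls()] converts from BED at the file boundary).
#' @param cnv_type `"deletion"` or `"duplication"` per call.
#' @param sample_id,condition Clone and treatment labels (recycled).
#' @return `GRanges` with the three metadata columns.
#' @export
cnv_calls <- function(chrom, start, end, cnv_type,
                      sample_id = "s1", condition = "NT") {
  ok <- cnv_type %in% c("deletion", "duplication")
  if (!all(ok)) stop("cnv_type must be 'deletion' or 'duplication'; offending value: ",
                     cnv_type[!ok][1])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$cnv_type <- cnv_type
  gr$sample_id <- rep_len(sample_id, length(gr))
  gr$condition <- rep_len(condition, length(gr))
  gr
}

#' Drop exceptionally large CNVs
#'
#' CNVs longer than `max_size` (default 2.5 Mb) are set aside before region
#' merging so that chromosome-arm-scale events cannot nominate uninformative
#' hotspots. The filter is strict: a CNV of exactly `max_size` is kept.
#'
#' @param cnvs `GRanges` of CNV calls.
#' @param max_size Size cutoff in bp.
#' @return List with elements `kept` and `omitted` partitioning the input.
#' @export
filter_large_cnvs <- function(cnvs, max_size = 2.5e6) {
  stopifnot(max_size > 0)
  big <- GenomicRanges::width(cnvs) > max_size
  list(kept = cnvs[!big], omitted = cnvs[big])
}

#' Merge CNV calls into CNV regions
#'
#' Overlapping or adjacent CNVs separated by no more than `max_gap` bp are
#' collapsed into regions by transitive chaining (the union of the calls plus
#' intervening gaps). Merging ignores CNV type and treatment; member calls
#' stay attached for downstream stratification.
#'
#' @param cnvs `GRanges` of (already size-filtered) CNV calls.
#' @param max_gap Maximum merged gap in bp (default 750 kb); a gap of exactly
#'   `max_gap` merges.
#' @return `GRanges` of regions with metadata columns `n_cnvs` (member count)
#'   and `members` (an [IRanges::IntegerList] of indices into `cnvs`).
#' @export
merge_to_regions <- function(cnvs, max_gap = 750e3) {
  stopifnot(max_gap >= 0)
  if (!length(cnvs)) stop("no CNV calls to merge")
  red <- GenomicRanges::reduce(cnvs, min.gapwidth = max_gap + 1,
                               with.revmap = TRUE, ignore.strand = TRUE)
  regions <- GenomicRanges::granges(red)
  regions$members <- red$revmap
  regions$n_cnvs <- lengths(red$revmap)
  GenomicRanges::sort(regions)
}

#' Classify CNV regions as singletons, clusters or hotspots
#'
#' @param regions Output of [merge_to_regions()].
#' @param hotspot_min Minimum member count for a hotspot (default 5).
#' @param cluster_min Minimum member count for a (non-hotspot) cluster
#'   (default 2); regions below it are singletons.
#' @return `regions` with an added `region_class` factor
#'   (`singleton`/`cluster`/`hotspot`).
#' @export
classify_regions <- function(regions, hotspot_min = 5, cluster_min = 2) {
  stopifnot(hotspot_min > cluster_min, cluster_min >= 2)
  n <- regions$n_cnvs
  cls <- ifelse(n >= hotspot_min, "hotspot",
                ifelse(n >= cluster_min, "cluster", "singleton"))
  regions$region_class <- factor(cls, levels = c("singleton", "cluster", "hotspot"))
  regions
}

# Lower-midpoint median: deterministic for even counts.
median_low <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Per-region summary table
#'
#' @param regions Classified regions ([classify_regions()]).
#' @param cnvs The CNV calls the regions were merged from (member indices
#'   must refer into this object).
#' @param median_type `"low"` (lower midpoint, deterministic; default) or
#'   `"interpolated"` (standard [stats::median()]).
#' @return `data.frame` with one row per region: coordinates, span length,
#'   member count, class, median member CNV size, and deletion/duplication
#'   member counts.
#' @export
region_summary <- function(regions, cnvs, median_type = c("low", "interpolated")) {
  median_type <- match.arg(median_type)
  med <- if (median_type == "low") median_low else median
  idx <- regions$members
  w <- GenomicRanges::width(cnvs)
  ty <- cnvs$cnv_type
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    span_length = GenomicRanges::width(regions),
    n_cnvs = regions$n_cnvs,
    region_class = as.character(regions$region_class),
    median_cnv_size = vapply(idx, function(i) as.numeric(med(w[i])), 0),
    n_deletions = vapply(idx, function(i) sum(ty[i] == "deletion"), 0L),
    n_duplications = vapply(idx, function(i) sum(ty[i] == "duplication"), 0L),
    stringsAsFactors = FALSE)
}

#' Reproduce the CNV-set summary from a published-style call table
#'
#' Convenience wrapper running the full region pipeline on an external CNV
#' call table (as distributed with published CNV studies): size filtering,
#' 750-kb merging, classification, and the clustering-significance Monte
#' Carlo.
#'
#' @param path CNV call TSV (see [read_cnv_calls()]).
#' @param genome A [mappable_genome()] for the assembly the calls are on.
#' @param max_size,max_gap,hotspot_min Pipeline parameters.
#' @param n_iter,seed Monte Carlo settings for [clustering_significance()].
#' @return List with `median_cnv_size`, `n_kept`, `n_omitted`, `n_regions`,
#'   `n_hotspots`, and `clustering_p`.
#' @export
reproduce_cnv_summary <- function(path, genome, max_size = 2.5e6,
                                  max_gap = 750e3, hotspot_min = 5,
                                  n_iter = 1000, seed = 1) {
  cnvs <- read_cnv_calls(path)
  flt <- filter_large_cnvs(cnvs, max_size)
  regions <- classify_regions(merge_to_regions(flt$kept, max_gap),
                              hotspot_min = hotspot_min)
  cs <- clustering_significance(flt$kept, genome, max_gap = max_gap,
                                k = hotspot_min, n_iter = n_iter, seed = seed)
  list(median_cnv_size = median(GenomicRanges::width(cnvs)),
       n_kept = length(flt$kept), n_omitted = length(flt$omitted),
       n_regions = length(regions),
       n_hotspots = sum(regions$region_class == "hotspot"),
       clustering_p = cs$p_ge_k)
}
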