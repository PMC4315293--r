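## Synthetic-data generator. Emulates the statistical structure the analysis
## assumes: a small multi-chromosome genome with excluded gaps; a TU
## population with a heavy upper length tail plus a handful of planted
## megabase-scale units; strand-specific Poisson nascent-RNA coverage;
## a replication-timing field that is early over transcribed bp, late over
## untranscribed bp, and delayed mid-TU in proportion to TU length; and CNVs
## drawn from a double-fork-failure risk model in which a TU of length L
## carries weight proportional to (L / N_s)^2 (N_s = median fork travel
## before stalling), with deletions concentrated mid-TU and duplications on
## the flanks. All randomness flows from one seed through fixed per-stage
## substreams.

#' Parameter set for the synthetic-data generator
#'
#' Defaults define the package's reference study conditions: 3 chromosomes
#' of 60 Mb with ~5% excluded, 200 TUs including five planted units of
#' 1-2 Mb, 300 CNVs (200 deletions, 100 duplications) with fork-stall scale
#' `N_s = 300` kb, and a CNV length distribution with median 186 kb.
#'
#' @param n_chroms,chrom_length Genome shape.
#' @param excluded_per_chrom,excluded_fraction Assembly-gap emulation.
#' @param n_tus Total TU count (including the planted large TUs).
#' @param large_tu_lengths Lengths of the planted megabase-scale TUs (bp).
#' @param tu_meanlog,tu_sdlog Log-normal length parameters of the ordinary
#'   TU population (heavy upper tail); lengths are clipped to
#'   `[5e3, tu_max_small]`.
#' @param tu_max_small Cap on ordinary TU length (bp).
#' @param rpkm_meanlog,rpkm_sdlog Log-normal TU intensity parameters.
#' @param rpkm_length_rho Rank-correlation knob between TU length and RPKM
#'   (negative: long TUs are weakly transcribed, as observed for large-TU
#'   fragile loci).
#' @param bin_size Coverage bin width (bp).
#' @param depth_total Library size used as the RPKM denominator (reads;
#'   split evenly between strands).
#' @param background_rate Mean background reads per bin outside TUs.
#' @param timing_early,timing_late Repli-seq-style timing scores (higher =
#'   earlier) for transcribed and untranscribed baselines.
#' @param timing_delay_per_mb Mid-TU timing delay amplitude per Mb of TU
#'   length (score units; the delay profile is triangular, peaking at 50%).
#' @param timing_sd Gaussian noise SD per timing segment.
#' @param timing_segment Timing segment width (bp).
#' @param baseline_cnv_rate Background CNV weight per mappable bp.
#' @param transcription_multiplier Multiplier on the TU-associated risk
#'   weights; 0 disables transcription-dependent risk entirely.
#' @param fork_stall_scale `N_s`, the median fork travel distance before
#'   stalling (bp); TU risk weight is
#'   `transcription_multiplier * (L / N_s)^2`.
#' @param n_deletions,n_duplications CNV counts.
#' @param cnv_meanlog,cnv_sdlog Log-normal CNV length parameters (default
#'   median 186 kb); lengths clipped to `[1e3, 2.4e6]`.
#' @param del_center_mean,del_center_sd Deletion center placement in TU
#'   percent coordinates, truncated normal on `[0, 100]`.
#' @param dup_center_offsets,dup_center_sd Duplication center placement:
#'   a balanced mixture of two flank lobes (percent coordinates).
#' @param seed Master RNG seed.
#' @return Object of class `synthetic_model` (a named list).
#' @export
synthetic_model <- function(n_chroms = 3, chrom_length = 60e6,
                            excluded_per_chrom = 4, excluded_fraction = 0.05,
                            n_tus = 200,
                            large_tu_lengths = c(1.0e6, 1.2e6, 1.5e6, 1.8e6, 2.0e6),
                            tu_meanlog = log(3e4), tu_sdlog = 1.1,
                            tu_max_small = 8e5,
                            rpkm_meanlog = log(1), rpkm_sdlog = 1,
                            rpkm_length_rho = -0.3,
                            bin_size = 1e3, depth_total = 2e7,
                            background_rate = 0.05,
                            timing_early = 75, timing_late = 35,
                            timing_delay_per_mb = 20, timing_sd = 1.5,
                            timing_segment = 1e3,
                            baseline_cnv_rate = 5e-7,
                            transcription_multiplier = 1,
                            fork_stall_scale = 3e5,
                            n_deletions = 200, n_duplications = 100,
                            cnv_meanlog = log(1.86e5), cnv_sdlog = 0.6,
                            del_center_mean = 50, del_center_sd = 15,
                            dup_center_offsets = c(-25, 125),
                            dup_center_sd = 15,
                            seed = 1) {
  m <- as.list(environment())
  stopifnot(m$fork_stall_scale > 0, m$baseline_cnv_rate >= 0,
            m$transcription_multiplier >= 0, m$n_deletions >= 0,
            m$n_duplications >= 0, m$n_tus >= length(m$large_tu_lengths))
  structure(m, class = "synthetic_model")
}

# Per-stage substream seeds derived from the master seed (kept within
# 32-bit integer range).
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, tus = 202L, coverage = 303L,
               timing = 404L, cnvs = 505L)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% .Machine$integer.max)
}

# Genome with randomly placed excluded gaps.
synth_genome <- function(m) {
  set.seed(stage_seed(m$seed, "genome"))
  sizes <- setNames(rep(m$chrom_length, m$n_chroms),
                    paste0("chr", seq_len(m$n_chroms)))
  gaps <- list()
  for (chrom in names(sizes)) {
    gw <- round(m$excluded_fraction * sizes[[chrom]] / m$excluded_per_chrom)
    if (gw < 1 || m$excluded_per_chrom < 1) next
    starts <- sort(sample.int(sizes[[chrom]] - gw, m$excluded_per_chrom))
    gaps[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                end = starts + gw - 1)
  }
  excluded <- if (length(gaps)) {
    df <- do.call(rbind, gaps)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  } else GenomicRanges::GRanges()
  mappable_genome(sizes, excluded)
}

# Non-overlapping TU placement (bin-aligned) with strand, length and RPKM.
synth_tus <- function(m, genome) {
  set.seed(stage_seed(m$seed, "tus"))
  n_small <- m$n_tus - length(m$large_tu_lengths)
  small_len <- pmin(pmax(round(rlnorm(n_small, m$tu_meanlog, m$tu_sdlog)), 5e3),
                    m$tu_max_small)
  len <- c(m$large_tu_lengths, small_len)
  len <- pmax(round(len / m$bin_size), 1) * m$bin_size
  if (sum(len) > 0.5 * genome$mappable_bp) {
    stop("infeasible model: TUs exceed half the mappable genome")
  }
  # RPKM with a rank-based length anticorrelation
  z_len <- rank(len, ties.method = "random")
  z_len <- qnorm((z_len - 0.5) / length(len))
  rho <- m$rpkm_length_rho
  z_rpkm <- rho * z_len + sqrt(1 - rho^2) * rnorm(length(len))
  tu_rpkm <- exp(m$rpkm_meanlog + m$rpkm_sdlog * z_rpkm)
  # sequential placement, non-overlapping across strands, 10-kb buffer
  slots <- slot_table(genome)
  chrom_bp <- vapply(slots, function(s) sum(s$width), 0)
  occupied <- lapply(slots, function(s) list(start = numeric(0), end = numeric(0)))
  ord <- order(len, decreasing = TRUE) # large first, avoids packing failures
  chroms <- character(length(len)); starts <- numeric(length(len))
  buffer <- 1e4
  for (j in ord) {
    L <- len[j]
    done <- FALSE
    for (attempt in seq_len(1e4)) {
      ch <- sample(names(slots), 1, prob = chrom_bp)
      s <- slots[[ch]]
      v <- pmax(0, s$width - L + 1)
      if (sum(v) == 0) next
      u <- floor(runif(1) * sum(v)) + 1
      i <- findInterval(u - 0.5, c(0, cumsum(v)))
      st <- s$start[i] + (u - c(0, cumsum(v))[i]) - 1
      st <- (floor((st - 1) / m$bin_size)) * m$bin_size + 1 # bin-align
      occ <- occupied[[ch]]
      if (!any(st <= occ$end + buffer & st + L - 1 >= occ$start - buffer)) {
        occupied[[ch]]$start <- c(occ$start, st)
        occupied[[ch]]$end <- c(occ$end, st + L - 1)
        chroms[j] <- ch; starts[j] <- st
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not place TU of ", L, " bp")
  }
  tus <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, width = len),
                                strand = sample(c("+", "-"), length(len),
                                                replace = TRUE))
  tus$rpkm <- tu_rpkm
  tus$is_large <- seq_along(len) <= length(m$large_tu_lengths)
  tus <- GenomicRanges::sort(tus, ignore.strand = TRUE)
  tus$tu_id <- seq_along(tus)
  tus
}

# Poisson coverage on both strands: background everywhere, TU signal on the
# TU's strand at depth proportional to RPKM.
synth_coverage <- function(m, genome, tus) {
  set.seed(stage_seed(m$seed, "coverage"))
  strand_total <- m$depth_total / 2
  lambda_per_rpkm <- (m$bin_size / 1e3) * (strand_total / 1e6)
  make_strand <- function(str) {
    counts <- lapply(genome$chrom_sizes, function(len) {
      rpois(ceiling(len / m$bin_size), m$background_rate)
    })
    sel <- tus[as.character(GenomicRanges::strand(tus)) == str]
    for (i in seq_along(sel)) {
      chrom <- as.character(GenomicRanges::seqnames(sel))[i]
      b0 <- (GenomicRanges::start(sel)[i] - 1) / m$bin_size + 1
      b1 <- GenomicRanges::end(sel)[i] / m$bin_size
      lam <- sel$rpkm[i] * lambda_per_rpkm
      counts[[chrom]][b0:b1] <- counts[[chrom]][b0:b1] +
        rpois(b1 - b0 + 1, lam)
    }
    coverage_track(counts, m$bin_size, str, total_reads = strand_total)
  }
  list(plus = make_strand("+"), minus = make_strand("-"))
}

# Timing field on fixed segments: late baseline, early over TUs, with a
# triangular mid-TU delay scaling with TU length.
synth_timing <- function(m, genome, tus) {
  set.seed(stage_seed(m$seed, "timing"))
  seg_list <- lapply(names(genome$chrom_sizes), function(chrom) {
    len <- genome$chrom_sizes[[chrom]]
    n <- ceiling(len / m$timing_segment)
    start <- (seq_len(n) - 1) * m$timing_segment + 1
    end <- pmin(seq_len(n) * m$timing_segment, len)
    val <- rep(m$timing_late, n)
    mid <- (start + end) / 2
    sel <- tus[as.character(GenomicRanges::seqnames(tus)) == chrom]
    for (i in seq_along(sel)) {
      s <- GenomicRanges::start(sel)[i]; e <- GenomicRanges::end(sel)[i]
      inside <- which(mid >= s & mid <= e)
      if (!length(inside)) next
      p <- 100 * (mid[inside] - s) / (e - s + 1)
      delay <- m$timing_delay_per_mb * (e - s + 1) / 1e6 *
        (1 - abs(p - 50) / 50)
      val[inside] <- m$timing_early - delay
    }
    data.frame(chrom = chrom, start = start, end = end, score = val)
  })
  df <- do.call(rbind, seg_list)
  df$score <- df$score + rnorm(nrow(df), 0, m$timing_sd)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$score <- df$score
  timing_track(gr, source = "repli_seq_score")
}

# CNVs from the (L / N_s)^2 risk model.
synth_cnvs <- function(m, genome, tus) {
  set.seed(stage_seed(m$seed, "cnvs"))
  n_cnv <- m$n_deletions + m$n_duplications
  if (n_cnv == 0) {
    cnvs <- GenomicRanges::GRanges()
    cnvs$cnv_type <- character(0); cnvs$sample_id <- character(0)
    cnvs$condition <- character(0); cnvs$source <- integer(0)
    return(cnvs)
  }
  L <- GenomicRanges::width(tus)
  w_tu <- m$transcription_multiplier * (L / m$fork_stall_scale)^2
  w_bg <- m$baseline_cnv_rate * genome$mappable_bp
  weights <- c(w_bg, w_tu)
  if (sum(weights) <= 0) stop("all CNV risk weights are zero")
  src <- sample.int(length(weights), n_cnv, replace = TRUE, prob = weights) - 1L
  type <- c(rep("deletion", m$n_deletions), rep("duplication", m$n_duplications))
  cnv_len <- pmin(pmax(round(rlnorm(n_cnv, m$cnv_meanlog, m$cnv_sdlog)), 1e3),
                  2.4e6)
  chroms <- character(n_cnv); starts <- numeric(n_cnv)
  slots <- slot_table(genome)
  chrom_bp <- vapply(slots, function(s) sum(s$width), 0)
  for (i in seq_len(n_cnv)) {
    if (src[i] == 0) { # background: the permutation placement law
      for (attempt in seq_len(1e4)) {
        ch <- sample(names(slots), 1, prob = chrom_bp)
        s <- slots[[ch]]
        v <- pmax(0, s$width - cnv_len[i] + 1)
        if (sum(v) == 0) next
        u <- floor(runif(1) * sum(v)) + 1
        k <- findInterval(u - 0.5, c(0, cumsum(v)))
        chroms[i] <- ch
        starts[i] <- s$start[k] + (u - c(0, cumsum(v))[k]) - 1
        break
      }
    } else {
      tu <- tus[src[i]]
      if (type[i] == "deletion") {
        repeat {
          p <- rnorm(1, m$del_center_mean, m$del_center_sd)
          if (p >= 0 && p <= 100) break
        }
      } else {
        p <- rnorm(1, sample(m$dup_center_offsets, 1), m$dup_center_sd)
      }
      center <- from_relative(p, tu)
      ch <- as.character(GenomicRanges::seqnames(tu))
      st <- round(center - cnv_len[i] / 2)
      st <- min(max(st, 1), genome$chrom_sizes[[ch]] - cnv_len[i] + 1)
      chroms[i] <- ch; starts[i] <- st
    }
  }
  cnvs <- cnv_calls(chroms, starts, starts + cnv_len - 1, type,
                    sample_id = paste0("clone", sample.int(50, n_cnv, TRUE)),
                    condition = sample(c("NT", "APH", "HU", "IR"), n_cnv,
                                       replace = TRUE,
                                       prob = c(0.1, 0.6, 0.2, 0.1)))
  cnvs$source <- src # 0 = background, otherwise TU index
  GenomicRanges::sort(cnvs, ignore.strand = TRUE)
}

#' Generate a complete synthetic dataset
#'
#' Produces every input the pipeline consumes, plus a ground-truth manifest
#' sufficient to compute all downstream expectations: genome and excluded
#' gaps, TU truth table with RPKM, strand-specific Poisson coverage, a
#' replication-timing field, and CNV calls drawn from the
#' transcription-dependent risk model.
#'
#' @param model A [synthetic_model()].
#' @return List of class `synthetic_dataset` with elements `genome`
#'   ([mappable_genome()]), `tus` (`GRanges` truth), `coverage` (list of
#'   `plus`/`minus` [coverage_track()]s), `timing` ([timing_track()]),
#'   `cnvs` (`GRanges` with `cnv_type`, `source`), `truth` (parameter and
#'   provenance manifest) and `model`.
#' @export
generate_dataset <- function(model) {
  stopifnot(is(model, "synthetic_model"))
  genome <- synth_genome(model)
  tus <- synth_tus(model, genome)
  coverage <- synth_coverage(model, genome, tus)
  timing <- synth_timing(model, genome, tus)
  cnvs <- synth_cnvs(model, genome, tus)
  truth <- list(
    seed = model$seed,
    large_tu_ids = tus$tu_id[tus$is_large],
    n_background_cnvs = sum(cnvs$source == 0),
    cnv_source = as.integer(cnvs$source),
    params = unclass(model))
  structure(list(genome = genome, tus = tus, coverage = coverage,
                 timing = timing, cnvs = cnvs, truth = truth, model = model),
            class = "synthetic_dataset")
}

#' Generate a matched null dataset
#'
#' Identical to [generate_dataset()] except that the transcription-dependent
#' CNV risk is disabled: every CNV is placed by the permutation engine's own
#' background law. Used for p-value calibration.
#'
#' @param model A [synthetic_model()].
#' @return A `synthetic_dataset`.
#' @export
null_dataset <- function(model) {
  m <- model
  m$transcription_multiplier <- 0
  if (m$baseline_cnv_rate <= 0) m$baseline_cnv_rate <- 1e-9
  generate_dataset(m)
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits the exact plain-text formats the readers consume: `chrom.sizes`,
#' `excluded.bed`, `tus.bed` (BED6 + RPKM column 7), `coverage_plus.bedgraph`
#' / `coverage_minus.bedgraph`, `timing.bedgraph`, `cnvs.tsv` and
#' `truth.json`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$genome
  write.table(data.frame(names(g$chrom_sizes), as.integer(g$chrom_sizes)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(g$excluded, file.path(dir, "excluded.bed"))
  tus <- dataset$tus
  tus$name <- paste0("TU", tus$tu_id)
  tus$score <- pmin(1000, round(tus$rpkm * 100))
  write_bed(tus, file.path(dir, "tus.bed"), extra_cols = "rpkm")
  write_coverage_bedgraph(dataset$coverage$plus,
                          file.path(dir, "coverage_plus.bedgraph"))
  write_coverage_bedgraph(dataset$coverage$minus,
                          file.path(dir, "coverage_minus.bedgraph"))
  seg <- dataset$timing$segments
  writeLines(sprintf("%s\t%d\t%d\t%.4f",
                     as.character(GenomicRanges::seqnames(seg)),
                     GenomicRanges::start(seg) - 1, GenomicRanges::end(seg),
                     seg$score),
             file.path(dir, "timing.bedgraph"))
  cnvs <- dataset$cnvs
  write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(cnvs)),
               start = GenomicRanges::start(cnvs) - 1,
               end = GenomicRanges::end(cnvs),
               type = cnvs$cnv_type, sample = cnvs$sample_id,
               condition = cnvs$condition),
    file.path(dir, "cnvs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
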