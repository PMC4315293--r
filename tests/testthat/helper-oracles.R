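# Brute-force oracles, kept independent of the package's code paths.

library(GenomicRanges)

# Per-bp bitmap of closed intervals on a toy chromosome of length len.
bitmap <- function(starts, ends, len) {
  v <- logical(len)
  for (i in seq_along(starts)) {
    v[max(1, starts[i]):min(len, ends[i])] <- TRUE
  }
  v
}

# Transitive-closure merge of closed intervals: two intervals connect when
# on the same chromosome with gap (start2 - end1 - 1) <= max_gap. Returns a
# data.frame of component spans and member counts.
oracle_merge <- function(chrom, start, end, max_gap) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (chrom[i] != chrom[j]) next
        gap <- max(start[i], start[j]) - min(end[i], end[j]) - 1
        if (gap <= max_gap && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    sel <- comp == cc
    data.frame(chrom = chrom[sel][1], start = min(start[sel]),
               end = max(end[sel]), n = sum(sel))
  }))
  out[order(out$chrom, out$start), ]
}

# Nearest-probe step function evaluated at a single bp position.
oracle_nearest_probe <- function(pos, probe_pos, probe_val) {
  d <- abs(probe_pos - pos)
  # midpoint rule: ties (equidistant) go to the left probe, matching a
  # boundary at floor((p1+p2)/2) inclusive
  i <- which(d == min(d))
  probe_val[i[1]]
}

# Full-enumeration two-sided Fisher p: sum of hypergeometric probabilities
# of all tables with the observed margins whose probability does not exceed
# the observed table's.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
  }, 0)
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rho by explicit average-rank computation and the Pearson
# product-moment formula written out in sums.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Exact two-sided Mann-Whitney p for small samples without ties, by
# enumeration of all group assignments.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_stat <- function(idx) {
    g1 <- pooled[idx]; g2 <- pooled[-idx]
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  obs <- u_stat(seq_len(n))
  all_idx <- utils::combn(length(pooled), n)
  us <- apply(all_idx, 2, u_stat)
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Toy single-chromosome genome without exclusions.
toy_genome <- function(len = 1e6, name = "chrT", excluded = GRanges()) {
  mappable_genome(setNames(len, name), excluded)
}
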