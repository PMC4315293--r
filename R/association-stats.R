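#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the two-sided "probability at most that of
#' the observed table" rule (the convention of [stats::fisher.test()], which
#' performs the computation).
#'
#' @param x A 2x2 integer matrix, or the count `a` with `b`, `c`, `d`.
#' @param b,c,d Remaining counts when `x` is scalar (row-major:
#'   `rbind(c(a, b), c(c, d))`).
#' @return List with `p` (two-sided p-value), `odds_ratio` (conditional MLE)
#'   and `table`.
#' @examples
#' fisher_exact(15, 1, 20, 65)$p # ~1.4e-7
#' @export
fisher_exact <- function(x, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(x)) x else rbind(c(x, b), c(c, d))
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Rho is computed on mid-ranked data (average ranks for ties); the p-value
#' is empirical, from random permutations of `y` with the add-one rule, two
#' sided on `|rho|`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer RNG seed.
#' @return List with `r`, `n`, `p`. A constant input vector gives `r = NA`
#'   and `p = NA` (correlation undefined).
#' @export
spearman_cor <- function(x, y, n_perm = 1e4, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(r = NA_real_, n = n, p = NA_real_))
  }
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), 0)
  list(r = r, n = n,
       p = (1 + sum(abs(perm) >= abs(r) - 1e-12)) / (n_perm + 1))
}

#' Pairwise two-sided Mann-Whitney tests between groups
#'
#' Wraps [stats::wilcox.test()] (exact where feasible, normal approximation
#' with tie and continuity correction otherwise) for all group pairs, e.g.
#' the singleton/cluster/hotspot strata of a region summary.
#'
#' @param groups Named list of numeric vectors (each n >= 1).
#' @return `data.frame` with `group1`, `group2`, `p`.
#' @export
group_difference <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  stopifnot(all(lengths(groups) >= 1))
  pairs <- utils::combn(names(groups), 2)
  p <- apply(pairs, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (length(unique(c(a, b))) == 1) return(1) # all values identical
    suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                        correct = TRUE)$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = p,
             stringsAsFactors = FALSE)
}
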