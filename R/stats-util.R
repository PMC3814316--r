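#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more successes when drawing `n` items
#' without replacement from a population of `N` items of which `K` are
#' successes. This is the enrichment test used throughout the package for
#' annotation and gene-set overlaps. The tail is evaluated by
#' [stats::phyper()], which sums the exact probability mass in a numerically
#' stable way, so p-values stay finite and accurate on genome-scale
#' backgrounds (N in the tens of thousands).
#'
#' @param k observed number of successes in the draw (integer, >= 0).
#' @param K number of successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return `P(X >= k)` as a single numeric value in (0, 1].
#' @examples
#' hypergeometric_pvalue(2, 3, 3, 10)
#' @export
hypergeometric_pvalue <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric parameters: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  if (k == 0) return(1.0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' @param a,b,c,d cell counts: row 1 = group A (in, out), row 2 = group B
#'   (in, out).
#' @param yates apply the Yates continuity correction (default off; the
#'   package's comparisons report the plain chi-squared statistic).
#' @return list with `statistic` and `p` (1 degree of freedom).
#' @examples
#' chi2_2x2(64, 136, 22, 178)
#' @export
chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(tab < 0)) stop("negative cell count")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: zero marginal in 2x2 table")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Fold ratio of two proportions
#'
#' `(k1/n1) / (k2/n2)`. Used for all "x-fold enrichment of group A over
#' group B" style statements. Returns `Inf` when `k2` is zero but `k1` is
#' not; returns `NaN` when both are zero.
#'
#' @param k1,n1 numerator count and group size.
#' @param k2,n2 denominator count and group size.
#' @return a single numeric fold value.
#' @examples
#' fold_of_proportions(16, 163, 2, 90) # ~4.4
#' @export
fold_of_proportions <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 < 0 || k2 < 0) stop("counts must be non-negative")
  (k1 / n1) / (k2 / n2)
}

#' Draw seeded random gene sets
#'
#' Uniform sampling without replacement within each set; sets are
#' independent across draws unless `disjoint_from_previous` is set, in
#' which case an element is used at most once across all returned sets.
#' All randomness is confined to the call: the caller's RNG state is
#' restored on exit, and the same `seed` reproduces the same sets.
#'
#' @param universe character vector of candidate elements.
#' @param size number of elements per set.
#' @param n_sets number of sets to draw.
#' @param seed integer seed (mandatory; every stochastic routine in this
#'   package takes an explicit seed).
#' @param disjoint_from_previous if TRUE, sets are mutually disjoint.
#' @return list of character vectors, each of length `size`.
#' @export
draw_random_gene_sets <- function(universe, size, n_sets, seed,
                                  disjoint_from_previous = FALSE) {
  if (size > length(universe)) stop("set size exceeds universe size")
  if (disjoint_from_previous && n_sets * size > length(universe)) {
    stop("cannot draw ", n_sets, " disjoint sets of ", size,
         " from a universe of ", length(universe))
  }
  with_seed(seed, {
    if (disjoint_from_previous) {
      pool <- sample(universe, n_sets * size)
      split(pool, rep(seq_len(n_sets), each = size))
    } else {
      lapply(seq_len(n_sets), function(i) sample(universe, size))
    }
  })
}

#' Empirical p-value with the add-one estimator
#'
#' `(1 + #\{null >= observed\}) / (n + 1)`: never exactly zero, with floor
#' `1/(n+1)` at `n` null samples.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @return empirical upper-tail p-value.
#' @export
empirical_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (length(null) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All stochastic functions in the package go
# through this so that a pipeline seed fully determines the run.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# kept within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
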