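# Chance-corrected clustering agreement: adjusted Rand index and adjusted
# mutual information, computed from the label co-occurrence contingency
# table.

check_label_pair <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(labels_a) < 2L) {
    stop("need at least two observations", call. = FALSE)
  }
  if (anyNA(labels_a) || anyNA(labels_b)) {
    stop("labels must not contain missing values", call. = FALSE)
  }
}

label_contingency <- function(labels_a, labels_b) {
  unclass(table(factor(labels_a), factor(labels_b)))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected so that the
#' expected value under random labelings with the same marginals is 0:
#' \eqn{(RI - E[RI]) / (\max RI - E[RI])} over the contingency table.
#' Symmetric and invariant to permuting cluster labels; 1 for identical
#' partitions. When both labelings are a single cluster the partitions agree
#' completely and 1 is returned.
#'
#' @param labels_a,labels_b Label vectors of equal length (n >= 2); any
#'   atomic type usable as a factor.
#' @return A scalar in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  check_label_pair(labels_a, labels_b)
  tab <- label_contingency(labels_a, labels_b)
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * n^2) {
    # both labelings constant (or equivalent degeneracy): complete agreement
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

entropy_counts <- function(cnt, n) {
  cnt <- cnt[cnt > 0]
  -sum((cnt / n) * log(cnt / n))
}

# Expected mutual information under the permutation (hypergeometric) null
# with fixed marginals a, b. Term-by-term sum over feasible cell counts.
expected_mutual_info <- function(a, b, n) {
  emi <- 0
  lg <- lgamma  # log-factorial via lgamma(k + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        logp <- lg(ai + 1) + lg(bj + 1) + lg(n - ai + 1) + lg(n - bj + 1) -
          lg(n + 1) - lg(nij + 1) - lg(ai - nij + 1) - lg(bj - nij + 1) -
          lg(n - ai - bj + nij + 1)
        emi <- emi + (nij / n) * log(n * nij / (ai * bj)) * exp(logp)
      }
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two labelings, chance-corrected under the
#' hypergeometric (fixed-marginals) null:
#' \eqn{(MI - E[MI]) / (\mathrm{norm}(H_a, H_b) - E[MI])}. The default
#' normalizer is the arithmetic mean of the entropies; `"min"`, `"max"` and
#' `"geometric"` are available. Equals 1 iff the labelings are identical up
#' to relabeling; two constant labelings return 1 by convention.
#'
#' @inheritParams adjusted_rand_index
#' @param average_method Entropy normalizer: `"arithmetic"` (default),
#'   `"min"`, `"max"` or `"geometric"`.
#' @return A scalar <= 1.
#' @examples
#' adjusted_mutual_info(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' @export
adjusted_mutual_info <- function(labels_a, labels_b,
                                 average_method = c("arithmetic", "min",
                                                    "max", "geometric")) {
  average_method <- match.arg(average_method)
  check_label_pair(labels_a, labels_b)
  tab <- label_contingency(labels_a, labels_b)
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  h_a <- entropy_counts(a, n)
  h_b <- entropy_counts(b, n)
  if (h_a == 0 && h_b == 0) return(1)
  nz <- which(tab > 0, arr.ind = TRUE)
  mi <- sum(vapply(seq_len(nrow(nz)), function(k) {
    nij <- tab[nz[k, 1], nz[k, 2]]
    (nij / n) * log(n * nij / (a[nz[k, 1]] * b[nz[k, 2]]))
  }, numeric(1)))
  emi <- expected_mutual_info(a, b, n)
  normalizer <- switch(average_method,
                       arithmetic = (h_a + h_b) / 2,
                       min = min(h_a, h_b),
                       max = max(h_a, h_b),
                       geometric = sqrt(h_a * h_b))
  denom <- normalizer - emi
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  (mi - emi) / denom
}
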