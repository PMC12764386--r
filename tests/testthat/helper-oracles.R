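# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (explicit dense inverses, exhaustive pair
# counting, term-by-term sums with factorial()).

# BLUP via an explicit matrix inverse, including the stability jitter the
# package always places on the Gram diagonal.
oracle_blup <- function(X, Y, params, Xstar) {
  K <- rbf_kernel(X, X, params)
  diag(K) <- diag(K) + params$tau2 + 1e-8 * params$sigma2
  kstar <- rbf_kernel(Xstar, X, params)
  drop(kstar %*% solve(K) %*% (Y - mean(Y))) + mean(Y)
}

# Log density of N(0, K + tau2 I) via determinant and solve().
oracle_lml <- function(X, Y, params) {
  K <- rbf_kernel(X, X, params)
  diag(K) <- diag(K) + params$tau2 + 1e-8 * params$sigma2
  n <- length(Y)
  -0.5 * drop(Y %*% solve(K, Y)) -
    0.5 * as.numeric(determinant(K)$modulus) - 0.5 * n * log(2 * pi)
}

# ARI by exhaustive pair counting over all C(n, 2) pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# AMI with the expected MI evaluated term by term with factorial().
oracle_ami <- function(a, b) {
  tab <- unclass(table(a, b))
  n <- sum(tab)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  H <- function(cnt) {
    p <- cnt[cnt > 0] / n
    -sum(p * log(p))
  }
  mi <- 0
  for (r in seq_along(ai)) for (c in seq_along(bj)) {
    if (tab[r, c] > 0) {
      mi <- mi + (tab[r, c] / n) * log(n * tab[r, c] / (ai[r] * bj[c]))
    }
  }
  emi <- 0
  for (r in seq_along(ai)) for (c in seq_along(bj)) {
    for (nij in max(1, ai[r] + bj[c] - n):min(ai[r], bj[c])) {
      if (nij < max(1, ai[r] + bj[c] - n)) next
      p <- (factorial(ai[r]) * factorial(bj[c]) * factorial(n - ai[r]) *
              factorial(n - bj[c])) /
        (factorial(n) * factorial(nij) * factorial(ai[r] - nij) *
           factorial(bj[c] - nij) * factorial(n - ai[r] - bj[c] + nij))
      emi <- emi + (nij / n) * log(n * nij / (ai[r] * bj[c])) * p
    }
  }
  ha <- H(ai)
  hb <- H(bj)
  if (ha == 0 && hb == 0) return(1)
  unname((mi - emi) / ((ha + hb) / 2 - emi))
}

# Small deterministic dataset for plumbing tests.
toy_dataset <- function(n = 24, seed = 7) {
  set.seed(seed)
  s <- matrix(runif(2 * n), n, 2)
  x <- matrix(runif(2 * n), n, 2)
  lab <- ifelse(s[, 1] < 0.5, 1L, 2L)
  y <- ifelse(lab == 1L, x[, 1] + 2 * x[, 2], -x[, 1] - 2 * x[, 2])
  spatial_dataset(s, x, y, true_labels = lab)
}
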