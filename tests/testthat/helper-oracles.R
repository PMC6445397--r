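# Independent brute-force oracles used to validate the package's exact
# tests and decompositions. These deliberately use different primitives
# (lchoose enumeration, O(m^2) threshold search, eigendecomposition) than
# the implementation paths they check.

# Two-sided Fisher exact p for one 2x2 table by full enumeration of the
# hypergeometric support via binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  obs <- lchoose(m1, a) + lchoose(m2, k - a) - lchoose(m1 + m2, k)
  min(1, sum(exp(logp)[logp <= obs + 1e-9]))
}

# Vectorized variant of the same enumeration (used for the exhaustive
# table sweep in the acceptance suite).
fisher_oracle_vec <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- pmax(0, k - m2); hi <- pmin(k, m1)
  len <- hi - lo + 1L
  idx <- rep.int(seq_along(a), len)
  x <- sequence(len) - 1L + rep.int(lo, len)
  logp <- lchoose(m1[idx], x) + lchoose(m2[idx], k[idx] - x) -
    lchoose(m1[idx] + m2[idx], k[idx])
  obs <- lchoose(m1, a) + lchoose(m2, k - a) - lchoose(m1 + m2, k)
  keep <- logp <= obs[idx] + 1e-9
  pmin(1, rowsum(ifelse(keep, exp(logp), 0), idx, reorder = TRUE)[, 1])
}

# BH q-values straight from the FDR definition: the smallest eligible
# threshold t (taken over observed p-values >= p_i) of m * t / #{p <= t}.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(m * ts / vapply(ts, function(t) sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Upper-tail hypergeometric P(X >= k) by binomial-coefficient enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  xs <- lo:hi
  probs <- exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n))
  sum(probs[xs >= k])
}

# Folded AUC by exhaustive concordant-pair counting.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  auc <- mean(cmp)
  max(auc, 1 - auc)
}
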