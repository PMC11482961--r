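# Independent brute-force oracles used to check the package implementations.

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  x <- max(0, k - n):min(k, m)
  p <- dhyper(x, m, n, k)
  sum(p[p <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# AUROC by explicit O(n^2) pair counting
auroc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# optimal k-medoid objective by exhaustive search over medoid subsets
pam_brute_oracle <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in combn(n, k, simplify = FALSE)) {
    best <- min(best, sum(apply(D[, med, drop = FALSE], 1, min)))
  }
  best
}

# rank-then-Pearson Spearman oracle
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# pairwise Jaccard similarity by direct set arithmetic
jaccard_pair_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- m[i, ]; v <- m[j, ]
    uni <- sum(u | v)
    out[i, j] <- if (uni == 0) 1 else sum(u & v) / uni
  }
  out
}
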