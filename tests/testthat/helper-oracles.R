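# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and sums only.

# Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# correlation matrix gene x gene via the direct formula
oracle_corr_matrix <- function(mat) {
  g <- nrow(mat)
  out <- diag(1, g)
  for (i in seq_len(g)) for (j in seq_len(g)) if (i < j) {
    out[i, j] <- out[j, i] <- oracle_pearson(mat[i, ], mat[j, ])
  }
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

# topological overlap by triple loop
oracle_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  g <- nrow(a)
  k <- rowSums(a)
  out <- diag(1, g)
  for (i in seq_len(g)) for (j in seq_len(g)) if (i != j) {
    l_ij <- 0
    for (u in seq_len(g)) if (u != i && u != j) l_ij <- l_ij + a[i, u] * a[u, j]
    out[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(adj)
  out
}

# Mantel correlation: Pearson over the strict upper triangles, by loops
oracle_mantel <- function(da, db) {
  n <- nrow(da)
  va <- c(); vb <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    va <- c(va, da[i, j]); vb <- c(vb, db[i, j])
  }
  oracle_pearson(va, vb)
}

# hypergeometric tail probabilities by direct summation of the pmf
# (table: a = overlap, module size m, flagged K, universe N)
oracle_hyper_pmf <- function(x, K, N, m) {
  exp(lchoose(K, x) + lchoose(N - K, m - x) - lchoose(N, m))
}
oracle_hyper_upper <- function(a, K, N, m) {
  xs <- a:min(K, m)
  sum(oracle_hyper_pmf(xs, K, N, m))
}
oracle_hyper_lower <- function(a, K, N, m) {
  xs <- max(0, m - (N - K)):a
  sum(oracle_hyper_pmf(xs, K, N, m))
}

# upper-quartile scale factors by hand: type-7 75th percentile over genes
# expressed somewhere, divided by library size, centered to geometric mean 1
oracle_uq_factors <- function(counts) {
  expressed <- rowSums(counts) > 0
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    x <- sort(counts[expressed, s])
    n <- length(x)
    h <- (n - 1) * 0.75 + 1
    lo <- floor(h)
    q75 <- x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
    f[s] <- q75 / sum(counts[, s])
  }
  f / exp(mean(log(f)))
}
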