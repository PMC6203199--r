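# Independent oracles used across the suite. These deliberately avoid the
# package's whitening path: quadratic forms are evaluated with an explicitly
# formed Moore-Penrose pseudo-inverse of the low-rank covariance
# reconstruction, and interval overlap with a brute-force O(n*m) scan.

random_binary_matrix <- function(n, d, p = 0.3) {
  matrix(rbinom(n * d, 1, p), nrow = n)
}

# dense-oracle scorer: mu/eigen from the raw sample covariance, SigmaHat from
# the top-k eigenpairs, pseudo-inverse via MASS::ginv
dense_oracle <- function(X, k) {
  mu <- colMeans(X)
  eg <- eigen(cov(X), symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  SigmaHat <- U %*% diag(eg$values[seq_len(k)], k) %*% t(U)
  Sp <- MASS::ginv(SigmaHat)
  qf <- function(a, b, w) {
    as.numeric(t(w * (a - mu)) %*% Sp %*% (w * (b - mu)))
  }
  d <- ncol(X)
  ones <- rep(1, d)
  list(
    mu = mu,
    mahalanobis = function(x, w = rep(1, d)) sqrt(qf(x, x, w)),
    cosine = function(x, w = rep(1, d)) {
      qf(x, ones, w) / sqrt(qf(x, x, w) * qf(ones, ones, w))
    },
    score = function(x, w = rep(1, d)) {
      denom <- sqrt(qf(x, x, w) * qf(ones, ones, w))
      acos(min(1, max(-1, qf(x, ones, w) / denom))) / denom
    }
  )
}

# brute-force overlap of 1-based positions against 0-based half-open
# intervals given as a data.frame(chrom, start, end)
brute_overlap <- function(variants, intervals) {
  vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1L
    any(intervals$chrom == variants$chrom[i] &
          intervals$start <= p0 & p0 < intervals$end)
  }, logical(1))
}

# annotation_matrix wrapper around a plain matrix
wrap_matrix <- function(X, class = "intergenic") {
  pines::annotation_matrix(
    pines::variant_table(rep("1", nrow(X)), seq_len(nrow(X)),
                         variant_class = class),
    X, pines::synthetic_schema(ncol(X)))
}

# rank-based AUROC: probability a positive outranks a negative
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
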