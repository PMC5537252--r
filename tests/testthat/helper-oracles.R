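# Independent oracles shared across suites.

# Straight-line mutual information (bits) from joint counts.
mi_oracle <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      mi <- mi + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
    }
  }
  mi
}

# Straight-line greedy MID ranking (criterion recomputed from scratch at
# every step) used as the mRMR oracle.
mrmr_oracle <- function(X, y, k) {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) mi_oracle(X[, j], y), numeric(1))
  sel <- integer(0)
  for (step in seq_len(min(k, p))) {
    best <- NA; best_crit <- -Inf
    for (j in setdiff(seq_len(p), sel)) {
      crit <- if (length(sel) == 0) rel[j] else {
        rel[j] - mean(vapply(sel, function(i) mi_oracle(X[, j], X[, i]),
                             numeric(1)))
      }
      if (crit > best_crit + 1e-12) { best <- j; best_crit <- crit }
    }
    sel <- c(sel, best)
  }
  sel
}

# Pairwise Mann-Whitney AUC: wins plus half-ties over all pos/neg pairs.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
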