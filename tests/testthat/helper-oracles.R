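# Independent oracles: brute-force implementations kept deliberately naive
# and separate from the package code paths they check.

# Exact Shapley values by full 2^d coalition enumeration with background
# expectation; feasible for d <= ~12.
exact_shap_oracle <- function(predict_fun, x, B) {
  d <- length(x)
  n_masks <- 2^d
  masks <- 0:(n_masks - 1)
  in_mask <- function(mask, j) bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L
  # v(S): mean over background rows of f with features in S set to x
  v <- numeric(n_masks)
  for (m in masks) {
    rows <- B
    for (j in seq_len(d)) {
      if (in_mask(m, j)) rows[, j] <- x[j]
    }
    v[m + 1] <- mean(predict_fun(rows))
  }
  fact <- factorial(0:d)
  phi <- numeric(d)
  for (j in seq_len(d)) {
    for (m in masks) {
      if (!in_mask(m, j)) {
        s <- sum(vapply(seq_len(d), function(k) in_mask(m, k), logical(1)))
        w <- fact[s + 1] * fact[d - s] / fact[d + 1]
        phi[j] <- phi[j] +
          w * (v[m + bitwShiftL(1L, j - 1L) + 1] - v[m + 1])
      }
    }
  }
  phi
}

# Jaccard distance by explicit position counting.
jaccard_oracle <- function(a, b) {
  discordant <- sum((a == 1) != (b == 1))
  informative <- sum(a == 1 | b == 1)
  if (informative == 0) 0 else discordant / informative
}

# AUC by exhaustive positive x negative pair concordance (ties = 1/2).
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Random probability model over d binary features: logistic in a random
# linear score plus pairwise interaction terms.
random_prob_model <- function(d, seed) {
  set.seed(seed)
  w <- rnorm(d, sd = 1.2)
  b0 <- rnorm(1, sd = 0.5)
  ij <- if (d >= 2) utils::combn(d, 2)[, sample(choose(d, 2),
                                                min(3, choose(d, 2)))]
  wij <- rnorm(ncol(ij), sd = 0.8)
  function(M) {
    s <- as.vector(M %*% w) + b0
    for (k in seq_len(ncol(ij))) {
      s <- s + wij[k] * M[, ij[1, k]] * M[, ij[2, k]]
    }
    1 / (1 + exp(-s))
  }
}
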