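# Independent straight-from-formula oracles. These deliberately use
# explicit per-group / per-state loops and never call into the package's
# vectorized code paths.

oracle_posmarg <- function(x, part, alpha) {
  total <- 0
  for (k in sort(unique(part))) {
    members <- which(part == k)
    n <- numeric(length(alpha))
    for (s in seq_along(alpha)) n[s] <- sum(x[members] == s)
    term <- lgamma(sum(alpha)) - sum(lgamma(alpha))
    for (s in seq_along(alpha)) term <- term + lgamma(n[s] + alpha[s])
    term <- term - lgamma(sum(n) + sum(alpha))
    total <- total + term
  }
  total
}

oracle_partition_prior <- function(part, K) {
  m <- numeric(K)
  for (k in seq_len(K)) m[k] <- sum(part == k)
  lgamma(K) + sum(lgamma(m + 1)) - lgamma(sum(m) + K)
}

oracle_model_score <- function(patterns, M, X, alpha, C, K, shift = 1) {
  total <- 0
  for (j in seq_len(nrow(X)))
    total <- total + oracle_posmarg(X[j, ], patterns[[M[j]]], alpha)
  o <- numeric(C)
  for (c in seq_len(C)) o[c] <- sum(M == c)
  total <- total + lgamma(C) - lgamma(length(M) + C) +
    sum(lgamma(o + shift))
  for (c in seq_len(C))
    total <- total + oracle_partition_prior(patterns[[c]], K)
  total
}

oracle_enrich_score <- function(A, M, states, patterns, freqs, beta,
                                alpha, C) {
  l1 <- sum(A == 1); l2 <- sum(A == 2)
  z1 <- z2 <- numeric(C)
  for (c in seq_len(C)) {
    z1[c] <- sum(A == 1 & M == c)
    z2[c] <- sum(A == 2 & M == c)
  }
  total <- lgamma(1 + beta) + lgamma(l1 + 1) + lgamma(l2 + beta) -
    lgamma(beta) - lgamma(l1 + l2 + 1 + beta)
  total <- total + lgamma(C) - lgamma(l1 + C)
  for (c in seq_len(C)) {
    total <- total + lgamma(z1[c] + 1)
    if (z2[c] > 0) total <- total + z2[c] * log(freqs[c])
  }
  for (j in seq_along(M))
    total <- total + oracle_posmarg(states[j, ], patterns[[M[j]]],
                                    alpha)
  total
}

## rank-by-rank average precision, ties broken by input order
oracle_ap <- function(scores, y) {
  ord <- order(-scores)
  tp <- 0; fp <- 0; precs <- numeric(0)
  for (r in seq_along(ord)) {
    if (y[ord[r]] == 1) {
      tp <- tp + 1
      precs <- c(precs, tp / (tp + fp))
    } else {
      fp <- fp + 1
    }
  }
  mean(precs)
}

rand_partition <- function(N, K) sample.int(K, N, replace = TRUE)

## exhaustive search over every (partition set, assignment) combination
## of a tiny model instance; returns the global maximum score
exhaustive_best_score <- function(X, alpha, C, K) {
  N <- ncol(X); L <- nrow(X)
  all_parts <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  all_assign <- as.matrix(expand.grid(rep(list(seq_len(C)), L)))
  best <- -Inf
  part_idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(all_parts))),
                                        C)))
  for (pi in seq_len(nrow(part_idx))) {
    pats <- lapply(seq_len(C), function(c)
      as.integer(all_parts[part_idx[pi, c], ]))
    for (ai in seq_len(nrow(all_assign))) {
      sc <- oracle_model_score(pats, as.integer(all_assign[ai, ]), X,
                               alpha, C, K)
      if (sc > best) best <- sc
    }
  }
  best
}
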