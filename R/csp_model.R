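# Dirichlet-multinomial partition model for cell-type-specificity patterns
# and its annealed conditional-maximization fitter.

#' Build the Dirichlet prior over chromatin states
#'
#' The prior pseudo-counts for the per-group multinomial state
#' distributions are the genome-wide proportions of each state across all
#' epigenomes, scaled to a total mass of \code{multiplier} (default 5).
#' Proportions of states absent from the data are floored at
#' \code{floor} before scaling so every component stays positive.
#'
#' @param states a \code{StateMatrix}, or an integer matrix of state
#'   labels in \code{1..n_states}.
#' @param n_states number of states S; taken from the \code{StateMatrix}
#'   if omitted.
#' @param multiplier total prior mass (sum of the returned vector).
#' @param floor lower bound applied to raw proportions before rescaling.
#' @return numeric vector of length S with positive entries summing to
#'   \code{multiplier}.
#' @export
dirichlet_prior <- function(states, n_states = NULL, multiplier = 5,
                            floor = 1e-6) {
  if (inherits(states, "StateMatrix")) {
    if (is.null(n_states)) n_states <- states$n_states
    x <- states$states
  } else {
    x <- states
    if (is.null(n_states)) n_states <- max(x)
  }
  stopifnot(n_states >= 1, multiplier > 0)
  prop <- tabulate(as.integer(x), nbins = n_states) / length(x)
  prop <- pmax(prop, floor)
  prop <- prop / sum(prop)
  prop * multiplier
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("Dirichlet prior 'alpha' must be finite and strictly positive")
  invisible(alpha)
}

## Dirichlet-multinomial log marginal of one group, vectorized over rows.
## counts: P x S matrix of state counts within the group at P positions.
## Empty groups (all-zero rows) contribute exactly 0.
.dm_term <- function(counts, alpha) {
  a0 <- sum(alpha)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  const <- lgamma(a0) - sum(lgamma(alpha))
  const + rowSums(lgamma(counts + rep(alpha, each = nrow(counts)))) -
    lgamma(rowSums(counts) + a0)
}

## State counts per position for a set of epigenome columns.
## X: P x N integer matrix; members: column indices; returns P x S.
.group_counts <- function(X, members, S) {
  P <- nrow(X)
  out <- matrix(0, P, S)
  if (length(members) == 0L) return(out)
  sub <- X[, members, drop = FALSE]
  for (s in seq_len(S)) out[, s] <- rowSums(sub == s)
  out
}

## One-hot indicator (P x S) of a single epigenome's states at P positions.
.onehot <- function(x, S) {
  out <- matrix(0, length(x), S)
  out[cbind(seq_along(x), x)] <- 1
  out
}

#' Per-position log marginal likelihood under one partition
#'
#' The states of the epigenomes within each group of the partition are
#' modelled as draws from a group-specific multinomial with a
#' Dirichlet(\code{alpha}) prior; the multinomial parameters are
#' marginalized analytically, giving a product of Dirichlet-multinomial
#' terms over groups. Empty groups contribute a factor of 1.
#'
#' @param states_at_j integer vector of length N (one state per
#'   epigenome) or a P x N matrix for vectorized evaluation.
#' @param partition integer vector of length N with group labels in
#'   \code{1..K}; empty groups are permitted.
#' @param alpha Dirichlet prior vector (length S), see
#'   \code{\link{dirichlet_prior}}.
#' @return log probability (length-P vector for matrix input).
#' @export
position_log_marginal <- function(states_at_j, partition, alpha) {
  .check_alpha(alpha)
  S <- length(alpha)
  X <- if (is.null(dim(states_at_j))) {
    matrix(as.integer(states_at_j), nrow = 1L)
  } else {
    states_at_j
  }
  if (ncol(X) != length(partition))
    stop("partition length must equal the number of epigenomes")
  if (any(X < 1L) || any(X > S))
    stop("state labels must lie in 1..length(alpha)")
  K <- max(partition)
  ll <- numeric(nrow(X))
  for (k in seq_len(K)) {
    members <- which(partition == k)
    if (length(members) == 0L) next
    ll <- ll + .dm_term(.group_counts(X, members, S), alpha)
  }
  if (is.null(dim(states_at_j))) ll[1L] else ll
}

#' Log prior of an epigenome partition
#'
#' Epigenomes are assigned to K groups by a multinomial with a
#' Dirichlet(1) prior on the group probabilities, marginalized
#' analytically: \code{lgamma(K) + sum(lgamma(m_k + 1)) - lgamma(N + K)}
#' where \code{m_k} counts the epigenomes in group k.
#'
#' @param partition integer vector with entries in \code{1..K}.
#' @param K number of groups (defaults to \code{max(partition)}).
#' @return log prior probability.
#' @export
partition_log_prior <- function(partition, K = max(partition)) {
  stopifnot(K >= 1, all(partition >= 1L), all(partition <= K))
  m <- tabulate(partition, nbins = K)
  lgamma(K) + sum(lgamma(m + 1)) - lgamma(sum(m) + K)
}

#' Joint log posterior of a CSP catalog and position assignment
#'
#' Sums the per-position Dirichlet-multinomial terms under each
#' position's assigned pattern, the marginalized pattern-frequency term
#' (Dirichlet(1) prior over the C pattern probabilities), and the
#' partition priors of all C patterns (including empty ones). Pattern
#' occurrence counts are recomputed from \code{assignment}.
#'
#' By default the frequency term uses the normalized Dirichlet(1)
#' multinomial marginal, \code{lgamma(o_c + 1)} per pattern;
#' \code{eq4_as_printed = TRUE} substitutes \code{lgamma(o_c + C)}.
#'
#' @param catalog a \code{CSPCatalog} (see \code{\link{csp_catalog}}).
#' @param assignment integer vector of pattern indices, one per position.
#' @param states \code{StateMatrix} or L x N integer matrix.
#' @param alpha Dirichlet state prior; defaults to the catalog's.
#' @param eq4_as_printed use \code{lgamma(o_c + C)} in the frequency term.
#' @return log posterior score (unnormalized).
#' @export
model_log_posterior <- function(catalog, assignment, states, alpha = NULL,
                                eq4_as_printed = FALSE) {
  X <- if (inherits(states, "StateMatrix")) states$states else states
  if (is.null(alpha)) alpha <- catalog$alpha
  .check_alpha(alpha)
  C <- length(catalog$patterns)
  L <- length(assignment)
  if (L > 0 && (any(assignment < 1L) || any(assignment > C)))
    stop("assignment indices outside catalog range")
  if (L != nrow(X) && L > 0)
    stop("assignment length must match the number of positions")
  o <- tabulate(assignment, nbins = C)
  data_term <- 0
  for (c in which(o > 0L)) {
    idx <- which(assignment == c)
    data_term <- data_term +
      sum(position_log_marginal(X[idx, , drop = FALSE],
                                catalog$patterns[[c]], alpha))
  }
  shift <- if (eq4_as_printed) C else 1
  freq_term <- lgamma(C) - lgamma(L + C) + sum(lgamma(o + shift))
  prior_term <- sum(vapply(catalog$patterns, partition_log_prior,
                           numeric(1), K = catalog$K))
  data_term + freq_term + prior_term
}

#' Construct a CSP catalog
#'
#' @param patterns list of integer partitions (length-N vectors with
#'   entries in \code{1..K}).
#' @param counts occurrence count of each pattern among assigned
#'   positions.
#' @param K maximum number of groups per pattern.
#' @param alpha Dirichlet state prior used when the catalog was fitted.
#' @param epigenome_ids optional epigenome identifiers.
#' @return object of class \code{CSPCatalog} with derived frequencies
#'   \code{freqs = counts / sum(counts)}.
#' @export
csp_catalog <- function(patterns, counts = rep(0, length(patterns)),
                        K = max(unlist(patterns)), alpha = NULL,
                        epigenome_ids = NULL) {
  stopifnot(is.list(patterns), length(patterns) >= 1,
            length(counts) == length(patterns))
  n <- unique(lengths(patterns))
  if (length(n) != 1L) stop("all patterns must cover the same epigenomes")
  for (p in patterns) {
    if (any(p < 1L) || any(p > K)) stop("group labels must lie in 1..K")
  }
  freqs <- if (sum(counts) > 0) counts / sum(counts) else
    rep(0, length(counts))
  structure(list(patterns = lapply(patterns, as.integer),
                 counts = as.numeric(counts), freqs = freqs,
                 K = as.integer(K), alpha = alpha,
                 epigenome_ids = epigenome_ids),
            class = "CSPCatalog")
}

#' @export
print.CSPCatalog <- function(x, ...) {
  cat(sprintf("CSPCatalog: %d patterns over %d epigenomes (K = %d)\n",
              length(x$patterns), length(x$patterns[[1]]), x$K))
  ng <- vapply(x$patterns, function(p) length(unique(p)), integer(1))
  cat(sprintf("  groups per pattern: %s\n",
              paste(range(ng), collapse = "-")))
  if (sum(x$counts) > 0)
    cat(sprintf("  top pattern covers %.1f%% of assigned positions\n",
                100 * max(x$freqs)))
  invisible(x)
}

## Renumber group labels by order of first appearance so structurally
## identical partitions compare equal (handles label switching).
canonical_partition <- function(partition) {
  first <- unique(partition)
  match(partition, first)
}

## Annealed choice among candidate scores: Boltzmann sampling at
## temperature > 0, strict argmax (first index on ties) otherwise.
.choose <- function(scores, temperature) {
  if (temperature > 0) {
    w <- exp((scores - max(scores)) / temperature)
    sample.int(length(scores), 1L, prob = w)
  } else {
    which.max(scores)
  }
}

## State-identity partition of one position: epigenomes sharing a state
## share a group; if that yields more than K groups the smallest are
## lumped into group K. Used to seed pattern partitions from data.
.seed_partition <- function(x, K) {
  g <- match(x, unique(x))
  if (max(g) > K) {
    ord <- order(-tabulate(g))
    keep <- ord[seq_len(K - 1L)]
    g <- ifelse(g %in% keep, match(g, keep), K)
  }
  as.integer(g)
}

## One conditional-update sweep over every (pattern, epigenome) group
## label. temp > 0 samples from the annealed conditional, temp == 0
## maximizes (first index on ties). Updates G in place and returns it.
.group_sweep <- function(Xt, M, G, K, S, alpha, temp = 0) {
  N <- ncol(Xt)
  for (c in seq_len(nrow(G))) {
    pos <- which(M == c)
    m <- tabulate(G[c, ], nbins = K)
    if (length(pos) == 0L) {
      ## prior-only conditional for patterns without instances
      for (i in seq_len(N)) {
        k_old <- G[c, i]
        m[k_old] <- m[k_old] - 1L
        k_new <- .choose(log(m + 1), temp)
        G[c, i] <- k_new
        m[k_new] <- m[k_new] + 1L
      }
      next
    }
    Xp <- Xt[pos, , drop = FALSE]
    cnt <- lapply(seq_len(K), function(k)
      .group_counts(Xp, which(G[c, ] == k), S))
    term <- vapply(cnt, function(ct) sum(.dm_term(ct, alpha)),
                   numeric(1))
    for (i in seq_len(N)) {
      k_old <- G[c, i]
      Oi <- .onehot(Xp[, i], S)
      cnt[[k_old]] <- cnt[[k_old]] - Oi
      m[k_old] <- m[k_old] - 1L
      term[k_old] <- sum(.dm_term(cnt[[k_old]], alpha))
      cand <- vapply(seq_len(K), function(k)
        sum(.dm_term(cnt[[k]] + Oi, alpha)), numeric(1))
      k_new <- .choose(sum(term) - term + cand + log(m + 1), temp)
      G[c, i] <- k_new
      cnt[[k_new]] <- cnt[[k_new]] + Oi
      m[k_new] <- m[k_new] + 1L
      term[k_new] <- cand[k_new]
    }
  }
  G
}

#' Fit the CSP model by annealed conditional maximization
#'
#' Pattern partitions are initialized from the data: each of the C
#' patterns takes the state-identity partition of a randomly chosen
#' training position (epigenomes sharing a state share a group), and
#' positions start at their best-fitting seed. Fitting then proceeds in
#' two phases.
#'
#' During the first \code{anneal_iters} sweeps (the exploration phase)
#' the position updates maximize the state likelihood under a uniform
#' pattern-frequency prior -- so rare specificity patterns can nucleate
#' before occurrence counts weigh in -- and patterns that lose all
#' their positions are re-seeded from the currently worst-explained
#' positions. With \code{sample_anneal = TRUE} the exploration phase
#' instead samples every update from its annealed conditional with
#' probability proportional to \code{exp(score / T)}, the temperature
#' decaying linearly from \code{t0} to 1 (classic simulated annealing).
#'
#' After the annealing phase every update enumerates its candidates
#' (all C pattern indices per position, all K group labels per
#' epigenome per pattern) and maximizes the exact full conditional of
#' the joint posterior, so the model score is non-decreasing across
#' post-annealing sweeps and superfluous patterns empty out (Occam
#' pruning). Empty patterns are dropped from the returned catalog,
#' group labels are canonicalized, and all L positions (not just the
#' training subsample) are assigned via \code{\link{assign_positions}}
#' with pattern frequencies estimated on the training subsample.
#'
#' @param states a \code{StateMatrix} or an L x N integer matrix.
#' @param C pattern capacity (patterns without instances end up pruned).
#' @param K maximum groups per pattern.
#' @param n_iter maximum number of sweeps.
#' @param anneal_iters number of initial exploration sweeps.
#' @param t0 initial annealing temperature (used when
#'   \code{sample_anneal = TRUE}).
#' @param sample_anneal sample annealed conditionals during the
#'   exploration phase instead of maximizing.
#' @param train_fraction fraction of positions used to train the model;
#'   the remainder is assigned post hoc.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param eq4_as_printed frequency-term variant, see
#'   \code{\link{model_log_posterior}}.
#' @param verbose print the score per sweep.
#' @return list with elements \code{catalog} (pruned \code{CSPCatalog}),
#'   \code{assignment} (length-L pattern indices), \code{train_idx},
#'   \code{train_assignment}, \code{log_posterior} (score after each
#'   sweep, training data), and \code{converged}.
#' @export
fit_csp_model <- function(states, C = 50, K = 5, n_iter = 100,
                          anneal_iters = 50, t0 = 5,
                          train_fraction = 0.05, seed = NULL,
                          sample_anneal = FALSE,
                          eq4_as_printed = FALSE, verbose = FALSE) {
  sm <- if (inherits(states, "StateMatrix")) states else NULL
  X <- if (is.null(sm)) as.matrix(states) else sm$states
  storage.mode(X) <- "integer"
  L <- nrow(X); N <- ncol(X)
  S <- if (is.null(sm)) max(X) else sm$n_states
  stopifnot(L >= 1, C >= 1, K >= 1, train_fraction > 0,
            train_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_train <- floor(L * train_fraction)
  if (n_train < 1) stop("train_fraction selects fewer than one position")
  train_idx <- sort(sample.int(L, n_train))
  Xt <- X[train_idx, , drop = FALSE]
  Lt <- nrow(Xt)
  alpha <- dirichlet_prior(Xt, n_states = S)
  shift <- if (eq4_as_printed) C else 1

  ## data-seeded initialization
  seeds <- sample.int(Lt, C, replace = C > Lt)
  G <- matrix(1L, C, N)
  for (c in seq_len(C)) G[c, ] <- .seed_partition(Xt[seeds[c], ], K)
  LL <- matrix(0, Lt, C)
  for (c in seq_len(C))
    LL[, c] <- position_log_marginal(Xt, G[c, ], alpha)
  M <- max.col(LL, ties.method = "first")
  o <- tabulate(M, nbins = C)

  score_now <- function() {
    cat_now <- csp_catalog(lapply(seq_len(C), function(c) G[c, ]),
                           counts = o, K = K, alpha = alpha)
    model_log_posterior(cat_now, M, Xt, alpha, eq4_as_printed)
  }
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(n_iter)) {
    annealing <- iter <= anneal_iters
    temp <- if (annealing && sample_anneal) {
      if (anneal_iters > 1) t0 - (t0 - 1) * (iter - 1) / (anneal_iters - 1)
      else t0
    } else 0
    changed <- FALSE

    G <- .group_sweep(Xt, M, G, K, S, alpha, temp = temp)
    LL <- matrix(0, Lt, C)
    for (c in seq_len(C))
      LL[, c] <- position_log_marginal(Xt, G[c, ], alpha)

    if (annealing) {
      ## re-seed instance-less patterns from worst-explained positions
      empties <- which(o == 0L)
      if (length(empties) > 0L) {
        cur <- LL[cbind(seq_len(Lt), M)]
        worst <- order(cur)[seq_len(min(length(empties), Lt))]
        for (ei in seq_along(worst)) {
          c <- empties[ei]
          G[c, ] <- .seed_partition(Xt[worst[ei], ], K)
          LL[, c] <- position_log_marginal(Xt, G[c, ], alpha)
        }
      }
      ## position updates under a uniform pattern prior; with
      ## sample_anneal the Gumbel-max draw realizes exp(LL / T)
      ## sampling, otherwise plain likelihood maximization
      if (sample_anneal) {
        gum <- -log(-log(matrix(stats::runif(Lt * C), Lt, C)))
        M_new <- max.col(LL / temp + gum, ties.method = "first")
      } else {
        M_new <- max.col(LL, ties.method = "first")
      }
      changed <- any(M_new != M)
      M <- M_new
      o <- tabulate(M, nbins = C)
    } else {
      ## exact conditional maximization, position by position
      for (j in seq_len(Lt)) {
        o[M[j]] <- o[M[j]] - 1L
        cnew <- which.max(LL[j, ] + log(o + shift))
        if (cnew != M[j]) changed <- TRUE
        M[j] <- cnew
        o[cnew] <- o[cnew] + 1L
      }
    }

    trace <- c(trace, score_now())
    if (verbose)
      message(sprintf("sweep %3d  T=%.2f  log-posterior %.4f",
                      iter, temp, trace[iter]))
    if (!changed && !annealing) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_csp_model: sweep limit reached before convergence; ",
            "returning current state")

  ## prune empty patterns, canonicalize, recompute counts
  keep <- which(o > 0L)
  patterns <- lapply(keep, function(c) canonical_partition(G[c, ]))
  remap <- integer(C); remap[keep] <- seq_along(keep)
  M_train <- remap[M]
  catalog <- csp_catalog(patterns, counts = o[keep], K = K,
                         alpha = alpha,
                         epigenome_ids = if (!is.null(sm))
                           sm$epigenome_ids else colnames(X))
  assignment <- integer(L)
  assignment[train_idx] <- M_train
  rest <- setdiff(seq_len(L), train_idx)
  if (length(rest) > 0)
    assignment[rest] <- assign_positions(catalog, X[rest, , drop = FALSE])
  list(catalog = catalog, assignment = assignment,
       train_idx = train_idx, train_assignment = M_train,
       log_posterior = trace, converged = converged)
}

#' Assign positions to their most probable pattern
#'
#' Each position receives the pattern maximizing \code{log p_c +}
#' its Dirichlet-multinomial log marginal under pattern c, with ties
#' broken by the lowest pattern index. Pattern frequencies \code{p_c}
#' come from the catalog.
#'
#' @param catalog fitted \code{CSPCatalog} with positive counts.
#' @param states \code{StateMatrix} or L x N integer matrix.
#' @param alpha Dirichlet state prior; defaults to the catalog's.
#' @return integer vector of pattern indices (length L).
#' @export
assign_positions <- function(catalog, states, alpha = NULL) {
  X <- if (inherits(states, "StateMatrix")) states$states else states
  if (is.null(alpha)) alpha <- catalog$alpha
  .check_alpha(alpha)
  nonempty <- which(catalog$counts > 0)
  if (length(nonempty) == 0L)
    stop("catalog has no non-empty patterns")
  logp <- rep(-Inf, length(catalog$patterns))
  logp[nonempty] <- log(catalog$freqs[nonempty])
  sc <- vapply(seq_along(catalog$patterns), function(c) {
    if (is.finite(logp[c]))
      logp[c] + position_log_marginal(X, catalog$patterns[[c]], alpha)
    else rep(-Inf, nrow(X))
  }, numeric(nrow(X)))
  sc <- matrix(sc, nrow = nrow(X))
  max.col(sc, ties.method = "first")
}
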