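# Risk-variant sub-selection under a two-group Bayesian mixture: group-1
# variants co-occur with CSPs at free (Dirichlet-prior) frequencies,
# group-2 variants follow the genome background p_c. Plus permutation
# p-values for per-pattern enrichment/depletion.

#' Choose the group-size penalty beta for the enrichment mixture
#'
#' The Beta(1, beta) prior on the group-1 probability must favor the
#' null of no enrichment; beta is 10 or the largest LD-cluster size
#' among the risk variants, whichever is greater.
#'
#' @param variants a \code{VariantSet} of risk variants (or a risk/null
#'   mix; only rows labelled \code{"risk"} count).
#' @return numeric penalty >= 10.
#' @export
choose_beta <- function(variants) {
  v <- variants$variants
  v <- v[v$label == "risk", , drop = FALSE]
  if (nrow(v) == 0L) stop("no risk variants to choose beta from")
  max(10, max(table(v$ld_cluster)))
}

#' Log posterior of the two-group enrichment mixture
#'
#' Implements the marginalized mixture score: a Beta(1, beta) term in
#' the group sizes (l1, l2), a Dirichlet(1) marginal over group-1
#' pattern co-occurrence counts z1c, the background multinomial
#' \code{sum_c z2c log p_c} for group 2, and the Dirichlet-multinomial
#' state term of every risk variant under its current pattern.
#'
#' @param grouping list with \code{A} (1/2 per variant) and \code{M}
#'   (pattern index per variant), as returned by
#'   \code{\link{fit_enrichment}}.
#' @param variants \code{VariantSet} of the risk variants.
#' @param catalog fitted \code{CSPCatalog} supplying background
#'   frequencies p_c.
#' @param beta group-size penalty (see \code{\link{choose_beta}}).
#' @param alpha Dirichlet state prior; defaults to the catalog's.
#' @return log score; \code{-Inf} when a background-zero pattern holds
#'   group-2 variants.
#' @export
enrichment_log_posterior <- function(grouping, variants, catalog, beta,
                                     alpha = NULL) {
  if (is.null(alpha)) alpha <- catalog$alpha
  .check_alpha(alpha)
  C <- length(catalog$patterns)
  A <- grouping$A; M <- grouping$M
  stopifnot(length(A) == length(M), all(A %in% c(1L, 2L)),
            all(M >= 1L), all(M <= C))
  l1 <- sum(A == 1L); l2 <- sum(A == 2L)
  z1 <- tabulate(M[A == 1L], nbins = C)
  z2 <- tabulate(M[A == 2L], nbins = C)
  p_c <- catalog$freqs
  mix <- lgamma(1 + beta) + lgamma(l1 + 1) + lgamma(l2 + beta) -
    lgamma(beta) - lgamma(l1 + l2 + 1 + beta)
  dir1 <- lgamma(C) - lgamma(l1 + C) + sum(lgamma(z1 + 1))
  bg <- sum(ifelse(z2 > 0, z2 * log(p_c), 0))
  state_term <- 0
  for (c in unique(M)) {
    idx <- which(M == c)
    state_term <- state_term +
      sum(position_log_marginal(variants$states[idx, , drop = FALSE],
                                catalog$patterns[[c]], alpha))
  }
  mix + dir1 + bg + state_term
}

#' Fit the enrichment mixture by annealed conditional maximization
#'
#' Sweeps over the variants; for each one, all 2C candidate
#' (group, pattern) combinations are enumerated and scored by their
#' full conditional. The first \code{anneal_iters} sweeps sample
#' candidates at a temperature decaying linearly from \code{t0} to 1;
#' later sweeps maximize, and additionally consider pattern-wise block
#' moves (all variants of one pattern switching group together, which
#' single-variant updates cannot reach because group-1 co-occurrence
#' counts are self-reinforcing), so the score is non-decreasing after
#' the annealing phase. Because the no-enrichment configuration is
#' itself a fixed point separated from group-1 coalitions by a score
#' barrier, the fitted mode is finally compared against the null
#' configuration (every variant in group 2 with its background-optimal
#' pattern) and the higher-scoring one is polished and returned; under
#' null data this dissolves spurious coalitions.
#'
#' @param variants \code{VariantSet} of risk variants carrying state
#'   vectors.
#' @param catalog fitted \code{CSPCatalog}.
#' @param beta group-size penalty; \code{NULL} uses
#'   \code{\link{choose_beta}}.
#' @param n_iter maximum sweeps.
#' @param anneal_iters,t0 annealing schedule (as in
#'   \code{\link{fit_csp_model}}).
#' @param seed integer seed.
#' @return list of class \code{RiskGrouping}: \code{A}, \code{M},
#'   \code{l1}, \code{l2}, \code{z1}, \code{z2}, \code{group1_ids},
#'   \code{log_posterior} trace, \code{beta}.
#' @export
fit_enrichment <- function(variants, catalog, beta = NULL, n_iter = 60,
                           anneal_iters = 20, t0 = 5, seed = NULL) {
  if (is.null(beta)) beta <- choose_beta(variants)
  stopifnot(beta >= 1)
  if (!is.null(seed)) set.seed(seed)
  alpha <- catalog$alpha
  .check_alpha(alpha)
  C <- length(catalog$patterns)
  n <- nrow(variants$states)
  log_pc <- ifelse(catalog$freqs > 0, log(catalog$freqs), -Inf)
  LL <- vapply(seq_len(C), function(c)
    position_log_marginal(variants$states, catalog$patterns[[c]],
                          alpha), numeric(n))
  LL <- matrix(LL, nrow = n)

  A <- sample(c(1L, 2L), n, replace = TRUE)
  M <- sample.int(C, n, replace = TRUE)
  l1 <- sum(A == 1L); l2 <- n - l1
  z1 <- tabulate(M[A == 1L], nbins = C)
  z2 <- tabulate(M[A == 2L], nbins = C)

  trace <- numeric(0)
  for (iter in seq_len(n_iter)) {
    temp <- if (iter <= anneal_iters) {
      if (anneal_iters > 1) t0 - (t0 - 1) * (iter - 1) / (anneal_iters - 1)
      else t0
    } else 0
    changed <- FALSE
    for (j in seq_len(n)) {
      if (A[j] == 1L) { l1 <- l1 - 1L; z1[M[j]] <- z1[M[j]] - 1L }
      else { l2 <- l2 - 1L; z2[M[j]] <- z2[M[j]] - 1L }
      sc1 <- log(l1 + 1) - log(l1 + C) + log(z1 + 1) + LL[j, ]
      sc2 <- log(l2 + beta) + log_pc + LL[j, ]
      sc <- c(sc1, sc2)
      pick <- .choose(sc, temp)
      a_new <- if (pick <= C) 1L else 2L
      c_new <- if (pick <= C) pick else pick - C
      if (a_new != A[j] || c_new != M[j]) changed <- TRUE
      A[j] <- a_new; M[j] <- c_new
      if (a_new == 1L) { l1 <- l1 + 1L; z1[c_new] <- z1[c_new] + 1L }
      else { l2 <- l2 + 1L; z2[c_new] <- z2[c_new] + 1L }
    }
    if (iter > anneal_iters) {
      ## block moves: all variants of one pattern change group together
      grp_part <- function(l1v, l2v, z1v, z2v) {
        lgamma(l1v + 1) + lgamma(l2v + beta) - lgamma(l1v + C) +
          sum(lgamma(z1v + 1)) +
          sum(ifelse(z2v > 0, z2v * log(catalog$freqs), 0))
      }
      repeat {
        moved <- FALSE
        for (c in seq_len(C)) {
          if (z1[c] == 0L && z2[c] == 0L) next
          cur <- grp_part(l1, l2, z1, z2)
          ## all of pattern c to group 2
          if (z1[c] > 0L) {
            z1a <- z1; z2a <- z2
            z2a[c] <- z2a[c] + z1a[c]; n_mv <- z1a[c]; z1a[c] <- 0L
            if (grp_part(l1 - n_mv, l2 + n_mv, z1a, z2a) > cur +
                1e-12) {
              A[M == c] <- 2L
              l1 <- l1 - n_mv; l2 <- l2 + n_mv; z1 <- z1a; z2 <- z2a
              moved <- TRUE; changed <- TRUE
              next
            }
          }
          ## all of pattern c to group 1
          if (z2[c] > 0L) {
            z1b <- z1; z2b <- z2
            z1b[c] <- z1b[c] + z2b[c]; n_mv <- z2b[c]; z2b[c] <- 0L
            if (grp_part(l1 + n_mv, l2 - n_mv, z1b, z2b) > cur +
                1e-12) {
              A[M == c] <- 1L
              l1 <- l1 + n_mv; l2 <- l2 - n_mv; z1 <- z1b; z2 <- z2b
              moved <- TRUE; changed <- TRUE
            }
          }
        }
        if (!moved) break
      }
    }
    trace <- c(trace, enrichment_log_posterior(
      list(A = A, M = M), variants, catalog, beta, alpha))
    if (!changed && iter > anneal_iters) break
  }

  ## the null mode (everything in group 2 at its background-optimal
  ## pattern) is a fixed point of its own; keep whichever mode scores
  ## higher, so no enrichment is reported when the null explains the
  ## data at least as well
  M_null <- max.col(matrix(log_pc, n, C, byrow = TRUE) + LL,
                    ties.method = "first")
  null_score <- enrichment_log_posterior(
    list(A = rep(2L, n), M = M_null), variants, catalog, beta, alpha)
  if (null_score > trace[length(trace)] + 1e-12) {
    A <- rep(2L, n); M <- M_null
    l1 <- 0L; l2 <- n
    z1 <- integer(C); z2 <- tabulate(M, nbins = C)
    trace <- c(trace, null_score)
  }
  structure(list(A = A, M = M, l1 = l1, l2 = l2, z1 = z1, z2 = z2,
                 group1_ids = variants$variants$variant_id[A == 1L],
                 log_posterior = trace, beta = beta),
            class = "RiskGrouping")
}

#' @export
print.RiskGrouping <- function(x, ...) {
  cat(sprintf(
    "RiskGrouping: %d of %d variants CSP-associated (group 1, %.1f%%)\n",
    x$l1, x$l1 + x$l2, 100 * x$l1 / (x$l1 + x$l2)))
  invisible(x)
}

#' Permutation test for per-pattern enrichment or depletion
#'
#' Compares the pattern counts of the risk variants against draws of
#' equally many positions from the genome-wide background assignment.
#' Two-sided p-values double the smaller tail with an add-one
#' correction, \code{p = min(1, 2 * min(p_ge, p_le))} where
#' \code{p_ge = (r + 1) / (n_perm + 1)}.
#'
#' @param risk_patterns integer pattern indices of the risk variants.
#' @param background integer pattern assignment of the genome windows.
#' @param n_perm number of permutation draws.
#' @param seed integer seed.
#' @param n_patterns number of patterns (defaults to the max observed).
#' @return data frame of class \code{EnrichmentReport}: \code{pattern},
#'   \code{observed}, \code{expected}, \code{p_two_sided},
#'   \code{signed_log10p} (negative for depletion).
#' @export
csp_permutation_test <- function(risk_patterns, background,
                                 n_perm = 10000, seed = NULL,
                                 n_patterns = max(background,
                                                  risk_patterns)) {
  stopifnot(n_perm >= 1)
  n_r <- length(risk_patterns)
  if (length(background) < n_r)
    stop("background assignment smaller than the risk set")
  if (!is.null(seed)) set.seed(seed)
  obs <- tabulate(risk_patterns, nbins = n_patterns)
  expd <- n_r * tabulate(background, nbins = n_patterns) /
    length(background)
  ge <- le <- integer(n_patterns)
  for (b in seq_len(n_perm)) {
    cnt <- tabulate(sample(background, n_r, replace = FALSE),
                    nbins = n_patterns)
    ge <- ge + (cnt >= obs)
    le <- le + (cnt <= obs)
  }
  p_ge <- (ge + 1) / (n_perm + 1)
  p_le <- (le + 1) / (n_perm + 1)
  p <- pmin(1, 2 * pmin(p_ge, p_le))
  out <- data.frame(pattern = seq_len(n_patterns), observed = obs,
                    expected = expd, p_two_sided = p,
                    signed_log10p = -log10(p) * sign(obs - expd))
  class(out) <- c("EnrichmentReport", "data.frame")
  out
}
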