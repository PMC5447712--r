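# Chromatin-state enrichment z-scores over fixed epigenome clusters.

#' Binomial z-score for one state in one epigenome cluster
#'
#' With n_sg occurrences of state s inside cluster g and n_s_neg_g
#' outside it, and p_g the proportion of epigenomes in g, the score is
#' \code{(n_sg - (n_sg + n_s_neg_g) * p_g) /
#' sqrt((n_sg + n_s_neg_g) * p_g * (1 - p_g) + 1)}; the +1 stabilizes
#' empty counts.
#'
#' @param n_sg,n_s_neg_g state counts inside/outside the cluster
#'   (vectorized).
#' @param p_g cluster proportion, strictly inside (0, 1).
#' @return numeric z-score(s).
#' @export
state_zscore <- function(n_sg, n_s_neg_g, p_g) {
  if (any(p_g <= 0 | p_g >= 1))
    stop("p_g must lie strictly in (0, 1)")
  stopifnot(all(n_sg >= 0), all(n_s_neg_g >= 0))
  tot <- n_sg + n_s_neg_g
  (n_sg - tot * p_g) / sqrt(tot * p_g * (1 - p_g) + 1)
}

#' Sign-preserving log compression of z-scores
#'
#' \code{sign(z) * log(|z| + 1)}: odd, strictly monotone, identity-like
#' near zero.
#'
#' @param z numeric vector.
#' @return transformed values.
#' @export
transform_z <- function(z) {
  sign(z) * log(abs(z) + 1)
}

#' State-by-cluster z-score matrix for one variant
#'
#' Counts each variant's per-epigenome states within each cluster and
#' scores every (state, cluster) cell; with S states and G clusters the
#' flattened matrix has S x G entries (250 for S = 25, G = 10).
#'
#' @param variant_states integer vector of length N (one state per
#'   epigenome) or an n x N matrix for several variants.
#' @param clusters a \code{ClusterDefinition} covering all N epigenomes
#'   (matched by position; names are documentation).
#' @param S number of states.
#' @param transformed apply \code{\link{transform_z}}.
#' @return S x G matrix for one variant, or an n x (S*G) matrix with
#'   columns ordered state-major (\code{s1_g1, s2_g1, ...}).
#' @export
variant_zscores <- function(variant_states, clusters, S,
                            transformed = FALSE) {
  g_of <- clusters$cluster_of
  G <- clusters$n_clusters
  X <- if (is.null(dim(variant_states)))
    matrix(as.integer(variant_states), nrow = 1L) else variant_states
  if (ncol(X) != length(g_of))
    stop("cluster definition must cover every epigenome")
  ## n_sg per variant: counts of state s among cluster-g epigenomes
  Z <- matrix(0, nrow(X), S * G)
  tot_s <- vapply(seq_len(S), function(s) rowSums(X == s),
                  numeric(nrow(X)))
  tot_s <- matrix(tot_s, nrow = nrow(X))
  for (g in seq_len(G)) {
    members <- which(g_of == g)
    p_g <- clusters$p_g[g]
    for (s in seq_len(S)) {
      n_sg <- rowSums(X[, members, drop = FALSE] == s)
      Z[, (g - 1L) * S + s] <-
        state_zscore(n_sg, tot_s[, s] - n_sg, p_g)
    }
  }
  if (transformed) Z <- transform_z(Z)
  colnames(Z) <- paste0("s", rep(seq_len(S), G), "_g",
                        rep(seq_len(G), each = S))
  if (is.null(dim(variant_states))) {
    matrix(Z[1L, ], S, G,
           dimnames = list(paste0("s", seq_len(S)),
                           paste0("g", seq_len(G))))
  } else Z
}

#' Background-subtracted trait-level z-score matrix
#'
#' Averages the raw per-variant z-scores over the risk variants,
#' subtracts the average over the null variants, and optionally applies
#' the sign-log transform to the difference.
#'
#' @param risk,null \code{VariantSet}s.
#' @param clusters a \code{ClusterDefinition}.
#' @param S number of states.
#' @param transformed transform the subtracted matrix.
#' @return S x G matrix.
#' @export
trait_zscores <- function(risk, null, clusters, S,
                          transformed = FALSE) {
  if (nrow(risk$states) == 0L || nrow(null$states) == 0L)
    stop("risk and null sets must be non-empty")
  zr <- colMeans(variant_zscores(risk$states, clusters, S))
  zn <- colMeans(variant_zscores(null$states, clusters, S))
  d <- zr - zn
  if (transformed) d <- transform_z(d)
  matrix(d, S, clusters$n_clusters,
         dimnames = list(paste0("s", seq_len(S)),
                         paste0("g", seq_len(clusters$n_clusters))))
}
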