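# GWAS power simulation: causal SNPs sampled along a precision-recall
# profile, correlated test statistics under block LD, prior-weighted
# per-SNP significance thresholds, and 1 kb detection power.

#' Sample causal SNPs along a precision-recall profile
#'
#' Reading the profile as "x% of causal variants come from the top y%
#' of SNPs ranked by the predictive model", each recall increment
#' between successive profile points contributes its share of the
#' \code{n_causal} causals, drawn uniformly without replacement from
#' the top \code{n_causal * recall / precision} ranked SNPs.
#'
#' @param pr_profile data frame with increasing \code{recall} in (0, 1]
#'   (ending at 1) and \code{precision} in (0, 1].
#' @param panel a \code{SnpPanel}; ranking by decreasing \code{score}.
#' @param n_causal number of causal SNPs.
#' @param seed integer seed.
#' @return integer vector of causal SNP indices (rows of
#'   \code{panel$snps}).
#' @export
sample_causals <- function(pr_profile, panel, n_causal = 100,
                           seed = NULL) {
  stopifnot(all(pr_profile$precision > 0),
            all(pr_profile$recall > 0), all(pr_profile$recall <= 1),
            !is.unsorted(pr_profile$recall))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel$snps)
  ranked <- order(-panel$snps$score)
  prev_recall <- 0
  chosen <- integer(0)
  for (t in seq_len(nrow(pr_profile))) {
    frac <- pr_profile$recall[t] - prev_recall
    prev_recall <- pr_profile$recall[t]
    k <- round(n_causal * pr_profile$recall[t]) - length(chosen)
    if (k <= 0) next
    top_n <- min(m, max(1L, ceiling(
      n_causal * pr_profile$recall[t] / pr_profile$precision[t])))
    avail <- setdiff(ranked[seq_len(top_n)], chosen)
    if (length(avail) < k) {
      avail <- setdiff(ranked, chosen)
    }
    chosen <- c(chosen, if (length(avail) == 1L) avail else
      sample(avail, k))
  }
  if (length(chosen) < n_causal) {
    avail <- setdiff(ranked, chosen)
    chosen <- c(chosen, sample(avail, n_causal - length(chosen)))
  }
  chosen
}

#' Simulate per-SNP association statistics under block LD
#'
#' Every SNP starts from a standard-normal null statistic. Each causal
#' SNP draws an effect size lambda from N(\code{effect_mean},
#' \code{effect_sd}) with a random sign and carries the statistic
#' \code{t = log(1 + lambda) * sqrt(n_samples)} (the per-observation
#' log-odds effect scaled by the square root of the sample size; set
#' \code{literal_t = TRUE} for \code{log(1 + lambda) / n_samples}).
#' Non-causal SNPs within the panel's LD radius of a causal take
#' \code{r * t + sqrt(1 - r^2) * z}, with r the panel correlation to
#' the nearest causal.
#'
#' @param panel a \code{SnpPanel}.
#' @param causals integer indices of causal SNPs.
#' @param n_samples GWAS sample size (cases + controls).
#' @param effect_mean,effect_sd effect-size distribution (sd, not
#'   variance).
#' @param literal_t divide by n instead of multiplying by sqrt(n).
#' @param seed integer seed.
#' @return numeric vector of statistics, one per panel SNP.
#' @export
simulate_stats <- function(panel, causals, n_samples = 2000,
                           effect_mean = 0.1, effect_sd = 0.05,
                           literal_t = FALSE, seed = NULL) {
  stopifnot(effect_sd > 0, all(causals >= 1),
            all(causals <= nrow(panel$snps)))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel$snps)
  z <- stats::rnorm(m)
  stat <- z
  if (length(causals) == 0L) return(stat)
  lam <- stats::rnorm(length(causals), effect_mean, effect_sd) *
    sample(c(-1, 1), length(causals), replace = TRUE)
  t_c <- if (literal_t) log(1 + lam) / n_samples else
    log(1 + lam) * sqrt(n_samples)
  pos <- panel$snps$pos
  blk <- panel$snps$block
  ## nearest causal within the LD radius drives each SNP
  for (i in seq_len(m)) {
    d <- abs(pos[causals] - pos[i])
    near <- which(d <= panel$ld_radius)
    if (length(near) == 0L) next
    cidx <- near[which.min(d[near])]
    if (causals[cidx] == i) {
      stat[i] <- t_c[cidx]
    } else {
      r <- if (blk[causals[cidx]] == blk[i]) panel$r_within else 0
      stat[i] <- r * t_c[cidx] + sqrt(1 - r^2) * z[i]
    }
  }
  stat
}

#' Prior-weighted per-SNP significance thresholds
#'
#' Allocates the overall budget \code{p_cut} across SNPs in proportion
#' to their predicted causal probabilities:
#' \code{p_i = p_cut * pi_i / sum(pi)}. Uniform priors reduce to the
#' Bonferroni threshold \code{p_cut / m}; the thresholds always sum to
#' \code{p_cut} exactly.
#'
#' @param priors non-negative per-SNP causal probabilities, not all 0.
#' @param p_cut overall significance budget in (0, 1).
#' @return numeric vector of thresholds.
#' @export
weighted_thresholds <- function(priors, p_cut = 0.05) {
  if (p_cut <= 0 || p_cut >= 1) stop("p_cut must lie in (0, 1)")
  if (any(priors < 0) || sum(priors) <= 0)
    stop("priors must be non-negative with positive sum")
  p_cut * priors / sum(priors)
}

#' Detection power within a distance window of the causals
#'
#' A SNP is detected when its two-sided normal p-value falls below its
#' per-SNP threshold; power is the fraction of causal SNPs with at
#' least one detected SNP within \code{window} bp (the causal itself
#' counts).
#'
#' @param statistics per-SNP statistics (e.g.
#'   \code{\link{simulate_stats}}).
#' @param thresholds per-SNP p-value thresholds.
#' @param causals causal SNP indices.
#' @param panel a \code{SnpPanel}.
#' @param window detection radius in bp.
#' @return power in [0, 1].
#' @export
compute_power <- function(statistics, thresholds, causals, panel,
                          window = 1000) {
  if (length(causals) == 0L) stop("empty causal set")
  pvals <- 2 * stats::pnorm(-abs(statistics))
  detected <- which(pvals < thresholds)
  if (length(detected) == 0L) return(0)
  pos <- panel$snps$pos
  hit <- vapply(causals, function(ci)
    any(abs(pos[detected] - pos[ci]) <= window), logical(1))
  mean(hit)
}

#' Per-SNP causal priors implied by a precision-recall profile
#'
#' Converts the profile into the per-rank causal intensity of
#' \code{\link{sample_causals}}: each recall increment spreads its
#' causal mass uniformly over the top \code{n_causal * recall /
#' precision} ranked SNPs, and the per-SNP contributions accumulate.
#' The result is the expected number of causals per SNP, usable
#' directly as prior weights for \code{\link{weighted_thresholds}}.
#'
#' @inheritParams sample_causals
#' @return non-negative vector over the panel SNPs.
#' @export
profile_priors <- function(pr_profile, panel, n_causal = 100) {
  m <- nrow(panel$snps)
  ranked <- order(-panel$snps$score)
  intensity <- numeric(m)
  prev_recall <- 0
  for (t in seq_len(nrow(pr_profile))) {
    mass <- n_causal * (pr_profile$recall[t] - prev_recall)
    prev_recall <- pr_profile$recall[t]
    if (mass <= 0) next
    top_n <- min(m, max(1L, ceiling(
      n_causal * pr_profile$recall[t] / pr_profile$precision[t])))
    intensity[ranked[seq_len(top_n)]] <-
      intensity[ranked[seq_len(top_n)]] + mass / top_n
  }
  intensity
}

#' Run the full power simulation
#'
#' For each replicate: sample causals along the PR profile, simulate
#' statistics, and measure 1 kb power under both the uniform
#' (Bonferroni) threshold and prior-weighted thresholds built from the
#' supplied per-SNP priors.
#'
#' @param pr_profile precision-recall profile (see
#'   \code{\link{sample_causals}}).
#' @param panel a \code{SnpPanel}.
#' @param priors per-SNP causal priors; \code{NULL} uses the
#'   profile-implied priors of \code{\link{profile_priors}}.
#' @param n_causal causal SNPs per replicate.
#' @param p_cut significance budget.
#' @param n_replicates simulation replicates.
#' @param seed integer seed.
#' @return data frame with one row per replicate: \code{power_uniform},
#'   \code{power_weighted}.
#' @export
run_power_sim <- function(pr_profile, panel, priors = NULL,
                          n_causal = 100, p_cut = 0.05,
                          n_replicates = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel$snps)
  if (is.null(priors))
    priors <- profile_priors(pr_profile, panel, n_causal)
  th_u <- weighted_thresholds(rep(1, m), p_cut)
  th_w <- weighted_thresholds(priors, p_cut)
  out <- data.frame(power_uniform = numeric(n_replicates),
                    power_weighted = numeric(n_replicates))
  for (b in seq_len(n_replicates)) {
    causals <- sample_causals(pr_profile, panel, n_causal)
    stat <- simulate_stats(panel, causals)
    out$power_uniform[b] <- compute_power(stat, th_u, causals, panel)
    out$power_weighted[b] <- compute_power(stat, th_w, causals, panel)
  }
  out
}
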