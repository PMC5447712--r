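# Seeded generators for every input the other modules consume, with
# planted ground truth carried alongside for parameter-recovery tests.

#' Default planted partitions for the desk-scale instance
#'
#' Four patterns over N epigenomes: one constitutive (all epigenomes in
#' one group) and three genuinely cell-type-specific partitions into two
#' or three groups, mirroring the structure seen in real multi-epigenome
#' segmentations where a constitutive pattern dominates.
#'
#' @param N number of epigenomes (default 12).
#' @return list of integer partitions.
#' @export
default_true_patterns <- function(N = 12) {
  stopifnot(N >= 6)
  half <- floor(N / 2)
  third <- floor(N / 3)
  list(
    rep(1L, N),                                       # constitutive
    c(rep(1L, half), rep(2L, N - half)),              # two halves
    c(rep(1L, third), rep(2L, third),
      rep(3L, N - 2L * third)),                       # three blocks
    rep(c(1L, 2L), length.out = N)                    # interleaved
  )
}

## One Dirichlet(conc) draw per group; redrawn (up to max_try times)
## until the groups' modal states are pairwise distinct, so planted
## partitions are identifiable (well-separated group distributions).
.draw_group_dists <- function(n_groups, S, concentration, max_try = 50L) {
  for (t in seq_len(max_try)) {
    th <- matrix(stats::rgamma(n_groups * S, shape = concentration),
                 n_groups, S)
    th <- th / rowSums(th)
    if (anyNA(th)) next
    if (n_groups == 1L || !anyDuplicated(max.col(th))) return(th)
  }
  th
}

#' Generate a synthetic chromatin-state matrix with planted patterns
#'
#' Position by position, a pattern is drawn from \code{pattern_freqs};
#' each group of the chosen partition draws a state distribution from
#' Dirichlet(\code{concentration}) (redrawn until group modes are
#' distinct, keeping groups well separated) and its member epigenomes
#' emit states independently from it.
#'
#' @param N,L,S epigenomes, windows, states.
#' @param true_patterns list of planted partitions (integer vectors of
#'   length N); defaults to \code{default_true_patterns(N)}.
#' @param pattern_freqs occurrence probability of each pattern; default
#'   0.70 constitutive and the rest split evenly.
#' @param concentration symmetric Dirichlet parameter controlling
#'   within-group state purity (smaller = purer).
#' @param seed integer seed.
#' @param window_size bp per window.
#' @return list with \code{states} (a \code{StateMatrix}) and
#'   \code{truth} (class \code{PlantedTruth}: the planted partitions,
#'   per-position pattern labels, frequencies and concentration).
#' @export
gen_state_matrix <- function(N = 12, L = 2000, S = 6,
                             true_patterns = default_true_patterns(N),
                             pattern_freqs = NULL,
                             concentration = 0.01, seed = 1,
                             window_size = 200L) {
  stopifnot(N >= 1, L >= 1, S >= 2, concentration > 0,
            all(lengths(true_patterns) == N))
  P <- length(true_patterns)
  if (is.null(pattern_freqs)) {
    pattern_freqs <- if (P == 1L) 1 else
      c(0.70, rep(0.30 / (P - 1), P - 1))
  }
  if (length(pattern_freqs) != P ||
      abs(sum(pattern_freqs) - 1) > 1e-8 || any(pattern_freqs <= 0))
    stop("pattern_freqs must be positive and sum to 1")
  set.seed(seed)
  labels <- sample.int(P, L, replace = TRUE, prob = pattern_freqs)
  X <- matrix(0L, L, N)
  for (j in seq_len(L)) {
    part <- true_patterns[[labels[j]]]
    groups <- sort(unique(part))
    th <- .draw_group_dists(length(groups), S, concentration)
    for (gi in seq_along(groups)) {
      members <- which(part == groups[gi])
      X[j, members] <- sample.int(S, length(members), replace = TRUE,
                                  prob = th[gi, ])
    }
  }
  sm <- state_matrix(X, n_states = S, window_size = window_size,
                     epigenome_ids = paste0("E", seq_len(N)))
  truth <- structure(list(patterns = lapply(true_patterns,
                                            canonical_partition),
                          position_labels = labels,
                          pattern_freqs = pattern_freqs,
                          concentration = concentration, seed = seed),
                     class = "PlantedTruth")
  list(states = sm, truth = truth)
}

## MAF and annotation model shared by risk and null variants so that
## matched-null construction is testable.
.annotation_vocab <- c("intergenic", "intronic", "utr", "regulatory",
                       "coding")
.annotation_probs <- c(0.35, 0.35, 0.10, 0.15, 0.05)

.draw_maf <- function(n) {
  0.5 * stats::rbeta(n, 1.2, 2.5)
}

#' Generate risk and null variant sets with planted CSP enrichment
#'
#' Risk variants fall on genomic windows carrying one of the
#' \code{enriched_patterns} at \code{enrichment_fold} times the
#' background rate; null variants follow the background. Each risk lead
#' variant brings \code{ld_cluster_size - 1} proxies placed in the same
#' window (hence sharing its pattern), emulating tight LD. MAF and
#' annotation categories are drawn from one shared model for both sets.
#'
#' @param states a \code{StateMatrix} (typically from
#'   \code{\link{gen_state_matrix}}).
#' @param truth the matching \code{PlantedTruth}.
#' @param enriched_patterns indices (into the planted patterns) that
#'   risk variants are enriched in.
#' @param enrichment_fold fold enrichment (>= 1); 1 means null-like.
#' @param n_risk,n_null set sizes (risk includes proxies).
#' @param ld_cluster_size lead + proxies per LD cluster.
#' @param seed integer seed.
#' @return list of two \code{VariantSet}s, \code{risk} and \code{null}.
#' @export
gen_variants <- function(states, truth, enriched_patterns = 2L,
                         enrichment_fold = 10, n_risk = 200,
                         n_null = 1000, ld_cluster_size = 4,
                         seed = 1) {
  stopifnot(enrichment_fold >= 1, n_risk >= 1, n_null >= 1,
            ld_cluster_size >= 1)
  set.seed(seed)
  L <- nrow(states$states)
  lab <- truth$position_labels
  enriched_win <- lab %in% enriched_patterns
  if (enrichment_fold > 1 && sum(enriched_win) == 0L)
    stop("no windows carry the requested enriched patterns")
  w_risk <- ifelse(enriched_win, enrichment_fold, 1)
  n_lead <- ceiling(n_risk / ld_cluster_size)
  lead_win <- sample.int(L, n_lead, replace = TRUE,
                         prob = w_risk / sum(w_risk))
  risk_win <- rep(lead_win, each = ld_cluster_size)[seq_len(n_risk)]
  risk_cluster <- rep(seq_len(n_lead), each = ld_cluster_size)[
    seq_len(n_risk)]
  null_win <- sample.int(L, n_null, replace = TRUE)

  mk <- function(win, cluster, label, prefix) {
    n <- length(win)
    offset <- sample.int(states$window_size, n, replace = TRUE) - 1L
    data.frame(
      variant_id = paste0(prefix, seq_len(n)),
      chrom = states$windows$chrom[win],
      pos = states$windows$start[win] + offset,
      ld_cluster = cluster,
      maf = .draw_maf(n),
      annotation = sample(.annotation_vocab, n, replace = TRUE,
                          prob = .annotation_probs),
      label = label, stringsAsFactors = FALSE)
  }
  risk_df <- mk(risk_win, paste0("ld", risk_cluster), "risk", "rs_r")
  null_df <- mk(null_win, paste0("ld_n", seq_len(n_null)), "null",
                "rs_n")
  list(risk = variant_set(risk_df,
                          states$states[risk_win, , drop = FALSE]),
       null = variant_set(null_df,
                          states$states[null_win, , drop = FALSE]))
}

#' Generate a block-LD SNP panel for power simulation
#'
#' SNPs are laid out in consecutive blocks; within a block all pairwise
#' correlations equal \code{r_within}, across blocks zero. Blocks are
#' spaced 2 Mb apart with 100 bp within-block spacing, so a 500 kb
#' indirect-association window always spans a whole block and never
#' reaches the next one.
#'
#' @param n_snps panel size.
#' @param block_size SNPs per block.
#' @param r_within within-block correlation, |r| <= 1.
#' @param seed integer seed (fixes the panel's prediction scores, drawn
#'   uniform so ranking is exchangeable).
#' @return object of class \code{SnpPanel}: data frame fields
#'   \code{snp_id}, \code{pos}, \code{block}, \code{score}, plus
#'   \code{r_within} and the 500 kb \code{ld_radius}.
#' @export
gen_ld_panel <- function(n_snps = 2000, block_size = 10,
                         r_within = 0.8, seed = 1) {
  stopifnot(n_snps >= 1, block_size >= 1, abs(r_within) <= 1)
  set.seed(seed)
  block <- rep(seq_len(ceiling(n_snps / block_size)),
               each = block_size)[seq_len(n_snps)]
  within <- stats::ave(seq_len(n_snps), block, FUN = seq_along)
  pos <- (block - 1L) * 2e6 + (within - 1L) * 100
  structure(list(snps = data.frame(snp_id = paste0("snp", seq_len(n_snps)),
                                   pos = pos, block = block,
                                   score = stats::runif(n_snps)),
                 r_within = r_within, ld_radius = 5e5),
            class = "SnpPanel")
}

#' Write a full synthetic dataset to a directory
#'
#' Emits \code{states.tsv}, \code{risk.tsv}, \code{null.tsv},
#' \code{clusters.tsv} and \code{truth.json} in the package's exchange
#' formats.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param preset \code{"default"} (planted enrichment),
#'   \code{"tiny"} (quick smoke-test sizes) or \code{"null"}
#'   (fold 1, no enrichment).
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_dataset <- function(dir, seed = 1, preset = "default") {
  preset <- match.arg(preset, c("default", "tiny", "null"))
  dims <- switch(preset,
    default = list(N = 12, L = 2000, fold = 10, n_risk = 200,
                   n_null = 1000),
    tiny = list(N = 6, L = 200, fold = 10, n_risk = 40, n_null = 200),
    null = list(N = 12, L = 2000, fold = 1, n_risk = 200,
                n_null = 1000))
  sim <- gen_state_matrix(N = dims$N, L = dims$L, seed = seed)
  vs <- gen_variants(sim$states, sim$truth, enrichment_fold = dims$fold,
                     n_risk = dims$n_risk, n_null = dims$n_null,
                     seed = seed + 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    states = file.path(dir, "states.tsv"),
    risk = file.path(dir, "risk.tsv"),
    null = file.path(dir, "null.tsv"),
    clusters = file.path(dir, "clusters.tsv"),
    truth = file.path(dir, "truth.json"))
  write_state_matrix(sim$states, paths$states)
  write_variants(vs$risk, paths$risk)
  write_variants(vs$null, paths$null)
  ## a simple two-way epigenome clustering consistent with the planted
  ## half-split pattern
  half <- floor(dims$N / 2)
  cl <- cluster_definition(stats::setNames(
    c(rep(1L, half), rep(2L, dims$N - half)),
    sim$states$epigenome_ids))
  write_clusters(cl, paths$clusters)
  truth_list <- list(patterns = sim$truth$patterns,
                     position_labels = sim$truth$position_labels,
                     pattern_freqs = sim$truth$pattern_freqs,
                     concentration = sim$truth$concentration,
                     seed = sim$truth$seed)
  writeLines(.to_json(truth_list), paths$truth)
  invisible(paths)
}

## Minimal JSON writer for the truth file (numbers, vectors, named and
## unnamed lists) to keep jsonlite out of the package's hard imports.
.to_json <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) {
      paste0("{", paste(sprintf('"%s":%s', names(x),
                                vapply(x, .to_json, character(1))),
                        collapse = ","), "}")
    } else {
      paste0("[", paste(vapply(x, .to_json, character(1)),
                        collapse = ","), "]")
    }
  } else if (is.character(x)) {
    if (length(x) == 1L) sprintf('"%s"', x) else
      paste0("[", paste(sprintf('"%s"', x), collapse = ","), "]")
  } else {
    v <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
    if (length(v) == 1L) v else
      paste0("[", paste(v, collapse = ","), "]")
  }
}
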