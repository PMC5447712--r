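# Shared fixtures, built once per test run. The desk-scale fitting
# configuration (pattern capacity 12, K = 5, 25 exploration + up to 35
# maximization sweeps, whole matrix as training data) is the one
# documented in the methods vignette.

.fixture_env <- new.env(parent = emptyenv())

fit_desk <- function(states, C = 12, seed = 1) {
  fit_csp_model(states, C = C, K = 5, n_iter = 60, anneal_iters = 25,
                train_fraction = 1, seed = seed)
}

## default synthetic instance + fitted model, reused across test files
default_fixture <- function() {
  if (!exists("default", envir = .fixture_env)) {
    sim <- gen_state_matrix(seed = 1)
    fit <- fit_desk(sim$states, seed = 1)
    clusters <- cluster_definition(stats::setNames(
      c(rep(1L, 6), rep(2L, 6)), sim$states$epigenome_ids))
    assign("default", list(sim = sim, fit = fit, clusters = clusters),
           envir = .fixture_env)
  }
  get("default", envir = .fixture_env)
}

two_cluster_def <- function(N = 12) {
  half <- floor(N / 2)
  cluster_definition(stats::setNames(
    c(rep(1L, half), rep(2L, N - half)), paste0("E", seq_len(N))))
}

## adjusted Rand index between two labelings (closed form from the
## pair-counting contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
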