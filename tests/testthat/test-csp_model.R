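test_that("per-position log marginal matches direct formula evaluation", {
  ## frozen value computed with oracle_posmarg (explicit Gamma products)
  expect_equal(position_log_marginal(c(1, 1, 2, 3, 3),
                                     c(1, 1, 1, 2, 2),
                                     c(0.5, 0.5, 0.5)),
               -5.16478597392351, tolerance = 1e-12)
  ## one draw under a symmetric prior is uniform over states
  expect_equal(position_log_marginal(2L, 1L, rep(1, 4)), log(1 / 4))
  ## an empty group contributes exactly zero
  part_dense <- c(1L, 1L, 2L)
  part_sparse <- c(1L, 1L, 3L)   # group 2 empty
  x <- c(1L, 2L, 2L)
  a <- c(0.3, 0.9)
  expect_equal(position_log_marginal(x, part_sparse, a),
               position_log_marginal(x, part_dense, a))
  expect_error(position_log_marginal(x, part_dense, c(0, 1)),
               "positive")
})

test_that("log marginal and partition prior agree with oracles on random instances", {
  set.seed(31)
  for (i in 1:60) {
    N <- sample(2:8, 1); S <- sample(2:4, 1); K <- sample(1:3, 1)
    x <- sample.int(S, N, replace = TRUE)
    part <- rand_partition(N, K)
    alpha <- stats::runif(S, 0.2, 3)
    expect_equal(position_log_marginal(x, part, alpha),
                 oracle_posmarg(x, part, alpha), tolerance = 1e-10)
    expect_equal(partition_log_prior(part, K),
                 oracle_partition_prior(part, K), tolerance = 1e-10)
    ## group-label permutation invariance
    perm <- sample.int(K)
    expect_equal(position_log_marginal(x, perm[part], alpha),
                 position_log_marginal(x, part, alpha),
                 tolerance = 1e-10)
    expect_equal(partition_log_prior(perm[part], K),
                 partition_log_prior(part, K), tolerance = 1e-10)
  }
})

test_that("partition prior closed forms hold", {
  expect_equal(partition_log_prior(1L, K = 2), log(1 / 2))
  for (K in 2:6) expect_equal(partition_log_prior(1L, K = K),
                              log(1 / K))
  expect_equal(partition_log_prior(rep(1L, 4), K = 2), log(0.2))
})

test_that("joint model score reduces, permutes and matches the oracle", {
  alpha <- c(1.2, 0.8)
  cat2 <- csp_catalog(list(c(1L, 1L), c(1L, 2L)), counts = c(1, 1),
                      K = 2, alpha = alpha)
  X <- matrix(c(1L, 2L, 2L, 2L), 2, 2)
  M <- c(1L, 2L)
  expect_equal(model_log_posterior(cat2, M, X, alpha),
               oracle_model_score(cat2$patterns, M, X, alpha,
                                  C = 2, K = 2),
               tolerance = 1e-12)
  ## empty data: prior-only score
  cat1 <- csp_catalog(list(c(1L, 2L)), counts = 0, K = 2,
                      alpha = alpha)
  expect_equal(model_log_posterior(cat1, integer(0),
                                   matrix(integer(0), 0, 2), alpha),
               partition_log_prior(c(1L, 2L), K = 2))
  ## relabeling groups in every pattern leaves the score unchanged
  cat2b <- csp_catalog(list(c(2L, 2L), c(2L, 1L)), counts = c(1, 1),
                       K = 2, alpha = alpha)
  expect_equal(model_log_posterior(cat2b, M, X, alpha),
               model_log_posterior(cat2, M, X, alpha))
  expect_error(model_log_posterior(cat2, c(1L, 3L), X, alpha),
               "outside catalog range")
  ## printed frequency-term variant differs by the documented shift
  expect_equal(model_log_posterior(cat2, M, X, alpha,
                                   eq4_as_printed = TRUE),
               oracle_model_score(cat2$patterns, M, X, alpha,
                                  C = 2, K = 2, shift = 2),
               tolerance = 1e-12)
})

test_that("a constant matrix yields one constitutive pattern", {
  sm <- state_matrix(matrix(2L, 60, 5), n_states = 3)
  fit <- fit_csp_model(sm, C = 4, K = 3, n_iter = 30,
                       anneal_iters = 10, train_fraction = 1,
                       seed = 1)
  expect_identical(length(fit$catalog$patterns), 1L)
  expect_identical(length(unique(fit$catalog$patterns[[1]])), 1L)
  expect_true(all(fit$assignment == 1L))
  expect_equal(fit$catalog$freqs, 1)
})

test_that("two planted partitions are recovered almost perfectly", {
  parts <- list(rep(1L, 12), c(rep(1L, 6), rep(2L, 6)))
  sim <- gen_state_matrix(N = 12, L = 500, S = 6,
                          true_patterns = parts,
                          pattern_freqs = c(0.7, 0.3), seed = 8)
  fit <- fit_desk(sim$states, C = 8, seed = 2)
  expect_identical(length(fit$catalog$patterns), 2L)
  expect_gte(ari(fit$assignment, sim$truth$position_labels), 0.95)
})

test_that("post-exploration sweeps never decrease the model score", {
  sim <- gen_state_matrix(N = 8, L = 300, S = 5, seed = 4,
                          true_patterns = default_true_patterns(8))
  fit <- fit_csp_model(sim$states, C = 8, K = 4, n_iter = 40,
                       anneal_iters = 15, train_fraction = 1,
                       seed = 3)
  tr <- fit$log_posterior
  expect_gte(length(tr), 16)
  expect_true(all(diff(tr[15:length(tr)]) >= -1e-8))
  expect_true(fit$converged)
})

test_that("fitting is reproducible under a fixed seed", {
  sim <- gen_state_matrix(N = 8, L = 200, S = 4, seed = 9,
                          true_patterns = default_true_patterns(8))
  f1 <- fit_csp_model(sim$states, C = 6, K = 3, n_iter = 40,
                      anneal_iters = 15, train_fraction = 0.8,
                      seed = 11)
  f2 <- fit_csp_model(sim$states, C = 6, K = 3, n_iter = 40,
                      anneal_iters = 15, train_fraction = 0.8,
                      seed = 11)
  expect_identical(f1$assignment, f2$assignment)
  expect_equal(f1$catalog$patterns, f2$catalog$patterns)
  expect_equal(f1$log_posterior, f2$log_posterior)
})

test_that("train-subsample fitting assigns held-out positions sensibly", {
  sim <- gen_state_matrix(N = 12, L = 1000, S = 6, seed = 6)
  fit <- fit_csp_model(sim$states, C = 12, K = 5, n_iter = 60,
                       anneal_iters = 25, train_fraction = 0.5,
                       seed = 5)
  expect_identical(length(fit$assignment), 1000L)
  expect_gte(ari(fit$assignment, sim$truth$position_labels), 0.9)
  expect_error(fit_csp_model(sim$states, train_fraction = 1e-5),
               "fewer than one position")
})

test_that("position assignment maximizes frequency-weighted likelihood", {
  alpha <- c(1, 1, 1)
  ## single-pattern catalog: everything goes to it
  cat1 <- csp_catalog(list(c(1L, 1L, 2L)), counts = 5, K = 2,
                      alpha = alpha)
  X <- matrix(sample.int(3, 15, replace = TRUE), 5, 3)
  expect_true(all(assign_positions(cat1, X) == 1L))
  ## three-pattern toy: index matches direct enumeration
  cat3 <- csp_catalog(list(c(1L, 1L, 1L), c(1L, 1L, 2L),
                           c(1L, 2L, 3L)),
                      counts = c(6, 3, 1), K = 3, alpha = alpha)
  x <- c(1L, 1L, 3L)
  direct <- vapply(1:3, function(c)
    log(cat3$freqs[c]) +
      oracle_posmarg(x, cat3$patterns[[c]], alpha), numeric(1))
  expect_identical(assign_positions(cat3, matrix(x, 1, 3)),
                   which.max(direct))
  empty <- csp_catalog(list(c(1L, 1L, 1L)), counts = 0, K = 1,
                       alpha = alpha)
  expect_error(assign_positions(empty, X), "non-empty")
})

test_that("excess capacity prunes back to the planted pattern count", {
  ## Occam behaviour: C well above the 4 planted patterns
  sim <- gen_state_matrix(seed = 21)
  fit <- fit_desk(sim$states, C = 12, seed = 7)
  n_planted <- length(sim$truth$patterns)
  expect_lte(length(fit$catalog$patterns), n_planted + 2)
  expect_gte(length(fit$catalog$patterns), n_planted - 1)
})
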