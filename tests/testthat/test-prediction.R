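test_that("CSP likelihood features evaluate every pattern", {
  alpha <- c(1, 0.5, 1.5)
  catalog <- csp_catalog(list(c(1L, 1L, 1L), c(1L, 2L, 2L),
                              c(1L, 2L, 2L)),
                         counts = c(3, 2, 1), K = 2, alpha = alpha)
  X <- matrix(sample.int(3, 12, replace = TRUE), 4, 3)
  f <- csp_features(X, catalog)
  expect_identical(dim(f), c(4L, 3L))
  ## duplicate patterns give identical columns
  expect_equal(f[, 2], f[, 3])
  for (j in 1:4) for (c in 1:3)
    expect_equal(unname(f[j, c]),
                 oracle_posmarg(X[j, ], catalog$patterns[[c]], alpha),
                 tolerance = 1e-10)
})

test_that("component maps are orthonormal, idempotent and rank-capped", {
  set.seed(12)
  cl <- two_cluster_def(12)
  X <- matrix(sample.int(6, 40 * 12, replace = TRUE), 40, 12)
  expect_warning(fe <- enrichment_features(X, cl, S = 6,
                                           n_components = 48),
                 "rank")
  k <- ncol(fe$features)
  expect_lt(k, 48)
  expect_equal(unname(crossprod(fe$map$rotation)), diag(k),
               tolerance = 1e-8)
  ## projecting a training row reproduces its training features
  fe2 <- enrichment_features(X[1:5, , drop = FALSE], cl, S = 6,
                             map = fe$map)
  expect_equal(fe2$features, fe$features[1:5, , drop = FALSE])
  ## component variances non-increasing and matching eigen analysis
  z <- variant_zscores(X, cl, S = 6, transformed = TRUE)
  ev <- eigen(stats::cov(z), symmetric = TRUE)$values
  expect_equal(fe$map$sdev^2, ev[seq_len(k)], tolerance = 1e-8)
  expect_true(all(diff(fe$map$sdev) <= 1e-12))
})

test_that("all-states indicators one-hot encode every epigenome", {
  X <- matrix(sample.int(4, 6 * 5, replace = TRUE), 6, 5)
  ind <- allstate_indicators(X, S = 4)
  expect_identical(dim(ind), c(6L, 20L))
  expect_true(all(rowSums(ind) == 5))
  for (j in 1:6) for (i in 1:5)
    expect_equal(ind[j, (i - 1) * 4 + X[j, i]], 1)
})

test_that("logistic training degrades gracefully and recovers truth", {
  set.seed(4)
  ## all-zero features: constant scores
  m0 <- train_glm(matrix(0, 30, 3), rep(c(0, 1), 15))
  expect_equal(length(unique(round(
    predict_scores(m0, matrix(0, 10, 3)), 12))), 1L)
  ## perfectly separating feature: ridge fallback keeps ordering
  x <- matrix(c(sort(stats::runif(20))), 20, 1)
  y <- rep(c(0, 1), each = 10)
  m1 <- train_glm(x, y)
  sc <- predict_scores(m1, x)
  expect_true(all(diff(sc) > -1e-12))
  ## coefficient recovery on simulated logistic data
  n <- 2000
  X <- matrix(stats::rnorm(n * 2), n, 2)
  eta <- -0.5 + 1 * X[, 1] - 2 * X[, 2]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  m2 <- train_glm(X, y)
  fit_ref <- stats::glm(y ~ X, family = stats::binomial())
  se <- summary(fit_ref)$coefficients[, 2]
  expect_true(all(abs(m2$coef - c(-0.5, 1, -2)) < 3 * se))
})

test_that("average precision equals the exhaustive computation", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  ## four-point toy: ranks give precisions 1, 2/3 at the positives
  expect_equal(pr_auc(c(0.9, 0.1, 0.8, 0.5), c(1, 0, 0, 1)),
               mean(c(1 / 1, 2 / 3)))
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    sc <- stats::runif(n)
    if (i %% 3 == 0) sc <- round(sc, 1)  # exercise ties
    y <- stats::rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(pr_auc(sc, y), oracle_ap(sc, y))
  }
  ## null baseline: random scores give roughly the prevalence
  set.seed(7)
  y <- stats::rbinom(4000, 1, 0.2)
  expect_equal(pr_auc(stats::runif(4000), y), 0.2, tolerance = 0.05)
  expect_error(pr_auc(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("single-cell-type selection finds the informative epigenome", {
  set.seed(10)
  n <- 200
  y <- rep(c(1L, 0L), each = n / 2)
  X <- matrix(sample.int(4, n * 6, replace = TRUE), n, 6)
  X[, 4] <- ifelse(y == 1, 1L, 3L)   # epigenome 4 separates perfectly
  expect_identical(select_best_celltype(X, y, S = 4), 4L)
  tr <- seq(1, 200, by = 2); te <- seq(2, 200, by = 2)
  sc <- single_celltype_scores(X[tr, 4], y[tr], X[te, 4], S = 4)
  expect_equal(pr_auc(sc, y[te]), 1)
  ## unseen level at test time collapses to the reference level
  sc2 <- single_celltype_scores(rep(c(1L, 2L), 10),
                                rep(c(0, 1), 10), c(1L, 2L, 4L),
                                S = 4)
  expect_equal(sc2[3], sc2[1])
})

test_that("trait evaluation is reproducible, leak-free at the null, and honors the size rule", {
  fx <- default_fixture()
  vs <- gen_variants(fx$sim$states, fx$sim$truth,
                     enrichment_fold = 1, n_risk = 60, n_null = 300,
                     seed = 12)
  ## null trait: labels carry no signal, AUC ~ prevalence
  suppressWarnings(
    ev <- evaluate_trait(vs$risk, vs$null, "csp+enrichment",
                         fx$fit$catalog, fx$clusters, S = 6,
                         n_repeats = 6, n_components = 6, seed = 3))
  prevalence <- 30 / (30 + 150)
  expect_lt(abs(ev$mean_auc - prevalence), 0.15)
  suppressWarnings(
    ev2 <- evaluate_trait(vs$risk, vs$null, "csp+enrichment",
                          fx$fit$catalog, fx$clusters, S = 6,
                          n_repeats = 6, n_components = 6, seed = 3))
  expect_identical(ev$aucs, ev2$aucs)
  ## too few risk variants: repeats skipped with a warning
  tiny <- vs$risk[1:4]
  expect_warning(
    ev3 <- evaluate_trait(tiny, vs$null, "all-states",
                          fx$fit$catalog, fx$clusters, S = 6,
                          n_repeats = 1, n_components = 6, seed = 1),
    "skipped")
  expect_identical(ev3$n_repeats, 0L)
  expect_true(is.na(ev3$mean_auc))
})

test_that("matched nulls reproduce the risk maf-annotation histogram", {
  fx <- default_fixture()
  vs <- gen_variants(fx$sim$states, fx$sim$truth,
                     enrichment_fold = 1, n_risk = 80, n_null = 800,
                     seed = 20)
  hist_of <- function(v, w = 0.05) {
    table(paste(pmin(floor(v$variants$maf / w), 9),
                v$variants$annotation))
  }
  ## pool that is a copy of the risk set: exact histogram
  m1 <- match_nulls(vs$risk, vs$risk, seed = 1)
  expect_equal(hist_of(m1), hist_of(vs$risk))
  ## large shared-model pool: exact histogram too
  m2 <- match_nulls(vs$risk, vs$null, seed = 2)
  expect_equal(hist_of(m2), hist_of(vs$risk))
  expect_identical(length(m2), length(vs$risk))
  ## pool lacking a category triggers the nearest-bin fallback
  keep <- vs$null$variants$annotation != "regulatory"
  pool2 <- vs$null[keep]
  if (any(vs$risk$variants$annotation == "regulatory"))
    expect_warning(match_nulls(vs$risk, pool2, seed = 3), "fallback")
})
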