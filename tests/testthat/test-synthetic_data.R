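test_that("generators are pure functions of their seed", {
  a <- gen_state_matrix(N = 6, L = 100, S = 4, seed = 3,
                        true_patterns = default_true_patterns(6))
  b <- gen_state_matrix(N = 6, L = 100, S = 4, seed = 3,
                        true_patterns = default_true_patterns(6))
  d <- gen_state_matrix(N = 6, L = 100, S = 4, seed = 4,
                        true_patterns = default_true_patterns(6))
  expect_identical(a$states$states, b$states$states)
  expect_identical(a$truth$position_labels, b$truth$position_labels)
  expect_false(identical(a$states$states, d$states$states))
  va <- gen_variants(a$states, a$truth, enrichment_fold = 1, seed = 9,
                     n_risk = 30, n_null = 50)
  vb <- gen_variants(a$states, a$truth, enrichment_fold = 1, seed = 9,
                     n_risk = 30, n_null = 50)
  expect_identical(va$risk$variants, vb$risk$variants)
  pa <- gen_ld_panel(seed = 2); pb <- gen_ld_panel(seed = 2)
  expect_identical(pa$snps, pb$snps)
})

test_that("planted pattern frequencies are honored", {
  sim <- gen_state_matrix(N = 12, L = 4000, S = 6, seed = 7)
  freq <- tabulate(sim$truth$position_labels, 4) / 4000
  se <- sqrt(sim$truth$pattern_freqs * (1 - sim$truth$pattern_freqs) /
               4000)
  expect_true(all(abs(freq - sim$truth$pattern_freqs) < 4 * se))
})

test_that("low concentration produces near-pure group emissions", {
  sim <- gen_state_matrix(N = 12, L = 300, S = 6,
                          true_patterns = list(rep(1L, 12)),
                          pattern_freqs = 1, concentration = 0.001,
                          seed = 2)
  n_const <- sum(apply(sim$states$states, 1,
                       function(r) length(unique(r)) == 1L))
  expect_gt(n_const / 300, 0.9)
  ## purity decreases as concentration grows
  sim2 <- gen_state_matrix(N = 12, L = 300, S = 6,
                           true_patterns = list(rep(1L, 12)),
                           pattern_freqs = 1, concentration = 1,
                           seed = 2)
  n_const2 <- sum(apply(sim2$states$states, 1,
                        function(r) length(unique(r)) == 1L))
  expect_lt(n_const2, n_const)
})

test_that("group state distributions are separated within patterns", {
  sim <- gen_state_matrix(N = 12, L = 400, S = 6, seed = 13)
  lab <- sim$truth$position_labels
  part <- sim$truth$patterns[[2]]
  idx <- which(lab == 2)
  ## modal states of the two groups differ at nearly every position
  g1 <- which(part == 1); g2 <- which(part == 2)
  mode_of <- function(v) as.integer(names(which.max(table(v))))
  same <- vapply(idx, function(j)
    mode_of(sim$states$states[j, g1]) ==
      mode_of(sim$states$states[j, g2]), logical(1))
  expect_lt(mean(same), 0.05)
})

test_that("risk variants land on enriched patterns at the planted fold", {
  sim <- gen_state_matrix(N = 12, L = 2000, S = 6, seed = 1)
  vs <- gen_variants(sim$states, sim$truth, enriched_patterns = 2L,
                     enrichment_fold = 10, n_risk = 400,
                     n_null = 2000, ld_cluster_size = 1, seed = 5)
  win_of <- function(v) v$variants$pos %/% 200 + 1
  lab <- sim$truth$position_labels
  p_risk <- mean(lab[win_of(vs$risk)] == 2)
  p_null <- mean(lab[win_of(vs$null)] == 2)
  p_bg <- mean(lab == 2)
  w <- p_bg * 10 / (p_bg * 10 + (1 - p_bg))  # expected risk rate
  expect_lt(abs(p_risk - w), 0.07)
  expect_lt(abs(p_null - p_bg), 0.04)
  ## fold 1 is indistinguishable from the background
  v0 <- gen_variants(sim$states, sim$truth, enrichment_fold = 1,
                     n_risk = 400, n_null = 10, ld_cluster_size = 1,
                     seed = 6)
  expect_lt(abs(mean(lab[win_of(v0$risk)] == 2) - p_bg), 0.05)
})

test_that("LD clusters share their lead variant's window", {
  sim <- gen_state_matrix(N = 6, L = 300, S = 4, seed = 3,
                          true_patterns = default_true_patterns(6))
  vs <- gen_variants(sim$states, sim$truth, enrichment_fold = 1,
                     n_risk = 40, n_null = 10, ld_cluster_size = 5,
                     seed = 4)
  win <- vs$risk$variants$pos %/% 200
  expect_true(all(tapply(win, vs$risk$variants$ld_cluster,
                         function(w) length(unique(w))) == 1))
  expect_true(all(table(vs$risk$variants$ld_cluster) <= 5))
  expect_true(all(vs$risk$variants$maf >= 0 &
                    vs$risk$variants$maf <= 0.5))
})

test_that("LD panels propagate statistics as r*t + sqrt(1-r^2)*z", {
  panel <- gen_ld_panel(n_snps = 60, block_size = 2, r_within = 0.6,
                        seed = 2)
  causals <- seq(1L, 59L, by = 2L)
  ## replay the generator's null draw to reconstruct the formula
  set.seed(3); st <- simulate_stats(panel, causals)
  set.seed(3); z <- stats::rnorm(60)
  proxies <- causals + 1L
  expect_equal(st[proxies],
               0.6 * st[causals] + sqrt(1 - 0.36) * z[proxies])
  ## residual noise share shrinks as r grows
  panel9 <- gen_ld_panel(n_snps = 60, block_size = 2, r_within = 0.9,
                         seed = 2)
  set.seed(3); st9 <- simulate_stats(panel9, causals)
  expect_equal(st9[proxies],
               0.9 * st9[causals] + sqrt(1 - 0.81) * z[proxies])
  ## blocks are packed inside and spaced beyond the LD radius
  expect_true(min(diff(panel$snps$pos[panel$snps$block == 1])) <
                panel$ld_radius)
  b2 <- which(panel$snps$block == 2)[1]
  expect_gt(panel$snps$pos[b2] - panel$snps$pos[1], panel$ld_radius)
})

test_that("a written dataset reloads into consistent objects", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(dir, seed = 4, preset = "tiny")
  sm <- read_state_matrix(paths$states, n_states = 6)
  expect_identical(dim(sm$states), c(200L, 6L))
  risk <- read_variants(paths$risk, sm)
  null <- read_variants(paths$null, sm)
  expect_identical(length(risk), 40L)
  expect_identical(length(null), 200L)
  cl <- read_clusters(paths$clusters)
  expect_identical(names(cl$cluster_of), sm$epigenome_ids)
  expect_true(file.exists(paths$truth))
  truth <- readLines(paths$truth)
  expect_match(truth, "position_labels", all = FALSE)
})
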