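# Generative, distributional and target-focused metrics against independent
# oracles.

test_that("validity, uniqueness and novelty follow their definitions", {
  expect_equal(generative_metrics(c("CCO", "C1CC"))[["validity"]], 50)
  gm <- generative_metrics(c("CCO", "OCC"))
  expect_equal(gm[["validity"]], 100)
  expect_equal(gm[["uniqueness"]], 50)
  gm2 <- generative_metrics(c("CCO", "c1ccccc1"), training_set = c("CCO", "c1ccccc1"))
  expect_equal(gm2[["novelty"]], 0)
  gm3 <- generative_metrics(c("CCO", "c1ccccc1"), training_set = "CCO")
  expect_equal(gm3[["novelty"]], 50)
  expect_error(generative_metrics(character(0)), "empty")
})

test_that("KS statistic matches ECDF enumeration", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(10, 11)), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  # independent ECDF oracle on random data
  set.seed(6)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  grid <- sort(c(a, b))
  oracle <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                           numeric(1))))
  expect_equal(ks_statistic(a, b), oracle)
  expect_error(ks_statistic(numeric(0), a), "empty")
})

test_that("KL divergence is nonnegative and matches the two-bin closed form", {
  a <- c(rep(0.25, 5), rep(0.75, 5))     # p = (0.5, 0.5)
  b <- c(rep(0.25, 9), rep(0.75, 1))     # q = (0.9, 0.1)
  expect_equal(kl_divergence(a, b, bins = 2),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-6)
  expect_lt(kl_divergence(a, a), 1e-8)
  set.seed(7)
  for (k in 1:10) {
    x <- rnorm(50); y <- rnorm(50, sample(0:2, 1))
    expect_gte(kl_divergence(x, y), 0)
  }
})

test_that("Frechet distance has metric-like behavior", {
  set.seed(11)
  E <- matrix(rnorm(300), 100, 3)
  expect_lt(frechet_distance(E, E), 1e-10)
  F2 <- matrix(rnorm(300, 1), 100, 3)
  expect_equal(frechet_distance(E, F2), frechet_distance(F2, E),
               tolerance = 1e-12)
  expect_gte(frechet_distance(E, F2), 0)
  # permuting rows (set semantics) leaves the value unchanged
  expect_equal(frechet_distance(E[sample(100), ], F2), frechet_distance(E, F2))
  # 1-D gaussians: closed form (mu diff)^2 + (sd diff)^2 ~ 1
  g1 <- matrix(rnorm(6000, 0, 1), ncol = 1)
  g2 <- matrix(rnorm(6000, 1, 1), ncol = 1)
  expect_equal(frechet_distance(g1, g2), 1, tolerance = 0.15)
  expect_error(frechet_distance(E[1, , drop = FALSE], F2), "at least 2")
})

test_that("subsampled comparison equals a transparent loop", {
  set.seed(4)
  A <- matrix(rnorm(120), 60, 2); B <- matrix(rnorm(120, 0.3), 60, 2)
  r <- subsampled_comparison(A, B, frechet_distance, subsample_size = 30,
                             n_reps = 5, seed = 77)
  # independent loop oracle with the same RNG protocol
  set.seed(77)
  vals <- vapply(1:5, function(k) {
    ia <- sample.int(60, 30); ib <- sample.int(60, 30)
    frechet_distance(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
  }, numeric(1))
  expect_equal(as.numeric(r), c(mean(vals), sd(vals)))
  # identical sets at full size: sd is 0
  r2 <- subsampled_comparison(A, A, frechet_distance, subsample_size = 60,
                              n_reps = 3, seed = 1)
  expect_equal(unname(r2[["sd"]]), 0)
  # fixed seed reruns identically
  r3 <- subsampled_comparison(A, B, frechet_distance, 30, 5, seed = 77)
  expect_identical(r, r3)
  expect_error(subsampled_comparison(A, B, frechet_distance, 100), "exceeds")
})

test_that("rediscovery metrics equal exhaustive recomputation", {
  train <- c("Clc1ccccc1", "Oc1ccncc1", "CCOC(=O)c1ccsc1")
  holdout <- c("Nc1ccc2ccccc2c1")
  gen <- c("Clc1ccccc1", "Clc1ccccc1C", "CCCCO", "Nc1ccc2ccccc2c1", "c1ccsc1")
  tm <- target_metrics(gen, train, holdout, threshold = 0.6)
  # brute-force oracle
  gfp <- lapply(gen, ecfp4); tfp <- lapply(train, ecfp4)
  S <- outer(seq_along(train), seq_along(gen),
             Vectorize(function(i, j) tanimoto(tfp[[i]], gfp[[j]])))
  expect_equal(tm$rr_t, 100 * mean(apply(S, 1, max) >= 0.6))
  expect_equal(tm$snn, mean(apply(S, 2, max)))
  gs <- unique(sapply(gen, murcko_scaffold))
  expect_equal(tm$rs_t, 100 * mean(unique(sapply(train, murcko_scaffold)) %in% gs))
  expect_equal(tm$rs_h, 100 * mean(unique(sapply(holdout, murcko_scaffold)) %in% gs))
  pair <- combn(length(gen), 2)
  expect_equal(tm$intdiv,
               1 - mean(apply(pair, 2, function(ij) tanimoto(gfp[[ij[1]]], gfp[[ij[2]]]))))

  # trivial identities
  tid <- target_metrics(train, train)
  expect_equal(tid$rr_t, 100); expect_equal(tid$rs_t, 100); expect_equal(tid$snn, 1)
  expect_equal(target_metrics(rep("c1ccccc1", 4), "c1ccccc1")$intdiv, 0)
  expect_error(target_metrics(gen, character(0)), "empty reference")
})

test_that("recovery metrics are monotone and duplicate-invariant", {
  train <- c("Clc1ccccc1", "Oc1ccncc1", "CCOC(=O)c1ccsc1")
  gen1 <- c("Clc1ccccc1")
  gen2 <- c(gen1, "Oc1ccncc1")
  m1 <- target_metrics(gen1, train)
  m2 <- target_metrics(gen2, train)
  expect_gte(m2$rr_t, m1$rr_t)
  expect_gte(m2$rs_t, m1$rs_t)
  # duplicates do not change RR_T
  m3 <- target_metrics(c(gen2, gen2), train)
  expect_equal(m3$rr_t, m2$rr_t)
  expect_equal(m3$rs_t, m2$rs_t)
  # input order invariance
  m4 <- target_metrics(rev(gen2), train)
  expect_equal(m4$rr_t, m2$rr_t)
  expect_equal(m4$snn, m2$snn)
})
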