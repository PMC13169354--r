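# Leakage-safe splitting: scaffold grouping, sphere exclusion, audit.

test_that("scaffold groups are never divided across sides", {
  scaf <- c("A", "A", "B", "B", "C", "C")
  sp <- scaffold_split(scaf, holdout_fraction = 0.5, seed = 1)
  for (s in unique(scaf)) {
    idx <- which(scaf == s)
    expect_true(all(idx %in% sp$train) || all(idx %in% sp$holdout), label = s)
  }
  expect_setequal(c(sp$train, sp$holdout), 1:6)
  # two scaffolds at fraction 0.5: one group per side
  sp2 <- scaffold_split(c("A", "A", "B", "B"), 0.5, seed = 2)
  expect_length(sp2$holdout, 2)
  expect_error(scaffold_split(rep("A", 5), 0.5), "unsplittable")
})

test_that("greedy size matching tracks the requested fraction", {
  set.seed(9)
  scaf <- rep(paste0("S", 1:10), times = sample(1:6, 10, replace = TRUE))
  n <- length(scaf)
  for (f in c(0.2, 0.35)) {
    sp <- scaffold_split(scaf, f, seed = 3)
    achieved <- length(sp$holdout) / n
    # achieved fraction within one largest-group granularity of the target
    expect_lte(abs(achieved - f), 6 / n + 1e-9)
  }
})

test_that("sphere exclusion removes at the inclusive 0.6 boundary", {
  # synthetic fingerprints with exact similarities: |A∩B|/|A∪B|
  train <- list(structure(1:10, n_bits = 2048L))
  h_exact <- structure(1:6, n_bits = 2048L)        # 6/10  = 0.6  -> removed
  h_below <- structure(c(1:5, 11:14), n_bits = 2048L)  # 5/14 < 0.6 -> kept
  h_ident <- structure(1:10, n_bits = 2048L)       # 1.0 -> removed
  se <- sphere_exclusion(list(h_exact, h_below, h_ident), train)
  expect_identical(se$removed, c(1L, 3L))
  expect_identical(se$keep, 2L)
  expect_equal(se$max_sim, c(0.6, 5 / 14, 1.0))
  # empty train set leaves the holdout unchanged
  se2 <- sphere_exclusion(list(h_exact), list())
  expect_identical(se2$keep, 1L)
})

test_that("the full split honors the leakage guarantee and its audit", {
  smis <- make_toy_corpus(toy_corpus_spec(n_molecules = 40, seed = 2))$smiles
  sp <- leakage_safe_split(smis, holdout_fraction = 0.25, seed = 4)
  expect_lt(sp$audit$max_cross_tanimoto, 0.6)
  expect_equal(sp$audit$shared_scaffold_count, 0)
  expect_length(intersect(sp$train, sp$holdout), 0)
  # audit equals brute-force recomputation
  mols <- lapply(smis, standardize)
  fps <- lapply(mols, `[[`, "fingerprint")
  mx <- max(vapply(sp$holdout, function(h)
    max(vapply(sp$train, function(t) tanimoto(fps[[h]], fps[[t]]), numeric(1))),
    numeric(1)))
  expect_equal(sp$audit$max_cross_tanimoto, mx)
  # determinism
  sp2 <- leakage_safe_split(smis, holdout_fraction = 0.25, seed = 4)
  expect_identical(sp$holdout, sp2$holdout)
  # a manually injected near-duplicate across sides trips the audit
  bad <- sp
  bad$train <- c(bad$train, bad$holdout[1])
  expect_error(audit_split(bad, smis), "leakage_detected")
})

test_that("split artifacts are written to disk", {
  smis <- make_toy_corpus(toy_corpus_spec(n_molecules = 25, seed = 6))$smiles
  sp <- leakage_safe_split(smis, 0.3, seed = 1)
  d <- tempfile()
  write_split(sp, smis, d)
  expect_true(all(file.exists(file.path(d, c("train.csv", "holdout.csv",
                                             "removed.csv", "audit.json")))))
  aud <- jsonlite::read_json(file.path(d, "audit.json"))
  expect_equal(aud$n_train, length(sp$train))
})
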