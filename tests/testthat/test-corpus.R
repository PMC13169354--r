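# Sequence assembly, length filtering, curriculum ordering, augmentation.

mini_vocab <- function() {
  onto <- make_toy_ontology(3)
  toks <- lapply(c("CCO", "Cc1ccccc1", "c1ccccc1"), tokenize_smiles)
  list(onto = onto, vocab = build_vocabulary(toks, onto))
}

mk_mol <- function(smiles, descriptors = character(0)) {
  m <- standardize(smiles)
  m$descriptor_ids <- descriptors
  m
}

test_that("sequence layouts follow the three conditioning modes", {
  mv <- mini_vocab(); v <- mv$vocab
  d1 <- mv$onto$id[1]
  START <- special_id(v, "START"); SEP <- special_id(v, "SEP")
  END <- special_id(v, "END")

  s0 <- build_sequence(mk_mol("CCO"), "unconditional", v)
  expect_identical(s0$assembled_ids,
                   as.integer(c(START, encode(c("C", "C", "O"), v), END)))

  s1 <- build_sequence(mk_mol("CCO", d1), "smarts_only", v)
  expect_identical(s1$assembled_ids,
                   as.integer(c(START, encode(d1, v), SEP,
                                encode(c("C", "C", "O"), v), END)))

  s2 <- build_sequence(mk_mol("Cc1ccccc1", d1), "hybrid", v)
  expect_identical(
    s2$assembled_ids,
    as.integer(c(START, encode(d1, v), SEP,
                 encode(tokenize_smiles("c1ccccc1"), v), SEP,
                 encode(tokenize_smiles(canonicalize("Cc1ccccc1")), v), END)))
  expect_equal(s2$l_tot,
               1 + length(tokenize_smiles("c1ccccc1")) +
                 length(tokenize_smiles(canonicalize("Cc1ccccc1"))))
})

test_that("assembly and decomposition round-trip in all modes", {
  mv <- mini_vocab(); v <- mv$vocab
  d <- mv$onto$id[1:2]
  for (mode in c("unconditional", "smarts_only", "hybrid")) {
    s <- build_sequence(mk_mol("Cc1ccccc1", d), mode, v)
    dec <- decompose_sequence(s$assembled_ids, v)
    expect_identical(dec$mode, mode)
    expect_identical(dec$target_tokens, s$target_tokens)
    if (mode != "unconditional") expect_identical(dec$descriptor_tokens, d)
    if (mode == "hybrid") expect_identical(dec$scaffold_tokens, s$scaffold_tokens)
  }
  # acyclic molecule in hybrid mode: empty scaffold span, both SEPs kept
  s <- build_sequence(mk_mol("CCO", d[1]), "hybrid", v)
  dec <- decompose_sequence(s$assembled_ids, v)
  expect_identical(dec$mode, "hybrid")
  expect_identical(dec$scaffold_tokens, character(0))
})

test_that("length filter bounds are inclusive [5, 140]", {
  expect_true(length_filter(5))
  expect_false(length_filter(4))
  expect_true(length_filter(140))
  expect_false(length_filter(141))
  expect_true(length_filter(72))
})

test_that("curriculum ordering is a stable complexity sort", {
  mk <- function(rc, bc, lt) structure(
    list(ring_count = rc, branch_count = bc, l_tot = lt),
    class = "training_sequence")
  seqs <- list(mk(2, 1, 10), mk(0, 0, 5), mk(1, 0, 8))
  expect_identical(curriculum_order(seqs)$order, c(2L, 3L, 1L))
  # ties preserve input order
  seqs2 <- list(mk(1, 1, 5), mk(1, 1, 5), mk(0, 0, 3))
  expect_identical(curriculum_order(seqs2)$order, c(3L, 1L, 2L))
  # property: output is a permutation with nondecreasing keys
  set.seed(8)
  seqs3 <- lapply(1:40, function(i)
    mk(sample(0:3, 1), sample(0:4, 1), sample(5:60, 1)))
  co <- curriculum_order(seqs3)
  expect_setequal(co$order, 1:40)
  keys <- sapply(seqs3[co$order], function(s)
    s$ring_count * 1e6 + s$branch_count * 1e3 + s$l_tot)
  expect_true(all(diff(keys) >= 0))
  expect_length(co$stage, 40)
  expect_equal(max(co$stage), 4)
})

test_that("augmentation preserves molecule identity and context", {
  corpus <- recon_corpus()
  v <- corpus$vocab
  s <- corpus$sequences[[1]]
  set.seed(4)
  expect_identical(augment(s, p = 0, v), s)
  for (k in 1:10) {
    a <- augment(s, p = 1, v)
    expect_identical(a$descriptor_tokens, s$descriptor_tokens)
    expect_identical(a$scaffold_tokens, s$scaffold_tokens)
    expect_identical(canonicalize(paste(a$target_tokens, collapse = "")),
                     s$canonical_smiles)
  }
})

test_that("augmentation rate sits inside the binomial 99% interval", {
  corpus <- recon_corpus()
  s <- corpus$sequences[[2]]
  n <- 4000; p <- 0.1
  set.seed(31)
  flips <- vapply(seq_len(n), function(i) {
    a <- augment(s, p = p, vocab = corpus$vocab)
    !identical(a$target_tokens, s$target_tokens)
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), n, p) / n
  # replacement draws that happen to re-render canonically still count as
  # non-flips only textually; allow the lower bound some slack for that
  expect_gte(mean(flips), ci[1] - 0.02)
  expect_lte(mean(flips), ci[2])
})

test_that("centroid similarity behaves at the extremes", {
  fps <- lapply(recon_raw()$smiles[1:20], ecfp4)
  expect_equal(centroid_similarity(fps, fps), 1.0)
  disj_a <- list(structure(1:4, n_bits = 2048L))
  disj_b <- list(structure(5:8, n_bits = 2048L))
  expect_equal(centroid_similarity(disj_a, disj_b), 0)
  # 95% subset keeps the centroid nearly unchanged
  sub <- fps[1:19]
  expect_gt(centroid_similarity(fps, sub), 0.99)
  expect_error(centroid_similarity(list(), fps), "empty")
})

test_that("curation counts reconcile to the input size", {
  raw <- c(recon_raw()$smiles[1:10], "C1CC", "[Na+].[Cl-]",
           recon_raw()$smiles[1], paste0("c1ccc(cc1)", strrep("C", 150)))
  corpus <- build_training_corpus(raw, toy_ontology(), mode = "hybrid")
  ct <- corpus$counts
  expect_equal(ct[["input"]], length(raw))
  expect_equal(ct[["kept"]] + ct[["rejected"]] + ct[["duplicate"]] +
                 ct[["dropped_by_length"]], ct[["input"]])
  expect_equal(ct[["rejected"]], 2)
  expect_equal(ct[["duplicate"]], 1)
  expect_equal(ct[["dropped_by_length"]], 1)
  # every retained sequence passes the filter
  expect_true(all(vapply(corpus$sequences, length_filter, logical(1))))
  # manifest and corpus CSV round-trip
  d <- tempfile()
  write_corpus(corpus, d)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$counts$kept, ct[["kept"]])
  expect_identical(man$vocab_hash, corpus$vocab$hash)
})

test_that("curated corpora contain each canonical SMILES at most once", {
  corpus <- recon_corpus()
  cans <- vapply(corpus$sequences, `[[`, character(1), "canonical_smiles")
  expect_false(any(duplicated(cans)))
})
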