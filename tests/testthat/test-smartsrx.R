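# Ontology loading/validation and functional-group profiling.

toy_rows <- function() data.frame(
  id = c("amide", "phenylCl"), level1 = c("Carbonyl", "Halogen"),
  level2 = c("Amide", "ArylHalide"),
  smarts = c("[NX3][CX3](=O)", "Clc1ccccc1"), stringsAsFactors = FALSE)

test_that("ontology loads, validates and round-trips", {
  onto <- as_ontology(toy_rows())
  expect_equal(nrow(onto), 2)
  tsv <- tempfile(fileext = ".tsv")
  write_ontology(onto, tsv)
  onto2 <- load_ontology(tsv)
  expect_equal(as.data.frame(onto2), as.data.frame(onto))
  # re-serialization is byte-identical
  tsv2 <- tempfile(fileext = ".tsv")
  write_ontology(onto2, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))

  dup <- rbind(toy_rows(), toy_rows()[1, ])
  expect_error(as_ontology(dup), "duplicate_id.*amide")
  bad <- toy_rows(); bad$smarts[2] <- "Clc1cccc["
  expect_error(as_ontology(bad), "row 2")
})

test_that("profile returns presence sets", {
  onto <- as_ontology(toy_rows())
  expect_identical(profile("CCCC", onto), character(0))
  expect_identical(profile("Clc1ccccc1", onto), "phenylCl")
  expect_identical(profile("CC(=O)NC", onto), "amide")
  empty <- make_toy_ontology(0)
  expect_identical(profile("CC(=O)NC", empty), character(0))
})

test_that("profile is invariant to the SMILES rendering", {
  onto <- toy_ontology()
  set.seed(3)
  for (s in recon_raw()$smiles[1:10]) {
    p <- profile(s, onto)
    expect_setequal(profile(randomize_smiles(s), onto), p)
  }
})

test_that("profile is monotone under ontology union and level projection", {
  onto <- toy_ontology()
  o1 <- as_ontology(as.data.frame(onto)[1:10, ])
  o2 <- as_ontology(as.data.frame(onto)[11:nrow(onto), ])
  for (s in recon_raw()$smiles[1:8]) {
    expect_setequal(profile(s, onto), union(profile(s, o1), profile(s, o2)))
    # level-1 profile equals the projection of the level-3 profile
    l3 <- profile(s, onto)
    expect_setequal(profile(s, onto, level = 1),
                    unique(onto$level1[match(l3, onto$id)]))
  }
})

test_that("class frequencies match a brute-force recount", {
  onto <- as_ontology(toy_rows())
  corpus <- c("CC(=O)NC", "CC(=O)Nc1ccc(Cl)cc1X" = "CC(=O)NCCl")
  cf <- class_frequency(list("CC(=O)NC", "CC(=O)NCC"), onto)
  expect_equal(cf$percent[cf$class == "Carbonyl"], 100)
  expect_equal(cf$percent[cf$class == "Halogen"], 0)
  expect_error(class_frequency(list(), onto), "empty_corpus")

  full <- toy_ontology()
  smis <- recon_raw()$smiles[1:30]
  cf2 <- class_frequency(as.list(smis), full)
  # O(N*K) recount
  for (cl in cf2$class) {
    manual <- mean(vapply(smis, function(s)
      cl %in% profile(s, full, level = 1), logical(1)))
    expect_equal(cf2$percent[cf2$class == cl], 100 * manual, label = cl)
  }
  expect_true(all(cf2$percent >= 0 & cf2$percent <= 100))
})

test_that("descriptor statistics follow the documented sd convention", {
  onto <- as_ontology(toy_rows())
  # counts {1, 1}: both amide-only molecules
  st <- descriptor_stats(list("CC(=O)NC", "CCC(=O)NC"), onto)
  expect_equal(unname(st), c(1, 0, 1))
  # counts {0, 2}: sample sd sqrt(2), population sd 1
  two <- list("CCCC", "CC(=O)Nc1ccc(Cl)cc1")
  onto2 <- as_ontology(toy_rows())
  st2 <- descriptor_stats(two, onto2)
  expect_equal(unname(st2), c(1, sqrt(2), 2))
  st3 <- descriptor_stats(two, onto2, sd_type = "population")
  expect_equal(unname(st3), c(1, 1, 2))
  st4 <- descriptor_stats(list("CCO"), make_toy_ontology(0))
  expect_equal(unname(st4), c(0, 0, 0))
  expect_error(descriptor_stats(list(), onto), "empty_corpus")
})
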