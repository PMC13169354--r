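# Molecule standardization, scaffolds, fingerprints, complexity and
# randomized SMILES.

test_that("standardize applies the curation rules", {
  expect_identical(standardize("CCO")$canonical_smiles, "CCO")

  # salt stripped, stereo removed; hand application of the rules gives
  # alanine's heavy-atom graph
  s <- standardize("C[C@H](N)C(=O)O.Cl")
  expect_identical(s$canonical_smiles, canonicalize("CC(N)C(=O)O"))
  expect_false(grepl("[@/\\\\]", s$canonical_smiles))
  expect_false(grepl("Cl", s$canonical_smiles))

  r <- standardize("[Na+].[Cl-]")
  expect_s3_class(r, "mol_rejection")
  expect_identical(r$reason, "inorganic")

  r2 <- standardize("C1CC")
  expect_s3_class(r2, "mol_rejection")
  expect_identical(r2$reason, "unparseable")

  # neutralization: carboxylate gains H, ammonium loses one; nitro and
  # quaternary N keep their charges
  expect_identical(standardize("CC(=O)[O-].[Na+]")$canonical_smiles, "CC(=O)O")
  expect_identical(standardize("C[NH3+].[Cl-]")$canonical_smiles, "CN")
  expect_true(grepl("\\[N\\+\\]", standardize("O=[N+]([O-])c1ccccc1")$canonical_smiles))
  expect_true(grepl("\\[N\\+\\]", standardize("C[N+](C)(C)C.[Cl-]")$canonical_smiles))
})

test_that("standardize is idempotent", {
  raws <- c("C[C@H](N)C(=O)O.Cl", "CC(=O)Nc1ccc(O)cc1", "O=[N+]([O-])c1ccsc1",
            "c1ccc(cc1)S(N)(=O)=O", "CC(C)Cc1ccc(cc1)C(C)C(=O)O")
  for (r in raws) {
    s1 <- standardize(r)
    s2 <- standardize(s1$canonical_smiles)
    expect_identical(s2$canonical_smiles, s1$canonical_smiles, label = r)
  }
})

test_that("murcko scaffold matches the ring-plus-linker definition", {
  expect_identical(murcko_scaffold("c1ccccc1"), "c1ccccc1")
  expect_identical(murcko_scaffold("CCO"), "")
  # pruning terminal atoms to a fixed point leaves the bare ring
  expect_identical(murcko_scaffold("CCc1ccccc1"), "c1ccccc1")
  expect_identical(murcko_scaffold("CC(=O)Nc1ccc(O)cc1"), "c1ccccc1")
  # linker between two rings is retained, with its exocyclic carbonyl
  benzophenone <- murcko_scaffold("O=C(c1ccccc1)c1ccccc1")
  expect_identical(benzophenone, canonicalize("O=C(c1ccccc1)c1ccccc1"))
  expect_error(murcko_scaffold("not-a-molecule"))
})

test_that("murcko scaffold is a fixed point", {
  for (s in recon_raw()$smiles[1:20]) {
    sc <- murcko_scaffold(s)
    if (nzchar(sc)) expect_identical(murcko_scaffold(sc), sc, label = s)
  }
})

test_that("scaffold is a substructure of its molecule", {
  for (s in recon_raw()$smiles[1:10]) {
    sc <- murcko_scaffold(s)
    if (nzchar(sc))
      expect_gte(length(profile(s, as_ontology(
        data.frame(id = "scaf", level1 = "x", level2 = "y", smarts = sc)))), 1)
  }
})

test_that("complexity key counts rings and branch points", {
  expect_equal(complexity_key("CCCC"), c(ring_count = 0L, branch_count = 0L))
  expect_equal(complexity_key("c1ccccc1"), c(ring_count = 1L, branch_count = 0L))
  # hand enumeration: naphthalene + tert-butyl = 2 rings; branch points are
  # the quaternary carbon and the ring-attachment carbon
  expect_equal(complexity_key("CC(C)(C)c1ccc2ccccc2c1"),
               c(ring_count = 2L, branch_count = 2L))
  expect_equal(complexity_key("CC(C)(C)c1ccc2ccccc2c1", count_ring_fusion = TRUE),
               c(ring_count = 2L, branch_count = 4L))
})

test_that("fingerprints give sane Tanimoto values", {
  expect_equal(tanimoto(ecfp4("CCO"), ecfp4("OCC")), 1.0)
  expect_equal(tanimoto(ecfp4("CCO"), ecfp4("c1ccccc1")), 0.0)
  expect_gte(length(ecfp4("C")), 1)
  # symmetry and range over fixture pairs
  smis <- recon_raw()$smiles[1:8]
  fps <- lapply(smis, ecfp4)
  for (i in 1:7) {
    t1 <- tanimoto(fps[[i]], fps[[i + 1]])
    expect_identical(t1, tanimoto(fps[[i + 1]], fps[[i]]))
    expect_gte(t1, 0); expect_lte(t1, 1)
    expect_equal(tanimoto(fps[[i]], fps[[i]]), 1.0)
  }
})

test_that("randomized SMILES canonicalize back to the source molecule", {
  expect_identical(randomize_smiles("C"), "C")
  # determinism under a fixed seed
  set.seed(42); a <- randomize_smiles("CC(=O)Nc1ccc(O)cc1")
  set.seed(42); b <- randomize_smiles("CC(=O)Nc1ccc(O)cc1")
  expect_identical(a, b)
  # CCO renderings are drawn from the atom-order enumeration
  set.seed(7)
  r <- replicate(20, randomize_smiles("CCO"))
  expect_true(all(r %in% c("CCO", "OCC", "C(C)O", "C(O)C")))
  expect_true(all(vapply(r, function(x) canonicalize(x) == "CCO", logical(1))))
})

test_that("canonicalization is invariant to atom ordering across the corpus", {
  set.seed(99)
  for (s in recon_raw()$smiles) {
    can <- canonicalize(s)
    for (k in 1:3) {
      r <- randomize_smiles(s)
      expect_identical(canonicalize(r), can, label = paste(s, "->", r))
    }
  }
})

test_that("the canonical dialect is parseable by an independent backend", {
  # OpenBabel re-reads our canonical SMILES and agrees on the formula
  for (s in recon_raw()$smiles[1:15]) {
    p <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", s, identity))
    expect_true(nzchar(p$formula), label = s)
    expect_equal(as.numeric(p$MW), mol_weight(s), tolerance = 0.01, label = s)
  }
})

test_that("smiles readers handle .smi and csv", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1 mol2", ""), smi)
  d <- read_smiles(smi)
  expect_equal(d$smiles, c("CCO", "c1ccccc1"))
  expect_equal(d$id, c("mol1", "mol2"))
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CCO", "CCN"), activity = c(1, 2)), csv,
            row.names = FALSE)
  d2 <- read_smiles(csv)
  expect_equal(d2$smiles, c("CCO", "CCN"))
  expect_error(read_smiles(csv, smiles_col = "nope"), "not found")
})
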