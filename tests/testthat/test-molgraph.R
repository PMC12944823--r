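test_that("SMILES round-trip canonically on the packaged benchmark ligands", {
  t1 <- recoveryBenchmark()
  for (s in c(t1$target_smiles, t1$reported_result_smiles)) {
    cp <- parseSmiles(s)
    expect_gt(numAtoms(cp), 0)
    # canonical SMILES is a fixed point of parse + canonicalize
    expect_identical(smiles(parseSmiles(smiles(cp))), smiles(cp))
  }
})

test_that("stereochemistry is stripped and charges neutralized on input", {
  stereo <- parseSmiles("O=C1NC(=O)/C(=C/c2cccc(c2)C(F)(F)F)/S1")
  expect_false(grepl("[/\\\\@]", smiles(stereo)))
  charged <- parseSmiles("C[NH+]1CCN(CC1)c1ccccc1")
  expect_false(grepl("\\+", smiles(charged)))
})

test_that("invalid valences are rejected with an error", {
  expect_error(parseSmiles("C(C)(C)(C)(C)C"))
  expect_error(parseSmiles(""))
})

test_that("aromaticity perception matches the expected systems", {
  arom_count <- function(s) {
    mg <- parseSmiles(s)@graph
    sum(molmc:::mg_aromatic(mg)$atoms)
  }
  expect_identical(arom_count("c1ccccc1"), 6L)          # benzene
  expect_identical(arom_count("C1CCCCC1"), 0L)          # cyclohexane
  expect_identical(arom_count("c1cc[nH]c1"), 5L)        # pyrrole
  expect_identical(arom_count("CNc1cnn(C)c(=O)c1Cl"), 6L)  # pyridazinone
  expect_identical(arom_count("CC(=O)c1cc(c2n1cccc2)c1ccccn1"), 15L) # indolizine + pyridine
  expect_identical(arom_count("COc1cc2c(ncnc2cc1OC)Nc1cccc(c1)SC"), 16L) # quinazoline + phenyl
})

test_that("the internal SMILES writer round-trips through the canonicalizer", {
  t1 <- recoveryBenchmark()
  for (s in t1$target_smiles) {
    cp <- parseSmiles(s)
    own <- molmc:::mg_write_smiles(cp@graph)
    expect_identical(smiles(parseSmiles(own)), smiles(cp))
  }
})

test_that("molecular weight and implicit hydrogens are consistent", {
  expect_equal(molWeight(benzene), 78.11, tolerance = 1e-3)
  expect_equal(molWeight(methane), 16.043, tolerance = 1e-3)
  sulfone <- parseSmiles("CS(=O)(=O)C")
  h <- molmc:::mg_implicit_h(sulfone@graph)
  expect_identical(h[sulfone@graph$elem == "S"], 0L)
})

test_that("cumulated ring systems are not aromatic and not fingerprint-equal", {
  fake <- parseSmiles("CC1=C(O)C=C=C=C1")     # cumulene-containing ring
  real <- parseSmiles("Cc1ccccc1O")
  expect_identical(sum(molmc:::mg_aromatic(fake@graph)$atoms), 0L)
  expect_lt(diceSimilarity(fake, real), 1)
})
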