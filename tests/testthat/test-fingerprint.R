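# Dice similarity on count-based atom-pair fingerprints.  Frozen expected
# values were computed with an independent reference atom-pair
# implementation and agree to full precision.

test_that("dice similarity reproduces frozen reference values", {
  ref <- list(
    list("c1ccccc1", "Cc1ccccc1", 0.5555555556),
    list("c1ccccc1", "CC(=O)c1cc(c2n1cccc2)c1ccccn1", 0.1547619048),
    list("CCO", "CCCC", 0.2222222222),
    list("c1ccccc1", "c1ccncc1", 0.6666666667),
    list("C1CCCCC1", "c1ccccc1", 0.0000000000),
    list("CNc1cnn(C)c(=O)c1Cl", "CC(=O)c1cc(c2n1cccc2)c1ccccn1", 0.1923076923)
  )
  for (r in ref) {
    d <- diceSimilarity(parseSmiles(r[[1]]), parseSmiles(r[[2]]))
    expect_equal(d, r[[3]], tolerance = 1e-9)
  }
})

test_that("dice is 1 on identity and symmetric", {
  t1 <- recoveryBenchmark()
  cps <- lapply(t1$target_smiles[1:6], parseSmiles)
  for (cp in cps) expect_identical(diceSimilarity(cp, cp), 1.0)
  set.seed(4)
  for (i in 1:20) {
    a <- cps[[sample.int(6, 1)]]; b <- cps[[sample.int(6, 1)]]
    expect_identical(diceSimilarity(a, b), diceSimilarity(b, a))
  }
})

test_that("fingerprints are invariant to atom ordering", {
  a <- parseSmiles("c1ccccc1CCO")
  b <- parseSmiles("OCCc1ccccc1")
  expect_identical(atomPairFingerprint(a), atomPairFingerprint(b))
})

test_that("single heavy atoms have empty fingerprints and dice 1 together", {
  expect_length(atomPairFingerprint(methane), 0)
  expect_identical(diceSimilarity(methane, parseSmiles("O")), 1.0)
  expect_identical(diceSimilarity(methane, ethane), 0.0)
})

test_that("n-butane pairs match a hand-enumerated oracle", {
  but <- parseSmiles("CCCC")
  fp <- atomPairFingerprint(but)
  expect_length(fp, 6)      # 4 heavy atoms -> 6 pairs
  # oracle: types CH3 = (C, deg1, pi0), CH2 = (C, deg2, pi0)
  tC1 <- (unname(molmc:::AP_ELEM_IDX["C"]) * 4 + 0) * 8 + 1
  tC2 <- (unname(molmc:::AP_ELEM_IDX["C"]) * 4 + 0) * 8 + 2
  code <- function(t1, t2, d) (min(t1, t2) * 512 + max(t1, t2)) * 32 + d
  oracle <- sort(c(code(tC1, tC2, 1), code(tC2, tC2, 1), code(tC2, tC1, 1),
                   code(tC1, tC2, 2), code(tC2, tC1, 2), code(tC1, tC1, 3)))
  expect_identical(fp, as.integer(oracle))
})

test_that("fingerprints are invariant to the Kekule assignment", {
  # same constitution entering through different resonance spellings
  a <- parseSmiles("C1=CC=CC=C1")
  b <- parseSmiles("c1ccccc1")
  expect_identical(atomPairFingerprint(a), atomPairFingerprint(b))
})
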