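# Property scores (SA, ESOL, QED), normalizers, composite objective and
# the mock predictor backend.

t2 <- designReference()

test_that("SA score reproduces the reference design-run values", {
  for (i in seq_len(nrow(t2))) {
    sa <- saScore(parseSmiles(t2$smiles[i]))
    expect_equal(sa, t2$sa_raw[i], tolerance = 0.1)
  }
})

test_that("SA behaves sensibly across complexity", {
  expect_lt(saScore(benzene), 5.5)               # easy half of the scale
  plain <- parseSmiles("CCC1CCCCC1")
  spiro <- parseSmiles("CCC12CCC(CC1)CC2")       # spiro/bridged analog
  expect_gt(saScore(spiro), saScore(plain))
  for (s in t2$smiles) {
    sa <- saScore(parseSmiles(s))
    expect_gte(sa, 1); expect_lte(sa, 10)
  }
})

test_that("ESOL reproduces the reference values and directions", {
  for (i in seq_len(nrow(t2))) {
    es <- esolScore(parseSmiles(t2$smiles[i]))
    expect_equal(es, t2$esol_raw[i], tolerance = 0.3)
  }
  # long alkyl chains reduce estimated solubility
  expect_lt(esolScore(parseSmiles("CCCCCCCCc1ccccc1")),
            esolScore(parseSmiles("Cc1ccccc1")))
  # the model is the documented linear combination of its descriptors
  mg <- parseSmiles("CCO")@graph
  manual <- 0.16 - 0.63 * molmc:::crippen_logp_mg(mg) -
    0.0062 * molmc:::mg_molwt(mg) +
    0.066 * molmc:::count_rotatable_bonds(mg) -
    0.74 * molmc:::aromatic_proportion(mg)
  expect_equal(esolScore(parseSmiles("CCO")), manual, tolerance = 1e-12)
})

test_that("drug-likeness reproduces the reference values within tolerance", {
  for (i in seq_len(nrow(t2))) {
    q <- qedNoMW(parseSmiles(t2$smiles[i]))
    expect_equal(q, t2$qed[i], tolerance = 0.05)
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("dropping the weight desirability stops penalizing heavy molecules", {
  heavy <- parseSmiles(
    "CCCCCN(C(=O)C(NC(=O)C(Cc1ccccc1)NC(=O)C)CCC(=O)O)CCCCC")  # MW ~ 530
  no_mw <- molmc:::qed_no_mw_mg(heavy@graph)
  full <- molmc:::qed_full_mg(heavy@graph)
  expect_gt(no_mw, full)
})

test_that("normalizers hit their boundary values", {
  thr <- 5.0
  expect_identical(normalizeSA(thr, thr), 1)
  expect_identical(normalizeSA(3.2, thr), 1)
  expect_identical(normalizeSA(10, thr), 0)
  expect_equal(normalizeSA((thr + 10) / 2, thr), 0.5)
  lo <- -13.705; hi <- -1.486
  expect_identical(normalizeESOL(hi, lo, hi), 1)
  expect_identical(normalizeESOL(lo, lo, hi), 0)
  expect_equal(normalizeESOL((lo + hi) / 2, lo, hi), 0.5)
})

test_that("ESOL normalization calibration reproduces the reference composites", {
  bounds <- calibrateEsolNormalization()
  expect_lt(bounds["lo"], bounds["hi"])
  for (i in seq_len(nrow(t2))) {
    pred <- 0.8 * t2$confidence[i] + 0.1 * normalizeSA(t2$sa_raw[i]) +
      0.05 * normalizeESOL(t2$esol_raw[i], bounds["lo"], bounds["hi"]) +
      0.05 * t2$qed[i]
    expect_equal(unname(pred), t2$composite[i], tolerance = 0.01)
  }
})

test_that("the composite is the exact weighted sum of its components", {
  mols <- c("Cc1ccccc1", "CCO", t2$smiles[1])
  bk <- mockBackend()
  for (s in mols) {
    br <- compositeScore(parseSmiles(s), bk, "MKV")
    expect_equal(br@composite,
                 0.8 * br@confidence + 0.1 * br@saNorm + 0.05 * br@esolNorm +
                   0.05 * br@qed, tolerance = 1e-12)
    expect_true(all(c(br@confidence, br@saNorm, br@esolNorm, br@qed,
                      br@composite) >= 0))
    expect_true(all(c(br@confidence, br@saNorm, br@esolNorm, br@qed,
                      br@composite) <= 1))
  }
})

test_that("confidence-only weights reduce the composite to the confidence", {
  w <- compositeWeights(1, 0, 0, 0)
  cp <- parseSmiles("Cc1ccccc1")
  bk <- mockBackend()
  br <- compositeScore(cp, bk, "MKV", weights = w)
  expect_identical(br@composite, predictConfidence(bk, "MKV", cp))
})

test_that("the mock backend is deterministic with a known optimum", {
  bk <- mockBackend(optimum = c(natoms = 6, hbd = 0, hba = 0, rings = 1),
                    scales = c(natoms = 5, hbd = 2, hba = 2, rings = 1))
  c1 <- predictConfidence(bk, "MKV", benzene)
  c2 <- predictConfidence(bk, "MKV", benzene)
  expect_identical(c1, c2)
  expect_equal(c1, 1.0)                    # benzene sits at the optimum
  expect_lt(predictConfidence(bk, "MKV", parseSmiles("CCCCCCCCCCCC")), c1)
  far <- predictConfidence(bk, "MKV", parseSmiles("NCCO"))
  nearer <- predictConfidence(bk, "MKV", parseSmiles("C1CCCCC1"))
  expect_lt(far, nearer)
})

test_that("score components stay bounded along a random walk", {
  set.seed(17)
  mg <- benzene@graph
  bk <- mockBackend()
  for (i in 1:40) {
    out <- molmc:::propose_mg(mg)
    if (out$feasible) mg <- out$mg
  }
  br <- compositeScore(molmc:::compound_from_mg(mg), bk, "MKV")
  expect_true(br@saNorm >= 0 && br@saNorm <= 1)
  expect_true(br@esolNorm >= 0 && br@esolNorm <= 1)
  expect_true(br@qed >= 0 && br@qed <= 1)
  expect_true(br@composite >= 0 && br@composite <= 1)
})
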