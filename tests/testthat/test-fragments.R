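# BRICS decomposition, compatibility rules and fragment moves.

test_that("molecules without cleavable bonds are their own single fragment", {
  for (s in c("c1ccccc1", "CC")) {
    lib <- bricsDecompose(parseSmiles(s))
    expect_identical(numFragments(lib), 1L)
    expect_false(grepl("\\*", lib@smiles[1]))
  }
})

test_that("benchmark ligand decomposes into the expected fragment multiset", {
  lib <- bricsDecompose(parseSmiles("SCc1ccc(cc1)C(=O)N1CCC(CC1)Cc1ccccc1"))
  got <- sort(vapply(lib@fragments, function(f)
    smiles(molmc:::compound_from_mg(molmc:::brics_cap(f))), character(1)))
  # H-capped fragments: thiol methyl, carbonyl, benzenes, piperidine, methylene
  expect_identical(numFragments(lib), 6L)
  expect_true(smiles(parseSmiles("C1CCNCC1")) %in% got)
  expect_true("c1ccccc1" %in% got)
  expect_true(sum(got == "c1ccccc1") >= 1)
  expect_true(smiles(parseSmiles("CS")) %in% got)
})

test_that("cut bonds always join a permitted link-type pair", {
  t1 <- recoveryBenchmark()
  for (s in t1$target_smiles) {
    mg <- parseSmiles(s)@graph
    bb <- molmc:::brics_bonds(mg)
    if (is.null(bb)) next
    for (r in seq_len(nrow(bb)))
      expect_true(molmc:::brics_compatible(bb[r, 2], bb[r, 3]))
  }
})

test_that("every benchmark ligand reassembles to its own constitution", {
  t1 <- recoveryBenchmark()
  for (s in t1$target_smiles) {
    cp <- parseSmiles(s)
    lib <- bricsDecompose(cp)
    if (numFragments(lib) == 1L) next
    asm <- reassemble_fragments(lib@fragments, smiles(cp))
    expect_false(is.null(asm))
  }
})

test_that("removing then re-adding a fragment restores the assembly", {
  cp <- parseSmiles("CCc1ccccc1")        # single BRICS bond: two fragments
  lib <- bricsDecompose(cp)
  expect_identical(numFragments(lib), 2L)
  set.seed(5)
  asm <- new("FragmentedCompound", graph = lib@fragments[[1]])
  joined <- addFragment(asm, lib)
  expect_true(attr(joined, "feasible"))
  expect_identical(smiles(capAssembly(joined)), smiles(cp))
  removed <- removeFragment(joined)
  expect_true(attr(removed, "feasible"))
  expect_true(length(openSites(removed)[, 1]) >= 1)
  rejoined <- addFragment(removed, lib)
  expect_identical(smiles(capAssembly(rejoined)), smiles(cp))
})

test_that("addFragment requires a compatible partner", {
  lib <- bricsDecompose(parseSmiles("CCc1ccccc1"))
  closed <- new("FragmentedCompound",
                graph = parseSmiles("c1ccccc1")@graph)  # no open sites
  r <- addFragment(closed, lib)
  expect_false(attr(r, "feasible"))
})

test_that("randomFragmentStart is uniform and reproducible", {
  lib <- defaultFragmentLibrary()
  expect_identical(numFragments(lib), 50L)
  set.seed(21); a <- randomFragmentStart(lib)
  set.seed(21); b <- randomFragmentStart(lib)
  expect_identical(molmc:::mg_write_smiles(a@graph),
                   molmc:::mg_write_smiles(b@graph))
  set.seed(8)
  draws <- replicate(5000, sample.int(50L, 1L))
  obs <- tabulate(draws, nbins = 50)
  chi <- sum((obs - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, df = 49))
})

test_that("H-capping along a fragment-MC trajectory always sanitizes", {
  lib <- defaultFragmentLibrary()
  set.seed(9)
  asm <- randomFragmentStart(lib)@graph
  failures <- 0L
  for (i in 1:300) {
    prop <- if (runif(1) < 0.6) molmc:::frag_add_mg(asm, lib@fragments)
            else molmc:::frag_remove_mg(asm)
    if (is.null(prop)) next
    if (!molmc:::mg_sanitize_ok(molmc:::brics_cap(prop))) failures <- failures + 1L
    else if (sum(prop$elem != "*") <= 60L) asm <- prop
  }
  expect_identical(failures, 0L)
})

test_that("fragment MC reassembles a ligand from its own fragments", {
  tgt <- parseSmiles("SCc1ccc(cc1)C(=O)N1CCC(CC1)Cc1ccccc1")
  lib <- bricsDecompose(tgt)
  res <- runFragmentMC(lib, function(x) diceSimilarity(x, tgt),
                       nSteps = 500, beta = 5, pAdd = 0.6,
                       resetInterval = 50, seed = 5, earlyStop = 1)
  expect_identical(res$bestScore, 1.0)
  expect_identical(smiles(res$best), smiles(tgt))
})
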