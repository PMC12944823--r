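test_that("addGroup grafts substituents at positions with free valence", {
  outs <- enumerate_outcomes(addGroup, benzene, tries = 300)
  expect_true(smiles(toluene) %in% outs)          # CH3 on benzene -> toluene
  expect_true(all(vapply(outs, function(s) numAtoms(parseSmiles(s)) > 6,
                         logical(1))))
  meth_outs <- enumerate_outcomes(addGroup, methane, tries = 200)
  expect_true(smiles(parseSmiles("CO")) %in% meth_outs)  # methanol
  # fully substituted ring: no hydrogen to replace
  c6f6 <- parseSmiles("Fc1c(F)c(F)c(F)c(F)c1F")
  set.seed(1)
  r <- addGroup(c6f6)
  expect_false(r@feasible)
  expect_identical(smiles(r@compound), smiles(c6f6))
})

test_that("removeAtom deletes one heavy atom and keeps the largest fragment", {
  outs <- enumerate_outcomes(removeAtom, toluene, tries = 200)
  expect_true(smiles(benzene) %in% outs)
  set.seed(2)
  r <- removeAtom(ethane)
  expect_true(r@feasible)
  expect_identical(smiles(r@compound), "C")
  expect_false(removeAtom(methane)@feasible)
})

test_that("changeAtomType swaps elements under valence constraints", {
  outs <- enumerate_outcomes(changeAtomType, benzene, tries = 400)
  expect_true(smiles(parseSmiles("c1ccncc1")) %in% outs)      # pyridine
  meoh_outs <- enumerate_outcomes(changeAtomType, parseSmiles("CO"), tries = 200)
  expect_true(smiles(parseSmiles("CS")) %in% meoh_outs)       # methanethiol
  # quaternary carbon cannot become a halogen
  neo <- parseSmiles("CC(C)(C)C")
  outs2 <- enumerate_outcomes(changeAtomType, neo, tries = 400)
  expect_false(any(grepl("F\\(", outs2)))
  for (s in outs2) expect_gt(numAtoms(parseSmiles(s)), 0)
})

test_that("addAtomInChain inserts an atom into an existing bond", {
  outs <- enumerate_outcomes(addAtomInChain, ethane, tries = 200)
  expect_true("CCC" %in% outs)                     # propane
  meoh_outs <- enumerate_outcomes(addAtomInChain, parseSmiles("CO"), tries = 200)
  expect_true(smiles(parseSmiles("CCO")) %in% meoh_outs)  # ethanol skeleton
  # insertion into an aromatic (kekulized) ring bond gives a 7-ring
  benz_outs <- enumerate_outcomes(addAtomInChain, benzene, tries = 100)
  expect_true(all(vapply(benz_outs, function(s)
    numAtoms(parseSmiles(s)) == 7L, logical(1))))
})

test_that("changeBondType toggles single and double bonds", {
  set.seed(1)
  r <- changeBondType(ethane)
  expect_true(r@feasible)
  expect_identical(smiles(r@compound), "C=C")
  set.seed(1)
  r2 <- changeBondType(parseSmiles("C=C"))
  expect_identical(smiles(r2@compound), "CC")
  expect_false(changeBondType(parseSmiles("CC(C)(C)C(C)(C)C"))@feasible)
})

test_that("formRing closes rings in the 3-8 window", {
  hex_outs <- enumerate_outcomes(formRing, parseSmiles("CCCCCC"), tries = 300)
  expect_true(smiles(cyclohexane) %in% hex_outs)
  set.seed(1)
  r <- formRing(parseSmiles("CCC"))
  expect_true(r@feasible)
  expect_identical(smiles(r@compound), smiles(parseSmiles("C1CC1")))
  expect_false(formRing(ethane)@feasible)
})

test_that("breakRing cuts a ring bond and kekulizes aromatics", {
  set.seed(1)
  r <- breakRing(cyclohexane)
  expect_true(r@feasible)
  expect_identical(smiles(r@compound), smiles(parseSmiles("CCCCCC")))
  outs <- enumerate_outcomes(breakRing, benzene, tries = 100)
  for (s in outs) {
    cp <- parseSmiles(s)
    expect_identical(numAtoms(cp), 6L)
    expect_length(molmc:::mg_rings(cp@graph), 0)   # acyclic
  }
  expect_false(breakRing(methane)@feasible)
})

test_that("toggleAromatic aromatizes and saturates rings, self-inversely", {
  set.seed(1)
  up <- toggleAromatic(cyclohexane)
  expect_true(up@feasible)
  expect_identical(smiles(up@compound), "c1ccccc1")
  set.seed(1)
  down <- toggleAromatic(up@compound)
  expect_identical(smiles(down@compound), smiles(cyclohexane))
  expect_false(toggleAromatic(parseSmiles("C1CCCC1"))@feasible)
  # heteroaromatic: saturated lactam-like ring can be aromatized
  pre <- parseSmiles("O=C1CC(Cl)C(NC)CN1C")
  outs <- enumerate_outcomes(toggleAromatic, pre, tries = 50)
  expect_true(length(outs) >= 1)
  expect_true(any(grepl("c", outs)))
})

test_that("rearrangeBonds migrates substituents across neighbors", {
  iso_outs <- enumerate_outcomes(rearrangeBonds, parseSmiles("CC(C)C"), tries = 300)
  expect_true("CCCC" %in% iso_outs)                # n-butane reachable
  expect_false(rearrangeBonds(ethane)@feasible)
  neo_outs <- enumerate_outcomes(rearrangeBonds, parseSmiles("CC(C)(C)C"),
                                 tries = 300)
  expect_true(smiles(parseSmiles("CCC(C)C")) %in% neo_outs)  # isopentane
})

test_that("proposeMove draws move kinds at the configured probabilities", {
  ms <- defaultMoveSet()
  expect_equal(sum(moveProbabilities(ms)), 1, tolerance = 1e-12)
  expect_equal(unname(moveProbabilities(ms)["add_group"]), 0.3)
  only_add <- defaultMoveSet()
  p <- moveProbabilities(only_add); p[] <- 0; p["add_group"] <- 1
  ms1 <- new("MoveSet", kinds = names(p), probs = unname(p))
  set.seed(3)
  r <- proposeMove(benzene, ms1)
  expect_true(r@feasible)
  expect_identical(r@moveKind, "add_group")
  # single atom with remove-only moves: nothing feasible
  p[] <- 0; p["remove_atom"] <- 1
  ms2 <- new("MoveSet", kinds = names(p), probs = unname(p))
  expect_false(proposeMove(methane, ms2)@feasible)
})

test_that("empirical move-kind frequencies match the standard probabilities", {
  set.seed(11)
  n <- 4000L
  kinds <- character(n)
  cp <- parseSmiles("CCc1ccccc1O")   # all nine move kinds feasible here
  for (i in seq_len(n)) {
    r <- proposeMove(cp)
    kinds[i] <- r@moveKind
  }
  obs <- table(factor(kinds, levels = names(molmc:::MOVE_KINDS)))
  expc <- molmc:::MOVE_KINDS * n
  chi <- sum((obs - expc)^2 / expc)
  expect_lt(chi, qchisq(0.999, df = 8))
})

test_that("random walks stay chemically valid (closure)", {
  seeds <- recoveryBenchmark()$target_smiles[1:10]
  seeds <- c(seeds, "c1ccccc1", "CCO", "CC(C)C", "c1ccncc1", "C1CCCCC1",
             "CC(=O)NC", "CSC", "FC(F)F", "CCCCC", "c1cc[nH]c1")
  set.seed(99)
  failures <- 0L
  for (s in seeds) {
    mg <- parseSmiles(s)@graph
    for (i in 1:120) {
      out <- molmc:::propose_mg(mg)
      if (out$feasible) {
        if (!molmc:::mg_sanitize_ok(out$mg)) failures <- failures + 1L
        else mg <- out$mg
      }
    }
  }
  expect_identical(failures, 0L)
})

test_that("identical seeds give identical move outcomes (determinism)", {
  set.seed(123); a <- proposeMove(toluene)
  set.seed(123); b <- proposeMove(toluene)
  expect_identical(smiles(a@compound), smiles(b@compound))
  expect_identical(a@moveKind, b@moveKind)
})

test_that("walks from benzene reach all elements, ring sizes and heteroaromatics", {
  set.seed(77)
  mg <- benzene@graph
  seen_elem <- character(0)
  seen_ring <- integer(0)
  het_arom <- FALSE
  for (i in 1:10000) {
    out <- molmc:::propose_mg(mg)
    if (!out$feasible) next
    if (molmc:::mg_natoms(out$mg) > 45L) next   # keep the walk bounded
    mg <- out$mg
    seen_elem <- union(seen_elem, mg$elem)
    rings <- molmc:::mg_rings(mg)
    seen_ring <- union(seen_ring, vapply(rings, length, integer(1)))
    if (!het_arom && length(rings)) {
      ar <- molmc:::mg_aromatic(mg)
      for (r in rings)
        if (all(ar$atoms[r]) && any(mg$elem[r] %in% c("N", "O", "S")))
          het_arom <- TRUE
    }
    if (het_arom && length(setdiff(c("C","N","O","S","F","Cl","Br","P"),
                                   seen_elem)) == 0 &&
        all(3:8 %in% seen_ring)) break
  }
  expect_setequal(setdiff(c("C","N","O","S","F","Cl","Br","P"), seen_elem),
                  character(0))
  expect_true(all(3:8 %in% seen_ring))
  expect_true(het_arom)
})

test_that("move pairs invert each other on the worked examples", {
  # form/break ring
  set.seed(2)
  ring <- formRing(parseSmiles("CCCCCC"))
  broken <- enumerate_outcomes(breakRing, ring@compound, tries = 50)
  expect_true(smiles(parseSmiles("CCCCCC")) %in% broken)
  # add group / remove atom
  grown <- enumerate_outcomes(addGroup, benzene, tries = 100)
  expect_true(smiles(toluene) %in% grown)
  shrunk <- enumerate_outcomes(removeAtom, toluene, tries = 100)
  expect_true(smiles(benzene) %in% shrunk)
})
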