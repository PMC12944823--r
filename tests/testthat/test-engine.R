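# Metropolis acceptance, chain mechanics, protocols.

test_that("the Metropolis rule accepts improvements and equalities always", {
  set.seed(1)
  expect_true(metropolisAccept(0.5, 0.5, beta = 50))
  for (i in 1:200) expect_true(metropolisAccept(runif(1) + 1, runif(1), 50))
})

test_that("acceptance frequency of a fixed decrease follows exp(-beta*ds)", {
  set.seed(42)
  for (beta in c(5, 50)) {
    ds <- 0.01
    n <- 100000L
    acc <- sum(replicate(n, metropolisAccept(0.5 - ds, 0.5, beta)))
    p <- exp(-beta * ds)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(acc / n - p), 3 * se + 1e-9)
  }
})

test_that("zero-step chains return the start compound scored once", {
  tgt <- toluene
  res <- runChain(benzene, function(x) diceSimilarity(x, tgt),
                  nSteps = 0, seed = 1)
  expect_identical(smiles(bestCompound(res$state)), smiles(benzene))
  expect_identical(res$state@nProposed, 0L)
})

test_that("chains are reproducible under a fixed seed", {
  tgt <- parseSmiles("CCc1ccccc1O")
  a <- runChain(benzene, function(x) diceSimilarity(x, tgt),
                nSteps = 150, seed = 7)
  b <- runChain(benzene, function(x) diceSimilarity(x, tgt),
                nSteps = 150, seed = 7)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(smiles(bestCompound(a$state)), smiles(bestCompound(b$state)))
})

test_that("very large beta behaves as greedy hill-climbing", {
  tgt <- parseSmiles("CCc1ccccc1O")
  res <- runChain(benzene, function(x) diceSimilarity(x, tgt),
                  nSteps = 200, beta = 1e9, seed = 3)
  acc <- res$trajectory[res$trajectory$accepted & !res$trajectory$is_reset, ]
  expect_true(all(diff(acc$score) >= -1e-12))
})

test_that("the best score is non-decreasing along every trajectory", {
  tgt <- parseSmiles("CNc1cnn(C)c(=O)c1Cl")
  res <- runChain(benzene, function(x) diceSimilarity(x, tgt),
                  nSteps = 300, seed = 11)
  tr <- res$trajectory[!res$trajectory$is_reset, ]
  run_best <- cummax(ifelse(tr$accepted, tr$score, -Inf))
  expect_true(all(diff(run_best[is.finite(run_best)]) >= -1e-12))
  expect_equal(bestScore(res$state), max(tr$score[tr$accepted], na.rm = TRUE))
})

test_that("resets are logged and do not count as proposals", {
  tgt <- parseSmiles("CNc1cnn(C)c(=O)c1Cl")
  res <- runChain(benzene, function(x) diceSimilarity(x, tgt),
                  nSteps = 250, resetInterval = 50, seed = 5)
  n_reset <- sum(res$trajectory$is_reset)
  n_prop <- sum(!res$trajectory$is_reset)
  expect_identical(res$state@nProposed, n_prop)
  # reset records carry the best-so-far score
  if (n_reset > 0) {
    rr <- res$trajectory[res$trajectory$is_reset, ]
    expect_true(all(rr$accepted))
  }
})

test_that("acceptanceRate handles the degenerate windows", {
  all_acc <- data.frame(step = 1:5, smiles = "C", move_kind = "x",
                        score = 1, accepted = TRUE, is_reset = FALSE)
  none <- transform(all_acc, accepted = FALSE)
  expect_identical(acceptanceRate(all_acc), 1)
  expect_identical(acceptanceRate(none), 0)
  expect_error(acceptanceRate(all_acc, from = 10))
})

test_that("single-replica recovery without stage 1 equals the plain chain", {
  seed <- 4L
  multi <- runMultireplicaRecovery("Cc1ccccc1O", replicas = 1L,
                                   stage1Steps = 0L, syncEvery = 500L,
                                   stage2Steps = 300L, seed = seed)
  chain_seed <- (seed * 10000L + 9999L) %% 2147483647L
  single <- runRecoveryChain("Cc1ccccc1O", nSteps = 300L, seed = chain_seed)
  expect_identical(bestScore(multi$state), bestScore(single$state))
  expect_identical(smiles(bestCompound(multi$state)),
                   smiles(bestCompound(single$state)))
})

test_that("recovery of a trivial target succeeds immediately", {
  res <- runRecoveryChain("c1ccccc1", startSmiles = "c1ccccc1",
                          nSteps = 10, seed = 1)
  expect_identical(bestScore(res$state), 1.0)
})

test_that("a design run climbs toward the mock optimum", {
  bk <- mockBackend(optimum = c(natoms = 10, hbd = 1, hba = 1, rings = 1),
                    scales = c(natoms = 4, hbd = 1.5, hba = 1.5, rings = 1))
  res <- runDesign("MKVL", bk, nSteps = 60, seed = 2)
  start_conf <- predictConfidence(bk, "MKVL", benzene)
  expect_gt(res$breakdown@confidence, start_conf)
  expect_gt(bestScore(res$state), 0.8 * start_conf)
  # best composite series non-decreasing
  tr <- res$trajectory[!res$trajectory$is_reset & res$trajectory$accepted, ]
  expect_true(all(diff(cummax(tr$score)) >= -1e-12))
})

test_that("cleanup never lets the confidence fall below its floor", {
  bk <- mockBackend(optimum = c(natoms = 8, hbd = 1, hba = 1, rings = 1),
                    scales = c(natoms = 4, hbd = 1.5, hba = 1.5, rings = 1))
  start <- parseSmiles("Cc1ccccc1O")
  conf0 <- predictConfidence(bk, "M", start)
  res <- runCleanup(start, bk, "M", nSteps = 40, seed = 6)
  final_conf <- predictConfidence(bk, "M", bestCompound(res$state))
  expect_gte(final_conf, conf0 - 0.02 - 1e-12)
})

test_that("an objective failure rejects the step and the chain continues", {
  tgt <- toluene
  flaky <- function(x) {
    if (numAtoms(x) >= 9) stop("backend failure")
    diceSimilarity(x, tgt)
  }
  res <- runChain(benzene, flaky, nSteps = 120, seed = 13)
  expect_identical(res$state@nProposed, sum(!res$trajectory$is_reset))
  # no accepted compound ever exceeded the failing size
  expect_true(numAtoms(bestCompound(res$state)) < 9)
})
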