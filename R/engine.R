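# The Monte Carlo state machine: Metropolis acceptance, reset-to-best,
# the two-stage multi-replica recovery protocol, design runs against a
# predictor backend, and the bias-only cleanup phase.
#
# All randomness flows through R's RNG; run functions seed it from their
# `seed` argument, and multi-replica runs derive one deterministic stream
# per (replica, block) so results do not depend on scheduling.

#' Metropolis acceptance rule
#'
#' A proposal is always accepted when the score does not decrease; a
#' score-decreasing proposal is accepted with probability
#' \eqn{\exp(-\beta \, \Delta s)} where \eqn{\Delta s = s_{cur} - s_{new}}
#' is the magnitude of the decrease (the standard Metropolis form for a
#' maximized score).
#'
#' @param sNew,sCur proposed and current score
#' @param beta inverse temperature (> 0); large beta approaches greedy
#'   hill-climbing
#' @return logical: accept the proposal (consumes one uniform draw only for
#'   score-decreasing proposals)
#' @examples
#' set.seed(1)
#' metropolisAccept(0.5, 0.4, beta = 50)   # improvement: always TRUE
#' @export
metropolisAccept <- function(sNew, sCur, beta) {
  stopifnot(is.finite(sNew), is.finite(sCur), beta > 0)
  if (sNew >= sCur) return(TRUE)
  stats::runif(1) < exp(-beta * (sCur - sNew))
}

# internal chain core operating on molecular graphs.
# objective: function(mg) -> numeric score (higher is better), or a list
#   with $score and extra columns for the trajectory.
# reset = NA disables reset-to-best.  Returns state + trajectory rows.
run_chain_mg <- function(mg, objective, nsteps, beta, reset = 100L,
                         probs = MOVE_KINDS, early_stop = Inf,
                         record = TRUE, step0 = 0L,
                         init = NULL) {
  eval_obj <- function(g) {
    v <- objective(g)
    if (is.list(v)) v else list(score = v)
  }
  if (is.null(init)) {
    cur <- eval_obj(mg)
    init <- list(mg = mg, score = cur$score,
                 best_mg = mg, best_score = cur$score,
                 nprop = 0L, nacc = 0L)
  }
  mg <- init$mg; s_cur <- init$score
  best_mg <- init$best_mg; best_score <- init$best_score
  nprop <- init$nprop; nacc <- init$nacc
  cap <- if (record) nsteps + nsteps %/% max(1L, if (is.na(reset)) nsteps else reset) + 2L else 0L
  r_step <- integer(cap); r_smiles <- character(cap); r_kind <- character(cap)
  r_score <- numeric(cap); r_acc <- logical(cap); r_reset <- logical(cap)
  nr <- 0L
  for (i in seq_len(nsteps)) {
    out <- propose_mg(mg, probs = probs)
    nprop <- nprop + 1L
    accepted <- FALSE
    s_new <- NA_real_
    if (out$feasible) {
      res <- tryCatch(eval_obj(out$mg), error = function(e) NULL)
      if (!is.null(res) && is.finite(res$score)) {
        s_new <- res$score
        if (metropolisAccept(s_new, s_cur, beta)) {
          accepted <- TRUE
          nacc <- nacc + 1L
          mg <- out$mg; s_cur <- s_new
          if (s_new > best_score) { best_mg <- mg; best_score <- s_new }
        }
      }
    }
    if (record) {
      nr <- nr + 1L
      r_step[nr] <- step0 + i; r_smiles[nr] <- mg_write_smiles(out$mg)
      r_kind[nr] <- out$kind; r_score[nr] <- s_new
      r_acc[nr] <- accepted; r_reset[nr] <- FALSE
    }
    if (best_score >= early_stop) break
    if (!is.na(reset) && (step0 + i) %% reset == 0L && s_cur < best_score) {
      mg <- best_mg; s_cur <- best_score
      if (record) {
        nr <- nr + 1L
        r_step[nr] <- step0 + i; r_smiles[nr] <- mg_write_smiles(mg)
        r_kind[nr] <- "reset"; r_score[nr] <- s_cur
        r_acc[nr] <- TRUE; r_reset[nr] <- TRUE
      }
    }
  }
  trajectory <- NULL
  if (record) {
    idx <- seq_len(nr)
    trajectory <- data.frame(step = r_step[idx], smiles = r_smiles[idx],
                             move_kind = r_kind[idx], score = r_score[idx],
                             accepted = r_acc[idx], is_reset = r_reset[idx],
                             stringsAsFactors = FALSE)
  }
  list(mg = mg, score = s_cur, best_mg = best_mg, best_score = best_score,
       nprop = nprop, nacc = nacc, trajectory = trajectory)
}

mcstate_from_core <- function(res) {
  new("MCState", current = compound_from_mg(res$mg), currentScore = res$score,
      best = compound_from_mg(res$best_mg), bestScore = res$best_score,
      step = res$nprop, nProposed = res$nprop, nAccepted = res$nacc)
}

#' Run a single Monte Carlo chain
#'
#' Executes propose / score / accept iterations under the Metropolis rule,
#' resetting the current structure to the best structure found every
#' \code{resetInterval} steps (a reset is logged with \code{is_reset=TRUE}
#' and does not count as a proposal).
#'
#' @param start starting \linkS4class{Compound}
#' @param objective function(Compound) -> numeric score, higher is better
#' @param nSteps number of MC steps
#' @param beta inverse temperature
#' @param resetInterval reset-to-best period; NA disables
#' @param moveSet the \linkS4class{MoveSet} used for proposals
#' @param seed integer seed (seeds R's RNG)
#' @param earlyStop stop when the best score reaches this value
#' @return list with \code{state} (an \linkS4class{MCState}) and
#'   \code{trajectory} (one data-frame row per proposed step)
#' @examples
#' target <- parseSmiles("Cc1ccccc1")
#' res <- runChain(parseSmiles("c1ccccc1"),
#'                 function(x) diceSimilarity(x, target),
#'                 nSteps = 50, beta = 50, seed = 1)
#' bestScore(res$state)
#' @export
runChain <- function(start, objective, nSteps = 10000L, beta = 50,
                     resetInterval = 100L, moveSet = defaultMoveSet(),
                     seed = 1L, earlyStop = Inf) {
  set.seed(seed)
  obj_mg <- function(mg) objective(compound_from_mg(mg))
  res <- run_chain_mg(start@graph, obj_mg, as.integer(nSteps), beta,
                      reset = if (is.na(resetInterval)) NA else as.integer(resetInterval),
                      probs = moveProbabilities(moveSet),
                      early_stop = earlyStop)
  list(state = mcstate_from_core(res), trajectory = res$trajectory)
}

# fast internal recovery objective (avoids Compound construction per step)
dice_objective_mg <- function(target_mg) {
  tgt <- ap_fingerprint_mg(target_mg)
  function(mg) dice_codes(ap_fingerprint_mg(mg), tgt)
}

#' Dice-similarity recovery by a single chain
#'
#' Evolves a start compound (default benzene) toward a target compound under
#' the dice-similarity objective on atom-pair fingerprints.
#'
#' @param targetSmiles target compound SMILES
#' @param startSmiles starting compound SMILES
#' @param nSteps,beta,resetInterval,moveSet,seed see \code{\link{runChain}}
#' @return list(state, trajectory); the run stops early once dice reaches 1
#' @export
runRecoveryChain <- function(targetSmiles, startSmiles = "c1ccccc1",
                             nSteps = 10000L, beta = 50, resetInterval = 100L,
                             moveSet = defaultMoveSet(), seed = 1L) {
  set.seed(seed)
  objective <- dice_objective_mg(parse_smiles_mg(targetSmiles))
  res <- run_chain_mg(parse_smiles_mg(startSmiles), objective,
                      as.integer(nSteps), beta,
                      reset = as.integer(resetInterval),
                      probs = moveProbabilities(moveSet),
                      early_stop = 1.0)
  list(state = mcstate_from_core(res), trajectory = res$trajectory)
}

#' Two-stage multi-replica recovery
#'
#' Stage 1 runs \code{replicas} chains; every \code{syncEvery} steps all
#' replicas are set to the best structure found by any replica so far
#' (free-running between synchronizations).  Stage 2 refines the global
#' best with a single chain using reset-to-best every
#' \code{resetInterval} steps.  Replica streams are seeded deterministically
#' from (seed, replica, block), so the result is independent of execution
#' order; ties in the global best are broken by lowest replica index.
#'
#' @param targetSmiles target compound SMILES
#' @param startSmiles starting compound SMILES
#' @param replicas stage-1 replica count
#' @param stage1Steps stage-1 steps per replica
#' @param syncEvery stage-1 synchronization period
#' @param stage2Steps stage-2 chain length
#' @param beta inverse temperature
#' @param resetInterval stage-2 reset period
#' @param moveSet proposal catalogue
#' @param seed integer master seed
#' @param recordTrajectory record the stage-2 trajectory (disable for
#'   benchmarking loops where only the best score matters)
#' @return list with \code{state} (best as \linkS4class{MCState}),
#'   \code{dice} (best dice), \code{stage} ("stage1"/"stage2"),
#'   \code{trajectory} (stage-2 rows, if reached and recorded)
#' @export
runMultireplicaRecovery <- function(targetSmiles, startSmiles = "c1ccccc1",
                                    replicas = 30L, stage1Steps = 5000L,
                                    syncEvery = 500L, stage2Steps = 10000L,
                                    beta = 50, resetInterval = 100L,
                                    moveSet = defaultMoveSet(), seed = 1L,
                                    recordTrajectory = TRUE) {
  probs <- moveProbabilities(moveSet)
  target_mg <- parse_smiles_mg(targetSmiles)
  objective <- dice_objective_mg(target_mg)
  start <- parse_smiles_mg(startSmiles)
  s0 <- objective(start)
  mkinit <- function() list(mg = start, score = s0, best_mg = start,
                            best_score = s0, nprop = 0L, nacc = 0L)
  reps <- replicate(replicas, mkinit(), simplify = FALSE)
  gbest <- list(mg = start, score = s0)
  nprop_total <- 0L; nacc_total <- 0L
  nblocks <- max(1L, as.integer(stage1Steps) %/% as.integer(syncEvery))
  for (b in seq_len(nblocks)) {
    for (r in seq_len(replicas)) {
      set.seed((as.integer(seed) * 10000L + r * 100L + b) %% 2147483647L)
      res <- run_chain_mg(NULL, objective, as.integer(syncEvery), beta,
                          reset = NA, probs = probs, early_stop = 1.0,
                          record = FALSE, init = reps[[r]])
      reps[[r]] <- list(mg = res$mg, score = res$score, best_mg = res$best_mg,
                        best_score = res$best_score, nprop = 0L, nacc = 0L)
      nprop_total <- nprop_total + res$nprop
      nacc_total <- nacc_total + res$nacc
      if (res$best_score > gbest$score)
        gbest <- list(mg = res$best_mg, score = res$best_score)
      if (gbest$score >= 1.0) {
        st <- new("MCState", current = compound_from_mg(gbest$mg),
                  currentScore = gbest$score,
                  best = compound_from_mg(gbest$mg), bestScore = gbest$score,
                  step = nprop_total, nProposed = nprop_total,
                  nAccepted = nacc_total)
        return(list(state = st, dice = gbest$score, stage = "stage1",
                    trajectory = NULL))
      }
    }
    for (r in seq_len(replicas))
      reps[[r]] <- list(mg = gbest$mg, score = gbest$score, best_mg = gbest$mg,
                        best_score = gbest$score, nprop = 0L, nacc = 0L)
  }
  set.seed((as.integer(seed) * 10000L + 9999L) %% 2147483647L)
  res <- run_chain_mg(gbest$mg, objective, as.integer(stage2Steps), beta,
                      reset = as.integer(resetInterval), probs = probs,
                      early_stop = 1.0, record = recordTrajectory)
  st <- mcstate_from_core(res)
  # the state's counters cover the whole protocol, both stages
  st@nProposed <- nprop_total + res$nprop
  st@nAccepted <- nacc_total + res$nacc
  st@step <- st@nProposed
  list(state = st, dice = res$best_score, stage = "stage2",
       trajectory = res$trajectory)
}

#' De novo design run against a predictor backend
#'
#' Single chain under the composite objective (confidence + SA + ESOL + QED
#' biases), default 2000 steps at beta = 50 with reset-to-best every 100
#' steps, starting from benzene.  A backend failure on a step rejects that
#' step and the chain continues.
#'
#' @param protein protein sequence (passed to the backend)
#' @param backend a \linkS4class{PredictorBackend}
#' @param nSteps,beta,resetInterval,moveSet,seed chain parameters
#' @param startSmiles starting compound SMILES
#' @param weights a \linkS4class{CompositeWeights}
#' @return list with \code{state}, \code{breakdown} (ScoreBreakdown of the
#'   best compound) and \code{trajectory}
#' @export
runDesign <- function(protein, backend, nSteps = 2000L, beta = 50,
                      resetInterval = 100L, moveSet = defaultMoveSet(),
                      startSmiles = "c1ccccc1", seed = 1L,
                      weights = compositeWeights()) {
  set.seed(seed)
  w <- c(weights@wConf, weights@wSa, weights@wEsol, weights@wQed)
  objective <- function(mg) {
    conf <- predictConfidence(backend, protein, compound_from_mg(mg))
    br <- composite_breakdown_mg(mg, conf, weights = w)
    list(score = br$composite, confidence = br$confidence, sa_raw = br$sa_raw,
         esol_raw = br$esol_raw, qed = br$qed)
  }
  res <- run_chain_mg(parse_smiles_mg(startSmiles), objective,
                      as.integer(nSteps), beta,
                      reset = as.integer(resetInterval),
                      probs = moveProbabilities(moveSet))
  best <- compound_from_mg(res$best_mg)
  conf <- predictConfidence(backend, protein, best)
  br <- composite_breakdown_mg(res$best_mg, conf, weights = w)
  breakdown <- new("ScoreBreakdown", confidence = br$confidence,
                   saRaw = br$sa_raw, saNorm = br$sa_norm,
                   esolRaw = br$esol_raw, esolNorm = br$esol_norm,
                   qed = br$qed, composite = br$composite)
  list(state = mcstate_from_core(res), breakdown = breakdown,
       trajectory = res$trajectory)
}

#' Cleanup phase: optimize the property biases under a confidence floor
#'
#' A short constrained stage (default 100 steps) whose objective is only the
#' renormalized SA/ESOL/QED biases; any proposal whose backend confidence
#' falls below (starting confidence - floorDrop) is rejected outright.  The
#' move probabilities shift mass toward atom removal and atom-type changes
#' (doubled and renormalized) to favor simplification.
#'
#' @param compound the scored compound to clean up
#' @param backend a \linkS4class{PredictorBackend}
#' @param protein protein sequence
#' @param nSteps number of cleanup steps
#' @param beta inverse temperature
#' @param floorDrop permitted confidence drop below the starting value
#' @param seed integer seed
#' @return list(state, trajectory); the final compound's confidence is
#'   always >= start confidence - floorDrop
#' @export
runCleanup <- function(compound, backend, protein = "", nSteps = 100L,
                       beta = 50, floorDrop = 0.02, seed = 1L) {
  set.seed(seed)
  conf0 <- predictConfidence(backend, protein, compound)
  floor_conf <- conf0 - floorDrop
  probs <- MOVE_KINDS
  probs[c("remove_atom", "change_atom_type")] <-
    2 * probs[c("remove_atom", "change_atom_type")]
  probs <- probs / sum(probs)
  objective <- function(mg) {
    conf <- predictConfidence(backend, protein, compound_from_mg(mg))
    if (conf < floor_conf) stop("below confidence floor")
    br <- composite_breakdown_mg(mg, conf)
    list(score = (0.1 * br$sa_norm + 0.05 * br$esol_norm + 0.05 * br$qed) / 0.2,
         confidence = conf)
  }
  res <- run_chain_mg(compound@graph, objective, as.integer(nSteps), beta,
                      reset = NA, probs = probs)
  list(state = mcstate_from_core(res), trajectory = res$trajectory)
}

#' Acceptance rate over a trajectory window
#'
#' Fraction of proposed steps accepted, reset records excluded.
#'
#' @param trajectory a trajectory data frame from a run function
#' @param from,to step window (defaults to the whole trajectory)
#' @return fraction in [0,1]
#' @export
acceptanceRate <- function(trajectory, from = -Inf, to = Inf) {
  tr <- trajectory[!trajectory$is_reset &
                     trajectory$step >= from & trajectory$step <= to, ]
  if (!nrow(tr)) stop("empty trajectory window")
  mean(tr$accepted)
}
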