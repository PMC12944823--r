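#' @import methods
NULL

#' Compound: a small organic molecule
#'
#' Carries the canonical SMILES together with an editable molecular graph
#' (heavy atoms, Kekule bond orders, implicit hydrogens).  Stereochemistry
#' is stripped on input and formal charges are neutralized; the graph always
#' passes chemical sanitization (valence rules) and has at least one heavy
#' atom.
#'
#' @slot smiles canonical SMILES string (no stereochemistry)
#' @slot graph internal molecular-graph representation
#' @exportClass Compound
setClass("Compound", representation(smiles = "character", graph = "list"),
         validity = function(object) {
           if (length(object@smiles) != 1L || !nzchar(object@smiles))
             return("smiles must be a single non-empty string")
           if (!mg_sanitize_ok(object@graph))
             return("molecular graph fails sanitization")
           TRUE
         })

#' MoveSet: the catalogue of chemical moves and their probabilities
#'
#' @slot kinds move kind names
#' @slot probs selection probabilities (non-negative, summing to one)
#' @exportClass MoveSet
setClass("MoveSet", representation(kinds = "character", probs = "numeric"),
         validity = function(object) {
           if (length(object@kinds) != length(object@probs))
             return("kinds and probs differ in length")
           if (!all(object@kinds %in% names(MOVE_KINDS)))
             return("unknown move kind")
           if (any(object@probs < 0)) return("negative probability")
           if (abs(sum(object@probs) - 1) > 1e-9)
             return("probabilities must sum to 1")
           TRUE
         })

#' MoveOutcome: result of applying a chemical move
#'
#' @slot compound the resulting (or, if infeasible, the input) Compound
#' @slot moveKind which operator was applied
#' @slot feasible whether a valid edit was found
#' @slot detail human-readable description of the edit
#' @exportClass MoveOutcome
setClass("MoveOutcome", representation(compound = "Compound",
                                       moveKind = "character",
                                       feasible = "logical",
                                       detail = "character"))

#' ScoreBreakdown: per-component record of the composite score
#'
#' @slot confidence backend confidence in [0,1]
#' @slot saRaw synthetic accessibility on the 1-10 scale
#' @slot saNorm normalized SA in [0,1]
#' @slot esolRaw estimated log10 aqueous solubility (mol/L)
#' @slot esolNorm normalized ESOL in [0,1]
#' @slot qed drug-likeness (molecular-weight term omitted) in [0,1]
#' @slot composite the weighted composite in [0,1]
#' @exportClass ScoreBreakdown
setClass("ScoreBreakdown", representation(confidence = "numeric",
                                          saRaw = "numeric", saNorm = "numeric",
                                          esolRaw = "numeric", esolNorm = "numeric",
                                          qed = "numeric", composite = "numeric"))

#' CompositeWeights: weights of the composite objective
#'
#' @slot wConf,wSa,wEsol,wQed non-negative weights summing to one
#' @exportClass CompositeWeights
setClass("CompositeWeights", representation(wConf = "numeric", wSa = "numeric",
                                            wEsol = "numeric", wQed = "numeric"),
         validity = function(object) {
           w <- c(object@wConf, object@wSa, object@wEsol, object@wQed)
           if (any(w < 0)) return("weights must be non-negative")
           if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1")
           TRUE
         })

#' PredictorBackend: contract for protein-ligand structure-prediction
#' confidence scorers
#'
#' Implementations provide \code{predictConfidence(backend, protein, smiles)}
#' returning a deterministic confidence in [0,1] (and optionally a predicted
#' complex structure).  Real co-folding models are wrapped behind this
#' contract; the package ships a deterministic mock for desk-scale work.
#'
#' @exportClass PredictorBackend
setClass("PredictorBackend", representation("VIRTUAL"))

#' MockBackend: deterministic descriptor-based confidence landscape
#'
#' @slot optimum named descriptor vector at which confidence equals 1
#' @slot scales named descriptor scales controlling the falloff
#' @exportClass MockBackend
setClass("MockBackend", contains = "PredictorBackend",
         representation(optimum = "numeric", scales = "numeric"))

#' MCConfig: Monte Carlo run configuration
#'
#' @slot beta inverse temperature of the Metropolis rule
#' @slot nSteps number of MC steps
#' @slot resetInterval reset-to-best period (steps)
#' @slot moveSet the MoveSet used for proposals
#' @slot startSmiles starting compound
#' @slot seed integer master seed
#' @exportClass MCConfig
setClass("MCConfig", representation(beta = "numeric", nSteps = "integer",
                                    resetInterval = "integer",
                                    moveSet = "MoveSet",
                                    startSmiles = "character",
                                    seed = "integer"),
         validity = function(object) {
           if (object@beta <= 0) return("beta must be positive")
           if (object@nSteps < 0L) return("nSteps must be >= 0")
           if (object@resetInterval < 1L) return("resetInterval must be >= 1")
           TRUE
         })

#' MCState: state of a Monte Carlo chain
#'
#' @slot current current Compound
#' @slot currentScore its objective value
#' @slot best best-so-far Compound
#' @slot bestScore best objective value (non-decreasing over a run)
#' @slot step steps executed
#' @slot nProposed,nAccepted proposal/acceptance counters
#' @exportClass MCState
setClass("MCState", representation(current = "Compound", currentScore = "numeric",
                                   best = "Compound", bestScore = "numeric",
                                   step = "integer", nProposed = "integer",
                                   nAccepted = "integer"))

#' FragmentLibrary: BRICS fragments with attachment labels
#'
#' @slot fragments list of fragment graphs (attachment dummies labeled with
#'   BRICS link types)
#' @slot smiles fragment SMILES with labeled dummies
#' @exportClass FragmentLibrary
setClass("FragmentLibrary", representation(fragments = "list",
                                           smiles = "character"),
         validity = function(object) {
           if (!length(object@fragments)) return("library is empty")
           TRUE
         })

#' FragmentedCompound: an assembly with open attachment points
#'
#' @slot graph molecular graph possibly containing labeled dummies
#' @exportClass FragmentedCompound
setClass("FragmentedCompound", representation(graph = "list"),
         validity = function(object) {
           capped <- brics_cap(object@graph)
           if (!mg_sanitize_ok(capped))
             return("H-capped assembly fails sanitization")
           TRUE
         })
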