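# Constructors, accessors and show methods for the user-facing classes.

#' Create a Compound from SMILES
#'
#' Parses SMILES (stereochemistry stripped, charges neutralized), sanitizes
#' the molecular graph and canonicalizes.  The canonical SMILES round-trips:
#' parsing it again yields the same string.
#'
#' @param smiles a SMILES string
#' @return a \linkS4class{Compound}
#' @examples
#' benzene <- parseSmiles("c1ccccc1")
#' smiles(benzene)
#' @export
parseSmiles <- function(smiles) {
  mg <- parse_smiles_mg(smiles)
  if (!mg_sanitize_ok(mg)) stop("molecule failed sanitization: ", smiles)
  new("Compound", smiles = mg_canonical_smiles(mg), graph = mg)
}

compound_from_mg <- function(mg) {
  new("Compound", smiles = mg_canonical_smiles(mg), graph = mg)
}

#' @rdname parseSmiles
#' @param x a Compound
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' @rdname parseSmiles
#' @export
setMethod("smiles", "Compound", function(x) x@smiles)

#' Number of heavy atoms
#' @param x a Compound or FragmentedCompound
#' @export
setGeneric("numAtoms", function(x) standardGeneric("numAtoms"))

#' @rdname numAtoms
#' @export
setMethod("numAtoms", "Compound", function(x) mg_natoms(x@graph))

#' @rdname numAtoms
#' @export
setMethod("numAtoms", "FragmentedCompound",
          function(x) sum(x@graph$elem != "*"))

#' Molecular weight (implicit hydrogens included)
#' @param x a Compound
#' @export
setGeneric("molWeight", function(x) standardGeneric("molWeight"))

#' @rdname molWeight
#' @export
setMethod("molWeight", "Compound", function(x) mg_molwt(x@graph))

setMethod("show", "Compound", function(object) {
  cat("Compound:", object@smiles, "\n")
  cat("  heavy atoms:", mg_natoms(object@graph),
      " bonds:", mg_nbonds(object@graph),
      " MW:", round(mg_molwt(object@graph), 2), "\n")
})

#' The standard move catalogue
#'
#' The nine elementary chemical moves with their standard selection
#' probabilities (add group .3, remove atom .2, change atom type .1, add
#' atom in chain .15, change bond type .025, form ring .025, break ring
#' .05, toggle aromatic .05, rearrange bonds .1).
#'
#' @param probs optional named numeric vector overriding the probabilities
#' @return a \linkS4class{MoveSet}
#' @examples
#' defaultMoveSet()
#' @export
defaultMoveSet <- function(probs = NULL) {
  p <- MOVE_KINDS
  if (!is.null(probs)) {
    if (is.null(names(probs)) || !all(names(probs) %in% names(MOVE_KINDS)))
      stop("probs must be named by move kind")
    p[names(probs)] <- probs
  }
  new("MoveSet", kinds = names(p), probs = unname(p))
}

#' @rdname defaultMoveSet
#' @param x a MoveSet
#' @export
setGeneric("moveProbabilities", function(x) standardGeneric("moveProbabilities"))

#' @rdname defaultMoveSet
#' @export
setMethod("moveProbabilities", "MoveSet", function(x) {
  p <- x@probs
  names(p) <- x@kinds
  p
})

setMethod("show", "MoveSet", function(object) {
  cat("MoveSet of", length(object@kinds), "chemical moves:\n")
  for (i in seq_along(object@kinds))
    cat(sprintf("  %-18s %.3f\n", object@kinds[i], object@probs[i]))
})

setMethod("show", "MoveOutcome", function(object) {
  cat("MoveOutcome:", object@moveKind,
      if (object@feasible) "(feasible)" else "(infeasible)", "\n")
  if (nzchar(object@detail)) cat("  ", object@detail, "\n")
  cat("  compound:", object@compound@smiles, "\n")
})

#' Composite-score weights
#'
#' Defaults to the standard combination 0.8 confidence + 0.1 SA +
#' 0.05 ESOL + 0.05 QED.
#'
#' @param wConf,wSa,wEsol,wQed non-negative weights summing to 1
#' @return a \linkS4class{CompositeWeights}
#' @export
compositeWeights <- function(wConf = 0.8, wSa = 0.1, wEsol = 0.05,
                             wQed = 0.05) {
  new("CompositeWeights", wConf = wConf, wSa = wSa, wEsol = wEsol, wQed = wQed)
}

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf(paste0("ScoreBreakdown: composite %.4f\n",
                     "  confidence %.4f | SA %.3f (norm %.3f) | ",
                     "ESOL %.3f (norm %.3f) | QED %.3f\n"),
              object@composite, object@confidence, object@saRaw, object@saNorm,
              object@esolRaw, object@esolNorm, object@qed))
})

setMethod("show", "MCState", function(object) {
  cat("MCState at step", object@step, "\n")
  cat(sprintf("  current: %s (%.4f)\n", object@current@smiles, object@currentScore))
  cat(sprintf("  best:    %s (%.4f)\n", object@best@smiles, object@bestScore))
  cat(sprintf("  acceptance: %d/%d (%.3f)\n", object@nAccepted, object@nProposed,
              if (object@nProposed > 0) object@nAccepted / object@nProposed else NA))
})

#' Acceptance ratio of a chain state
#' @param x an MCState
#' @export
setGeneric("acceptanceRatio", function(x) standardGeneric("acceptanceRatio"))

#' @rdname acceptanceRatio
#' @export
setMethod("acceptanceRatio", "MCState", function(x) {
  if (x@nProposed == 0L) return(NA_real_)
  x@nAccepted / x@nProposed
})

#' Best compound of a state
#' @param x an MCState
#' @export
setGeneric("bestCompound", function(x) standardGeneric("bestCompound"))

#' @rdname bestCompound
#' @export
setMethod("bestCompound", "MCState", function(x) x@best)

#' @rdname bestCompound
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))

#' @rdname bestCompound
#' @export
setMethod("bestScore", "MCState", function(x) x@bestScore)

setMethod("show", "FragmentLibrary", function(object) {
  cat("FragmentLibrary of", length(object@fragments), "BRICS fragments\n")
  n <- min(5L, length(object@smiles))
  for (i in seq_len(n)) cat("  ", object@smiles[i], "\n")
  if (length(object@smiles) > n) cat("  ...\n")
})

setMethod("show", "FragmentedCompound", function(object) {
  sites <- brics_open_sites(object@graph)
  cat("FragmentedCompound:", mg_write_smiles(object@graph), "\n")
  cat("  open attachment points:", if (is.null(sites)) 0L else nrow(sites), "\n")
})

#' Open attachment points of an assembly
#' @param x a FragmentedCompound
#' @return two-column matrix (dummy atom index, BRICS label), or NULL
#' @export
setGeneric("openSites", function(x) standardGeneric("openSites"))

#' @rdname openSites
#' @export
setMethod("openSites", "FragmentedCompound", function(x) brics_open_sites(x@graph))

#' H-cap an assembly into a Compound
#'
#' Replaces all open attachment points by implicit hydrogens.
#' @param x a FragmentedCompound
#' @return a \linkS4class{Compound}
#' @export
setGeneric("capAssembly", function(x) standardGeneric("capAssembly"))

#' @rdname capAssembly
#' @export
setMethod("capAssembly", "FragmentedCompound",
          function(x) compound_from_mg(brics_cap(x@graph)))
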