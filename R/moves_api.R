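# Exported wrappers around the chemical-move operators.  Each operator
# enumerates the feasible edits of its kind on the current molecule, draws
# one uniformly using R's RNG (seed with set.seed for reproducibility), and
# returns a MoveOutcome whose compound always sanitizes.

wrap_outcome <- function(out) {
  cp <- if (out$feasible) compound_from_mg(out$mg) else compound_from_mg(out$mg)
  new("MoveOutcome", compound = cp, moveKind = out$kind,
      feasible = out$feasible, detail = out$detail)
}

#' Elementary chemical moves
#'
#' The nine atomistic move operators: \code{addGroup} grafts a small
#' substituent (CH3, OH, NH2, halogen, =O, OCH3, SH, nitrile, CF3) at an
#' accessible position, replacing a hydrogen or occasionally a small
#' terminal group; \code{removeAtom} deletes a heavy atom (keeping the
#' largest fragment if the graph disconnects); \code{changeAtomType} swaps
#' an element; \code{addAtomInChain} inserts an atom into a bond;
#' \code{changeBondType} toggles a bond between single and double;
#' \code{formRing} closes a ring of 3-8 atoms; \code{breakRing} cuts a ring
#' bond (aromatic rings are kekulized first); \code{toggleAromatic}
#' aromatizes a ring when a valid Kekule assignment exists, or saturates an
#' aromatic ring; \code{rearrangeBonds} migrates a substituent from an atom
#' with more than two bonds to one of its neighbors.
#'
#' @param compound a \linkS4class{Compound}
#' @return a \linkS4class{MoveOutcome}; infeasible moves return the input
#'   compound with \code{feasible = FALSE}
#' @examples
#' set.seed(1)
#' addGroup(parseSmiles("c1ccccc1"))
#' @name moves
NULL

#' @rdname moves
#' @export
addGroup <- function(compound) wrap_outcome(move_add_group(compound@graph))

#' @rdname moves
#' @export
removeAtom <- function(compound) wrap_outcome(move_remove_atom(compound@graph))

#' @rdname moves
#' @export
changeAtomType <- function(compound)
  wrap_outcome(move_change_atom_type(compound@graph))

#' @rdname moves
#' @export
addAtomInChain <- function(compound)
  wrap_outcome(move_add_atom_in_chain(compound@graph))

#' @rdname moves
#' @export
changeBondType <- function(compound)
  wrap_outcome(move_change_bond_type(compound@graph))

#' @rdname moves
#' @export
formRing <- function(compound) wrap_outcome(move_form_ring(compound@graph))

#' @rdname moves
#' @export
breakRing <- function(compound) wrap_outcome(move_break_ring(compound@graph))

#' @rdname moves
#' @export
toggleAromatic <- function(compound)
  wrap_outcome(move_toggle_aromatic(compound@graph))

#' @rdname moves
#' @export
rearrangeBonds <- function(compound)
  wrap_outcome(move_rearrange_bonds(compound@graph))

#' Propose one move drawn from a MoveSet
#'
#' Draws a move kind by its probability and applies it; on infeasibility the
#' kind and site are redrawn up to \code{maxRetries} times.  A fully
#' infeasible proposal returns the input with \code{feasible = FALSE} and is
#' counted as a rejected step by the engine.
#'
#' @param compound a \linkS4class{Compound}
#' @param moveSet a \linkS4class{MoveSet} (default: the standard catalogue)
#' @param maxRetries redraw attempts before giving up
#' @return a \linkS4class{MoveOutcome}
#' @examples
#' set.seed(7)
#' proposeMove(parseSmiles("c1ccccc1"))
#' @export
proposeMove <- function(compound, moveSet = defaultMoveSet(),
                        maxRetries = 25L) {
  probs <- moveProbabilities(moveSet)
  wrap_outcome(propose_mg(compound@graph, probs = probs,
                          max_retries = maxRetries))
}
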