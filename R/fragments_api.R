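# Exported fragment surface: BRICS decomposition, library handling and the
# two fragment-level moves, plus the fragment MC protocol.

#' BRICS decomposition
#'
#' Cleaves every bond matching a permitted BRICS link-type pair, replacing
#' it by two labeled attachment dummies.  Reassembling the fragments along
#' compatible labels regenerates the input constitution (7-7 cuts keep
#' their double bond on the dummy, so reassembly is exact).
#'
#' @param compound a \linkS4class{Compound}
#' @return a \linkS4class{FragmentLibrary} of the fragments (a molecule
#'   with no cleavable bond yields itself as a single fragment)
#' @examples
#' bricsDecompose(parseSmiles("c1ccccc1"))
#' @export
bricsDecompose <- function(compound) {
  frags <- brics_decompose_mg(compound@graph)
  new("FragmentLibrary", fragments = frags,
      smiles = vapply(frags, mg_write_smiles, character(1)))
}

#' Build a fragment library from several compounds
#'
#' Decomposes each compound and pools the unique fragments.
#'
#' @param compounds list of \linkS4class{Compound}s
#' @return a \linkS4class{FragmentLibrary}
#' @export
fragmentLibraryFromCompounds <- function(compounds) {
  frags <- list(); keys <- character(0)
  for (cp in compounds) {
    for (fr in brics_decompose_mg(cp@graph)) {
      key <- mg_canonical_smiles(fr)
      if (key %in% keys) next
      keys <- c(keys, key)
      frags[[length(frags) + 1L]] <- fr
    }
  }
  new("FragmentLibrary", fragments = frags,
      smiles = vapply(frags, mg_write_smiles, character(1)))
}

#' Number of fragments in a library
#' @param x a FragmentLibrary
#' @export
setGeneric("numFragments", function(x) standardGeneric("numFragments"))

#' @rdname numFragments
#' @export
setMethod("numFragments", "FragmentLibrary", function(x) length(x@fragments))

#' Pick a random starting fragment
#'
#' Uniformly draws one library fragment as the initial assembly.
#'
#' @param library a \linkS4class{FragmentLibrary}
#' @return a \linkS4class{FragmentedCompound}
#' @export
randomFragmentStart <- function(library) {
  i <- sample.int(length(library@fragments), 1L)
  new("FragmentedCompound", graph = library@fragments[[i]])
}

# internal fragment moves on graphs -----------------------------------------

frag_add_mg <- function(asm, lib_frags) {
  sites <- brics_open_sites(asm)
  if (is.null(sites)) return(NULL)
  site_row <- sites[sample.int(nrow(sites), 1L), , drop = TRUE]
  lab <- site_row[2]
  cand <- which(vapply(lib_frags, function(fr)
    any(vapply(fr$label[fr$elem == "*"], brics_compatible, logical(1), i = lab)),
    logical(1)))
  if (!length(cand)) return(NULL)
  fr <- lib_frags[[cand[sample.int(length(cand), 1L)]]]
  fsites <- brics_open_sites(fr)
  ok <- fsites[vapply(fsites[, 2], brics_compatible, logical(1), i = lab), ,
               drop = FALSE]
  fs <- ok[sample.int(nrow(ok), 1L), , drop = TRUE]
  out <- brics_join(asm, site_row[1], fr, fs[1])
  if (!mg_sanitize_ok(brics_cap(out))) return(NULL)
  out
}

frag_remove_mg <- function(asm) {
  bb <- brics_bonds(asm)
  if (is.null(bb)) return(NULL)
  r <- bb[sample.int(nrow(bb), 1L), , drop = TRUE]
  cut <- brics_cut_bond(asm, r[1], r[2], r[3])
  comp <- mg_components(cut)
  sizes <- vapply(unique(comp), function(cid)
    sum(cut$elem[comp == cid] != "*"), integer(1))
  keep_ids <- unique(comp)[sizes == max(sizes)]
  if (length(keep_ids) > 1L) {
    keys <- vapply(keep_ids, function(cid)
      mg_write_smiles(mg_subset(cut, which(comp == cid))), character(1))
    keep_ids <- keep_ids[order(keys)][1]
  }
  mg_subset(cut, which(comp == keep_ids[1]))
}

#' Fragment-level moves
#'
#' \code{addFragment} picks a random open attachment point and bonds a
#' label-compatible library fragment there; \code{removeFragment} cuts a
#' random inter-fragment (BRICS-cleavable) bond, keeps the larger side and
#' leaves a labeled placeholder in place of the removed part.
#'
#' @param assembly a \linkS4class{FragmentedCompound}
#' @param library a \linkS4class{FragmentLibrary}
#' @return the new \linkS4class{FragmentedCompound}, or the unchanged input
#'   with attribute \code{feasible=FALSE} when no move exists
#' @name fragmentMoves
NULL

#' @rdname fragmentMoves
#' @export
addFragment <- function(assembly, library) {
  out <- frag_add_mg(assembly@graph, library@fragments)
  if (is.null(out)) {
    res <- assembly
    attr(res, "feasible") <- FALSE
    return(res)
  }
  res <- new("FragmentedCompound", graph = out)
  attr(res, "feasible") <- TRUE
  res
}

#' @rdname fragmentMoves
#' @export
removeFragment <- function(assembly) {
  out <- frag_remove_mg(assembly@graph)
  if (is.null(out)) {
    res <- assembly
    attr(res, "feasible") <- FALSE
    return(res)
  }
  res <- new("FragmentedCompound", graph = out)
  attr(res, "feasible") <- TRUE
  res
}

#' Fragment-recombination Monte Carlo
#'
#' Evolves an assembly by adding (probability \code{pAdd}) and removing
#' fragments under the Metropolis rule, scoring the H-capped assembly.
#' Defaults follow the fragment protocol: 500 steps, beta = 5, p(add) = .6,
#' reset-to-best every 50 steps, start from a random library fragment.
#'
#' @param library a \linkS4class{FragmentLibrary}
#' @param objective function(Compound) -> numeric, higher is better
#' @param nSteps,beta,resetInterval,pAdd protocol parameters
#' @param seed integer seed
#' @param start optional \linkS4class{FragmentedCompound} starting assembly
#' @param earlyStop stop once the best score reaches this value
#' @return list(best (Compound), bestScore, trajectory, nAccepted, nProposed)
#' @export
runFragmentMC <- function(library, objective, nSteps = 500L, beta = 5,
                          resetInterval = 50L, pAdd = 0.6, seed = 1L,
                          start = NULL, earlyStop = Inf) {
  set.seed(seed)
  if (is.null(start)) start <- randomFragmentStart(library)
  asm <- start@graph
  score_of <- function(g) objective(compound_from_mg(brics_cap(g)))
  s_cur <- score_of(asm)
  best <- list(g = asm, s = s_cur)
  nprop <- 0L; nacc <- 0L
  rows <- list()
  for (i in seq_len(nSteps)) {
    kind <- if (stats::runif(1) < pAdd) "add_fragment" else "remove_fragment"
    prop <- if (kind == "add_fragment") frag_add_mg(asm, library@fragments)
            else frag_remove_mg(asm)
    nprop <- nprop + 1L
    accepted <- FALSE; s_new <- NA_real_
    if (!is.null(prop)) {
      s_new <- tryCatch(score_of(prop), error = function(e) NA_real_)
      if (is.finite(s_new) && metropolisAccept(s_new, s_cur, beta)) {
        accepted <- TRUE; nacc <- nacc + 1L
        asm <- prop; s_cur <- s_new
        if (s_new > best$s) best <- list(g = asm, s = s_new)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      step = i, smiles = mg_write_smiles(asm), move_kind = kind,
      score = s_new, accepted = accepted, is_reset = FALSE,
      stringsAsFactors = FALSE)
    if (best$s >= earlyStop) break
    if (i %% resetInterval == 0L && s_cur < best$s) {
      asm <- best$g; s_cur <- best$s
      rows[[length(rows) + 1L]] <- data.frame(
        step = i, smiles = mg_write_smiles(asm), move_kind = "reset",
        score = s_cur, accepted = TRUE, is_reset = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  list(best = compound_from_mg(brics_cap(best$g)), bestScore = best$s,
       trajectory = do.call(rbind, rows), nAccepted = nacc, nProposed = nprop)
}
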