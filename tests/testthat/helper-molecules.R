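# shared fixtures built in code

benzene <- parseSmiles("c1ccccc1")
toluene <- parseSmiles("Cc1ccccc1")
cyclohexane <- parseSmiles("C1CCCCC1")
ethane <- parseSmiles("CC")
methane <- parseSmiles("C")

# enumerate the distinct feasible outcomes of a move operator by repeated
# seeded application (brute-force generator used as oracle)
enumerate_outcomes <- function(op, compound, tries = 400L, seed = 1L) {
  set.seed(seed)
  out <- character(0)
  for (i in seq_len(tries)) {
    r <- op(compound)
    if (r@feasible) out <- c(out, smiles(r@compound))
  }
  unique(out)
}

# guided reassembly of a fragment set: backtracking join search for an
# assembly whose H-capped constitution equals the target (filling the first
# open site at each step is complete because every site must end up filled)
reassemble_fragments <- function(frags, target_smiles) {
  join_all <- function(asm, rest) {
    sites <- molmc:::brics_open_sites(asm)
    if (!length(rest)) {
      if (is.null(sites)) {
        capped <- molmc:::compound_from_mg(molmc:::brics_cap(asm))
        if (smiles(capped) == target_smiles) return(asm)
      }
      return(NULL)
    }
    if (is.null(sites)) return(NULL)
    si <- 1L
    for (fi in seq_along(rest)) {
      fs <- molmc:::brics_open_sites(rest[[fi]])
      if (is.null(fs)) next
      for (fj in seq_len(nrow(fs))) {
        if (!molmc:::brics_compatible(sites[si, 2], fs[fj, 2])) next
        cand <- molmc:::brics_join(asm, sites[si, 1], rest[[fi]], fs[fj, 1])
        res <- join_all(cand, rest[-fi])
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  join_all(frags[[1]], frags[-1])
}
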