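# Circular atom-environment identifiers (ECFP-style iterated neighborhood
# labels) used to key the shipped fragment-contribution tables for the
# synthetic-accessibility and logP models.  Keys are a function of this
# package's own atom invariants and are therefore stable across sessions;
# the shipped tables map key hashes to the published contribution values.

# deterministic 31-bit string hash (polynomial, exact in double arithmetic)
env_hash <- function(s) {
  h <- 0
  for (cd in utf8ToInt(s)) h <- (h * 31 + cd) %% 2147483647
  as.integer(h)
}

env_hash_vec <- function(v) vapply(v, env_hash, integer(1), USE.NAMES = FALSE)

# per-atom environment label strings for radii 0..radius
env_keys <- function(mg, radius = 2L, arom = mg_aromatic(mg)) {
  n <- mg_natoms(mg)
  h <- mg_implicit_h(mg)
  deg <- mg_degree(mg)
  ringb <- mg_ring_bonds(mg)
  in_ring <- logical(n)
  if (any(ringb)) in_ring[unique(c(mg$bi[ringb], mg$bj[ringb]))] <- TRUE
  lab <- paste0(mg$elem, deg, "H", h, ifelse(in_ring, "R", ""),
                ifelse(arom$atoms, "a", ""))
  out <- matrix("", n, radius + 1L)
  out[, 1] <- lab
  # neighbor lists with bond codes (aromatic bonds keyed 'a' so the label is
  # invariant to the Kekule assignment inside aromatic rings)
  nbr <- vector("list", n)
  for (k in seq_len(mg_nbonds(mg))) {
    code <- if (arom$bonds[k]) "a" else as.character(mg$bo[k])
    nbr[[mg$bi[k]]] <- rbind(nbr[[mg$bi[k]]], c(mg$bj[k], code))
    nbr[[mg$bj[k]]] <- rbind(nbr[[mg$bj[k]]], c(mg$bi[k], code))
  }
  cur <- lab
  for (r in seq_len(radius)) {
    nxt <- character(n)
    for (a in seq_len(n)) {
      nb <- nbr[[a]]
      if (is.null(nb)) { nxt[a] <- paste0(cur[a], "|"); next }
      parts <- paste0(nb[, 2], cur[as.integer(nb[, 1])])
      nxt[a] <- paste0(cur[a], "|", paste(sort(parts), collapse = ";"))
    }
    cur <- nxt
    out[, r + 1L] <- cur
  }
  out
}

# bond sets within radius r of each atom (for the environment deduplication
# rule used by the synthetic-accessibility fragment score)
env_bond_sets <- function(mg, D = mg_dist(mg), radius = 2L) {
  n <- mg_natoms(mg)
  m <- mg_nbonds(mg)
  sets <- vector("list", radius)
  for (r in seq_len(radius)) {
    sets[[r]] <- lapply(seq_len(n), function(a) {
      if (!m) return(integer(0))
      keep <- which(pmin(D[a, mg$bi], D[a, mg$bj]) <= r - 1L)
      keep
    })
  }
  sets
}
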