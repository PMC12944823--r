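# BRICS fragment decomposition and recombination.
#
# The 16 published BRICS link-type environments are implemented as graph
# predicates on the Kekule representation; a bond is cleavable when its two
# atoms match a permitted link-type pair.  Cutting replaces the bond by two
# labeled attachment dummies (element "*", label = the link type of the atom
# the dummy is attached to); fragments recombine only across permitted label
# pairs (7-7 joins re-form a double bond, all others a single bond).

BRICS_PAIRS <- matrix(c(
  1, 3,  1, 5,  1, 10,
  3, 4,  3, 13, 3, 14, 3, 15, 3, 16,
  4, 5,  4, 11,
  5, 12, 5, 14, 5, 16, 5, 13, 5, 15,
  6, 13, 6, 14, 6, 15, 6, 16,
  7, 7,
  8, 9,  8, 10, 8, 13, 8, 14, 8, 15, 8, 16,
  9, 13, 9, 14, 9, 15, 9, 16,
  10, 13, 10, 14, 10, 15, 10, 16,
  11, 13, 11, 14, 11, 15, 11, 16,
  13, 14, 13, 15, 13, 16,
  14, 14, 14, 15, 14, 16,
  15, 16,
  16, 16), ncol = 2, byrow = TRUE)

brics_compatible <- function(i, j) {
  any((BRICS_PAIRS[, 1] == i & BRICS_PAIRS[, 2] == j) |
        (BRICS_PAIRS[, 1] == j & BRICS_PAIRS[, 2] == i))
}

# per-atom BRICS link-type predicates; ctx carries precomputed graph facts
brics_context <- function(mg) {
  n <- mg_natoms(mg)
  m <- mg_nbonds(mg)
  arom <- mg_aromatic(mg)
  ringb <- mg_ring_bonds(mg)
  deg <- mg_degree(mg)
  adj <- mg_adj(mg)
  in_ring <- logical(n)
  if (any(ringb)) in_ring[unique(c(mg$bi[ringb], mg$bj[ringb]))] <- TRUE
  dbl <- integer(n); trp <- integer(n)
  dbl_o <- logical(n)   # has =O
  for (k in seq_len(m)) {
    if (mg$bo[k] == 2L) {
      dbl[mg$bi[k]] <- dbl[mg$bi[k]] + 1L; dbl[mg$bj[k]] <- dbl[mg$bj[k]] + 1L
      if (mg$elem[mg$bj[k]] == "O") dbl_o[mg$bi[k]] <- TRUE
      if (mg$elem[mg$bi[k]] == "O") dbl_o[mg$bj[k]] <- TRUE
    }
    if (mg$bo[k] == 3L) { trp[mg$bi[k]] <- trp[mg$bi[k]] + 1L; trp[mg$bj[k]] <- trp[mg$bj[k]] + 1L }
  }
  # single non-ring neighbors by element, per atom
  snr <- vector("list", n)
  for (k in seq_len(m)) {
    if (mg$bo[k] != 1L || ringb[k]) next
    snr[[mg$bi[k]]] <- c(snr[[mg$bi[k]]], mg$bj[k])
    snr[[mg$bj[k]]] <- c(snr[[mg$bj[k]]], mg$bi[k])
  }
  # in-ring neighbors
  rnb <- vector("list", n)
  for (k in seq_len(m)) {
    if (!ringb[k]) next
    rnb[[mg$bi[k]]] <- c(rnb[[mg$bi[k]]], mg$bj[k])
    rnb[[mg$bj[k]]] <- c(rnb[[mg$bj[k]]], mg$bi[k])
  }
  list(mg = mg, arom = arom, ringb = ringb, deg = deg, adj = adj,
       in_ring = in_ring, dbl = dbl, trp = trp, dbl_o = dbl_o,
       snr = snr, rnb = rnb)
}

brics_is <- function(ctx, a, type) {
  mg <- ctx$mg; el <- mg$elem[a]
  switch(as.character(type),
    "1" = el == "C" && ctx$deg[a] == 3L && ctx$dbl_o[a],
    "3" = el == "O" && ctx$deg[a] == 2L && !ctx$arom$atoms[a] &&
          any(mg$elem[ctx$snr[[a]]] == "C"),
    "4" = el == "C" && ctx$deg[a] >= 2L && ctx$dbl[a] == 0L && ctx$trp[a] == 0L &&
          any(mg$elem[ctx$snr[[a]]] == "C"),
    "5" = el == "N" && ctx$deg[a] >= 2L && ctx$dbl[a] == 0L && ctx$trp[a] == 0L &&
          !ctx$arom$atoms[a] &&
          all(mg$elem[ctx$adj[[a]]] %in% c("C", "S")) &&
          !(ctx$in_ring[a] && any(ctx$dbl_o[ctx$rnb[[a]]] & mg$elem[ctx$rnb[[a]]] == "C")),
    "6" = el == "C" && ctx$deg[a] == 3L && !ctx$in_ring[a] && ctx$dbl_o[a],
    "7" = el == "C" && ctx$deg[a] %in% c(2L, 3L) && !ctx$arom$atoms[a] &&
          any(mg$elem[ctx$adj[[a]]] == "C"),
    "8" = el == "C" && !ctx$in_ring[a] && ctx$deg[a] >= 2L &&
          ctx$dbl[a] == 0L && ctx$trp[a] == 0L,
    "9" = el == "N" && ctx$arom$atoms[a] && ctx$deg[a] >= 2L,
    "10" = el == "N" && ctx$in_ring[a] && !ctx$arom$atoms[a] &&
           any(ctx$dbl_o[ctx$rnb[[a]]] & mg$elem[ctx$rnb[[a]]] == "C") &&
           length(ctx$rnb[[a]]) >= 2L,
    "11" = el == "S" && ctx$deg[a] == 2L && !ctx$arom$atoms[a] &&
           any(mg$elem[ctx$snr[[a]]] == "C"),
    "12" = el == "S" && ctx$deg[a] == 4L && ctx$dbl[a] >= 2L,
    "13" = {
      rn <- ctx$rnb[[a]]
      rn_ali <- rn[!ctx$arom$atoms[rn]]
      el == "C" && ctx$in_ring[a] && !ctx$arom$atoms[a] &&
        any(mg$elem[rn_ali] %in% c("N", "O", "S")) &&
        sum(mg$elem[rn_ali] %in% c("C", "N", "O", "S")) >= 2L
    },
    "14" = el == "C" && ctx$arom$atoms[a] &&
           any(ctx$arom$atoms[ctx$rnb[[a]]] & mg$elem[ctx$rnb[[a]]] %in% c("N", "O", "S")),
    "15" = {
      rn <- ctx$rnb[[a]]
      el == "C" && ctx$in_ring[a] && !ctx$arom$atoms[a] &&
        sum(mg$elem[rn] == "C" & !ctx$arom$atoms[rn]) >= 2L
    },
    "16" = el == "C" && ctx$arom$atoms[a] &&
           sum(ctx$arom$atoms[ctx$rnb[[a]]] & mg$elem[ctx$rnb[[a]]] == "C") >= 2L,
    FALSE)
}

# order in which link-type pairs are tried for each bond (published rule
# ordering); first match labels the bond
BRICS_TRY_ORDER <- list(
  c(1, 3), c(1, 5), c(1, 10),
  c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
  c(4, 5), c(4, 11),
  c(5, 12), c(5, 14), c(5, 16), c(5, 13), c(5, 15),
  c(6, 13), c(6, 14), c(6, 15), c(6, 16),
  c(7, 7),
  c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
  c(9, 13), c(9, 14), c(9, 15), c(9, 16),
  c(10, 13), c(10, 14), c(10, 15), c(10, 16),
  c(11, 13), c(11, 14), c(11, 15), c(11, 16),
  c(13, 14), c(13, 15), c(13, 16),
  c(14, 14), c(14, 15), c(14, 16),
  c(15, 16),
  c(16, 16))

# all cleavable bonds with their link-type labels:
# matrix of (bond index, label at bi, label at bj)
brics_bonds <- function(mg, ctx = brics_context(mg)) {
  out <- NULL
  for (k in seq_len(mg_nbonds(mg))) {
    if (ctx$ringb[k]) next
    a <- mg$bi[k]; b <- mg$bj[k]
    if (mg$elem[a] == "*" || mg$elem[b] == "*") next
    for (pr in BRICS_TRY_ORDER) {
      want_double <- all(pr == 7)
      if (want_double && mg$bo[k] != 2L) next
      if (!want_double && mg$bo[k] != 1L) next
      if (brics_is(ctx, a, pr[1]) && brics_is(ctx, b, pr[2])) {
        out <- rbind(out, c(k, pr[1], pr[2])); break
      }
      if (brics_is(ctx, a, pr[2]) && brics_is(ctx, b, pr[1])) {
        out <- rbind(out, c(k, pr[2], pr[1])); break
      }
    }
  }
  out
}

# cut one labeled bond: replace a-b by a-[*i] and b-[*j]
brics_cut_bond <- function(mg, k, lab_i, lab_j) {
  a <- mg$bi[k]; b <- mg$bj[k]; o <- mg$bo[k]
  mg <- mg_remove_bond(mg, k)
  mg <- mg_add_atom(mg, "*", label = lab_i)
  mg <- mg_add_bond(mg, a, mg_natoms(mg), o)
  mg <- mg_add_atom(mg, "*", label = lab_j)
  mg_add_bond(mg, b, mg_natoms(mg), o)
}

# exhaustive decomposition: cut every cleavable bond, return fragment list
brics_decompose_mg <- function(mg) {
  bb <- brics_bonds(mg)
  if (is.null(bb)) return(list(mg))
  # cut from highest bond index down so indices stay valid
  ord <- order(-bb[, 1])
  for (r in ord) mg <- brics_cut_bond(mg, bb[r, 1], bb[r, 2], bb[r, 3])
  comp <- mg_components(mg)
  lapply(unique(comp), function(cid) mg_subset(mg, which(comp == cid)))
}

# open attachment points: (atom index of dummy, label)
brics_open_sites <- function(mg) {
  idx <- which(mg$elem == "*")
  if (!length(idx)) return(NULL)
  cbind(idx, mg$label[idx])
}

# join assembly dummy `site` with fragment dummy `fsite` (both atom indices
# into their own graphs); returns combined graph
brics_join <- function(asm, site, frag, fsite) {
  stopifnot(asm$elem[site] == "*", frag$elem[fsite] == "*")
  order <- if (asm$label[site] == 7L && frag$label[fsite] == 7L) 2L else 1L
  n0 <- mg_natoms(asm)
  anchor_a <- c(asm$bi[asm$bj == site], asm$bj[asm$bi == site])[1]
  anchor_f <- c(frag$bi[frag$bj == fsite], frag$bj[frag$bi == fsite])[1]
  comb <- mg_new(c(asm$elem, frag$elem), c(asm$bi, frag$bi + n0),
                 c(asm$bj, frag$bj + n0), c(asm$bo, frag$bo),
                 c(asm$label, frag$label))
  comb <- mg_add_bond(comb, anchor_a, anchor_f + n0, order)
  mg_remove_atoms(comb, c(site, fsite + n0))
}

# cap all open placeholders with hydrogen (i.e. delete the dummies; implicit
# H fills the freed valence)
brics_cap <- function(mg) {
  idx <- which(mg$elem == "*")
  if (!length(idx)) return(mg)
  mg_remove_atoms(mg, idx)
}

# H-capped canonical comparison helper
brics_frag_key <- function(mg) mg_write_smiles(mg)
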