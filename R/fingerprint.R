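# Atom-pair fingerprints (Carhart-style) and dice similarity.
#
# Every heavy-atom pair contributes one feature (type_i, type_j, topological
# distance); the fingerprint is the count multiset of such features.  Atom
# types combine element, heavy-atom degree (capped at 7) and pi-electron
# count (capped at 3, aromatic atoms counted as one pi electron), which makes
# the fingerprint invariant to atom ordering and to the Kekule assignment of
# aromatic rings.

AP_ELEM_IDX <- c(C = 1L, N = 2L, O = 3L, S = 4L, F = 5L, Cl = 6L, Br = 7L,
                 P = 8L, `*` = 9L)
AP_MAXDIST <- 30L

# integer-coded atom types
ap_atom_types <- function(mg, arom = mg_aromatic(mg)) {
  n <- mg_natoms(mg)
  deg <- pmin(mg_degree(mg), 7L)
  pi <- integer(n)
  for (k in seq_len(mg_nbonds(mg))) if (mg$bo[k] > 1L) {
    pi[mg$bi[k]] <- pi[mg$bi[k]] + mg$bo[k] - 1L
    pi[mg$bj[k]] <- pi[mg$bj[k]] + mg$bo[k] - 1L
  }
  pi[arom$atoms] <- 1L
  pi <- pmin(pi, 3L)
  (unname(AP_ELEM_IDX[mg$elem]) * 4L + pi) * 8L + deg
}

# sorted integer vector of pair codes (with multiplicity)
ap_fingerprint_mg <- function(mg) {
  n <- mg_natoms(mg)
  if (n < 2L) return(integer(0))
  types <- ap_atom_types(mg)
  D <- mg_dist(mg)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  keep <- !is.na(d) & d >= 1L & d <= AP_MAXDIST
  iu <- iu[keep, , drop = FALSE]
  d <- d[keep]
  t1 <- types[iu[, 1]]; t2 <- types[iu[, 2]]
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  sort.int((lo * 512L + hi) * 32L + d)
}

# dice on two sorted count multisets: 2*|intersection| / (|a|+|b|);
# run-length encoding keeps the multiset intersection fully vectorized
dice_codes <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la + lb == 0L) return(1.0)
  if (la == 0L || lb == 0L) return(0.0)
  ra <- rle(a); rb <- rle(b)
  m <- match(ra$values, rb$values)
  ok <- !is.na(m)
  inter <- sum(pmin(ra$lengths[ok], rb$lengths[m[ok]]))
  2 * inter / (la + lb)
}
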