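# Physicochemical descriptors feeding the solubility (ESOL) and
# drug-likeness (QED) models: rotatable bonds, topological polar surface
# area, hydrogen-bond donors/acceptors, aromatic rings and proportion.

# rotatable bonds, strict flavor: single non-ring bonds between two
# non-terminal heavy atoms, excluding atoms in triple bonds, trihalomethyl /
# tert-butyl carbons, and amide/ester/thioamide-type C(=X)-N/O/S linkages
count_rotatable_bonds <- function(mg, ringb = mg_ring_bonds(mg),
                                  arom = mg_aromatic(mg)) {
  m <- mg_nbonds(mg)
  if (!m) return(0L)
  n <- mg_natoms(mg)
  deg <- mg_degree(mg)
  in_triple <- logical(n)
  dbl_to <- vector("list", n)   # elements double-bonded (non-aromatic) to atom
  for (k in seq_len(m)) {
    if (mg$bo[k] == 3L) { in_triple[mg$bi[k]] <- TRUE; in_triple[mg$bj[k]] <- TRUE }
    if (arom$bonds[k]) next
    if (mg$bo[k] == 2L) {
      dbl_to[[mg$bi[k]]] <- c(dbl_to[[mg$bi[k]]], mg$elem[mg$bj[k]])
      dbl_to[[mg$bj[k]]] <- c(dbl_to[[mg$bj[k]]], mg$elem[mg$bi[k]])
    }
  }
  adj <- mg_adj(mg)
  # trihalomethyl / tert-butyl carbons act like terminal blobs
  blob <- vapply(seq_len(n), function(a) {
    if (mg$elem[a] != "C" || deg[a] < 4L) return(FALSE)
    term <- adj[[a]][deg[adj[[a]]] == 1L]
    els <- mg$elem[term]
    sum(els == "F") >= 3L || sum(els == "Cl") >= 3L || sum(els == "Br") >= 3L ||
      sum(els == "C") >= 3L
  }, logical(1))
  cnt <- 0L
  for (k in seq_len(m)) {
    if (mg$bo[k] != 1L || ringb[k]) next
    a <- mg$bi[k]; b <- mg$bj[k]
    if (deg[a] < 2L || deg[b] < 2L) next
    if (in_triple[a] || in_triple[b]) next
    if (blob[a] || blob[b]) next
    amide_like <- function(x, y) {
      # x = carbon with exocyclic double bond to N/O/S; y = N/O/S partner
      mg$elem[x] == "C" && deg[x] == 3L &&
        any(dbl_to[[x]] %in% c("N", "O", "S")) &&
        (mg$elem[y] == "N" || mg$elem[y] == "O" ||
           (mg$elem[y] == "S" && deg[y] > 1L))
    }
    if (amide_like(a, b) || amide_like(b, a)) next
    cnt <- cnt + 1L
  }
  cnt
}

# Ertl topological polar surface area, N/O contributions only
tpsa_mg <- function(mg, arom = mg_aromatic(mg)) {
  n <- mg_natoms(mg)
  h <- mg_implicit_h(mg)
  total <- 0
  m <- mg_nbonds(mg)
  rings3 <- Filter(function(r) length(r) == 3L, mg_rings(mg))
  in3ring <- logical(n)
  for (r in rings3) in3ring[r] <- TRUE
  for (a in seq_len(n)) {
    el <- mg$elem[a]
    if (el != "N" && el != "O") next
    # bond orders at atom, aromatic bonds counted separately
    s1 <- 0L; s2 <- 0L; s3 <- 0L; sa <- 0L
    for (k in seq_len(m)) {
      if (mg$bi[k] != a && mg$bj[k] != a) next
      if (arom$bonds[k]) sa <- sa + 1L
      else if (mg$bo[k] == 1L) s1 <- s1 + 1L
      else if (mg$bo[k] == 2L) s2 <- s2 + 1L
      else s3 <- s3 + 1L
    }
    hs <- h[a]
    contrib <- 0
    if (el == "O") {
      if (arom$atoms[a] && sa >= 2L) contrib <- 13.14
      else if (hs >= 1L) contrib <- 20.23
      else if (s2 >= 1L) contrib <- 17.07
      else if (in3ring[a]) contrib <- 12.53
      else contrib <- 9.23
    } else {
      if (arom$atoms[a] && sa >= 2L) {
        if (hs >= 1L) contrib <- 15.79
        else if (sa >= 3L) contrib <- 4.41
        else if (s1 >= 1L) contrib <- 4.93
        else if (s2 >= 1L) contrib <- 8.39
        else contrib <- 12.89
      } else if (hs == 0L) {
        if (s3 >= 1L && s2 == 0L && s1 == 0L) contrib <- 23.79
        else if (s2 >= 2L) contrib <- 11.68
        else if (s3 >= 1L && s2 >= 1L) contrib <- 13.60
        else if (s2 == 1L) contrib <- 12.36
        else if (in3ring[a]) contrib <- 3.01
        else contrib <- 3.24
      } else if (hs == 1L) {
        if (s2 >= 1L) contrib <- 23.85
        else if (in3ring[a]) contrib <- 21.94
        else contrib <- 12.03
      } else contrib <- 26.02
    }
    total <- total + contrib
  }
  total
}

# aromatic proportion: fraction of heavy atoms flagged aromatic
aromatic_proportion <- function(mg, arom = mg_aromatic(mg)) {
  if (!mg_natoms(mg)) return(0)
  sum(arom$atoms) / mg_natoms(mg)
}

# number of fully aromatic SSSR rings
count_aromatic_rings <- function(mg, arom = mg_aromatic(mg)) {
  rings <- mg_rings(mg)
  if (!length(rings)) return(0L)
  sum(vapply(rings, function(r) all(arom$atoms[r]), logical(1)))
}

# hydrogen-bond donors: N-H, O-H and S-H bearing heavy atoms, counted once
# per atom
count_hbd <- function(mg) {
  h <- mg_implicit_h(mg)
  sum(h >= 1L & mg$elem %in% c("N", "O", "S"), na.rm = TRUE)
}

# hydrogen-bond acceptors following the QED acceptor pattern set
count_hba <- function(mg, arom = mg_aromatic(mg)) {
  n <- mg_natoms(mg)
  h <- mg_implicit_h(mg)
  deg <- mg_degree(mg)
  bs <- mg_bondsum(mg)
  m <- mg_nbonds(mg)
  dbl_cnt <- integer(n); trp_cnt <- integer(n)
  nbr_amide <- logical(n)  # N bonded to C=O or S=O
  adj <- mg_adj(mg)
  for (k in seq_len(m)) {
    if (mg$bo[k] == 2L) { dbl_cnt[mg$bi[k]] <- dbl_cnt[mg$bi[k]] + 1L
                          dbl_cnt[mg$bj[k]] <- dbl_cnt[mg$bj[k]] + 1L }
    if (mg$bo[k] == 3L) { trp_cnt[mg$bi[k]] <- trp_cnt[mg$bi[k]] + 1L
                          trp_cnt[mg$bj[k]] <- trp_cnt[mg$bj[k]] + 1L }
  }
  has_xdbl_o <- logical(n)  # atom is C/S carrying =O (or =S) double bond
  for (k in seq_len(m)) if (mg$bo[k] == 2L) {
    i <- mg$bi[k]; j <- mg$bj[k]
    if (mg$elem[i] %in% c("C", "S") && mg$elem[j] %in% c("O", "S")) has_xdbl_o[i] <- TRUE
    if (mg$elem[j] %in% c("C", "S") && mg$elem[i] %in% c("O", "S")) has_xdbl_o[j] <- TRUE
  }
  cnt <- 0L
  for (a in seq_len(n)) {
    el <- mg$elem[a]
    if (el == "O") {
      if (arom$atoms[a]) cnt <- cnt + 1L                     # [oH0;X2]
      else if (h[a] == 1L) cnt <- cnt + 1L                   # hydroxyl
      else if (h[a] == 0L && deg[a] == 2L) cnt <- cnt + 1L   # ether
      else if (h[a] == 0L && deg[a] == 1L && dbl_cnt[a] >= 1L) cnt <- cnt + 1L  # carbonyl O
    } else if (el == "S") {
      if (arom$atoms[a]) next                                # aromatic s not in list
      if (h[a] == 0L && bs[a] == 2L) cnt <- cnt + 1L         # thioether / thione S(v2)
    } else if (el == "N") {
      if (arom$atoms[a]) {
        if (h[a] == 0L && deg[a] == 2L) cnt <- cnt + 1L      # pyridine-type n
      } else if (trp_cnt[a] >= 1L && deg[a] == 1L) {
        cnt <- cnt + 1L                                      # nitrile N
      } else if (dbl_cnt[a] == 0L && trp_cnt[a] == 0L) {
        # amine N (X3 counts H): exclude N-C=O / N-S=O
        if (deg[a] + h[a] == 3L && !any(has_xdbl_o[adj[[a]]])) cnt <- cnt + 1L
      }
    }
  }
  cnt
}
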