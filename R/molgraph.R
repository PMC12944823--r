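# Internal molecular-graph machinery.
#
# Molecules are carried as plain lists ("mg"): heavy atoms only, implicit
# hydrogens, Kekule bond orders (1,2,3), neutral atoms.  This keeps the
# Monte Carlo hot loop free of external library calls; OpenBabel (via
# ChemmineOB) is used only at the boundaries for SMILES parsing and
# canonicalization.
#
#   mg$elem  character(n)  element symbols ("C","N","O","S","F","Cl","Br","P",
#                          or "*" for a fragment attachment dummy)
#   mg$label integer(n)    BRICS link-type label for dummies, 0 otherwise
#   mg$bi, mg$bj integer(m) bond endpoints (1-based, bi < bj)
#   mg$bo    integer(m)    bond order

MG_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "P", "*")

# allowed valence states per element (lowest state used to fill implicit H)
MG_VALENCES <- list(
  C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L,
  P = c(3L, 5L), `*` = 1L
)

MG_MASS <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, F = 18.998,
  Cl = 35.45, Br = 79.904, P = 30.974, `*` = 0, H = 1.008
)

mg_new <- function(elem, bi = integer(0), bj = integer(0), bo = integer(0),
                   label = NULL) {
  if (is.null(label)) label <- integer(length(elem))
  swap <- bi > bj
  if (any(swap)) {
    tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  }
  list(elem = as.character(elem), label = as.integer(label),
       bi = as.integer(bi), bj = as.integer(bj), bo = as.integer(bo))
}

mg_natoms <- function(mg) length(mg$elem)
mg_nbonds <- function(mg) length(mg$bi)

# sum of bond orders per atom
mg_bondsum <- function(mg) {
  bs <- integer(mg_natoms(mg))
  if (mg_nbonds(mg)) {
    agg <- rowsum(c(mg$bo, mg$bo), c(mg$bi, mg$bj), reorder = FALSE)
    bs[as.integer(rownames(agg))] <- as.integer(agg)
  }
  bs
}

mg_degree <- function(mg) {
  d <- integer(mg_natoms(mg))
  if (mg_nbonds(mg)) {
    tb <- tabulate(c(mg$bi, mg$bj), nbins = mg_natoms(mg))
    d <- tb
  }
  d
}

MG_BASEVAL <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L,
                P = 3L, `*` = 1L)

# implicit hydrogen count per atom; NA where no allowed valence state fits.
# S may expand to valence 4/6 and P to 5 (hypervalent states carry no H)
mg_implicit_h <- function(mg, bondsum = mg_bondsum(mg)) {
  val <- unname(MG_BASEVAL[mg$elem])
  h <- val - bondsum
  s <- mg$elem == "S" & bondsum > 2L
  if (any(s)) h[s] <- ifelse(bondsum[s] <= 4L, 4L - bondsum[s],
                             ifelse(bondsum[s] <= 6L, 6L - bondsum[s], NA_integer_))
  p <- mg$elem == "P" & bondsum > 3L
  if (any(p)) h[p] <- ifelse(bondsum[p] <= 5L, 5L - bondsum[p], NA_integer_)
  # attachment dummies never carry hydrogens; 7-labeled BRICS dummies sit on
  # a double bond
  du <- mg$elem == "*"
  if (any(du)) h[du] <- ifelse(bondsum[du] <= 2L, 0L, NA_integer_)
  h[h < 0L] <- NA_integer_
  as.integer(h)
}

# chemical sanitization: valences satisfiable, sane bond table
mg_sanitize_ok <- function(mg, require_connected = TRUE) {
  n <- mg_natoms(mg)
  if (n < 1L) return(FALSE)
  if (!all(mg$elem %in% MG_ELEMENTS)) return(FALSE)
  m <- mg_nbonds(mg)
  if (m) {
    if (any(mg$bi < 1L | mg$bj > n | mg$bi == mg$bj)) return(FALSE)
    if (any(!mg$bo %in% 1:3)) return(FALSE)
    if (anyDuplicated(paste(mg$bi, mg$bj))) return(FALSE)
  }
  if (anyNA(mg_implicit_h(mg))) return(FALSE)
  if (require_connected && length(unique(mg_components(mg))) > 1L) return(FALSE)
  TRUE
}

mg_adj <- function(mg) {
  n <- mg_natoms(mg)
  adj <- vector("list", n)
  for (k in seq_len(mg_nbonds(mg))) {
    adj[[mg$bi[k]]] <- c(adj[[mg$bi[k]]], mg$bj[k])
    adj[[mg$bj[k]]] <- c(adj[[mg$bj[k]]], mg$bi[k])
  }
  adj
}

mg_components <- function(mg) {
  as.integer(cpp_components(mg_natoms(mg), mg$bi, mg$bj))
}

# all-pairs topological distances via boolean matrix expansion
mg_dist <- function(mg, maxd = 64L) {
  cpp_dist(mg_natoms(mg), mg$bi, mg$bj)
}

# ring bonds: bonds lying on some cycle, i.e. non-bridges (iterative DFS
# lowlink bridge finding)
mg_ring_bonds <- function(mg) {
  cpp_ring_bonds(mg_natoms(mg), mg$bi, mg$bj)
}

# smallest-set-of-smallest-rings style perception: for every non-tree edge,
# the shortest cycle through it (deduplicated)
mg_rings <- function(mg, maxsize = 24L) {
  if (!mg_nbonds(mg) || mg_natoms(mg) < 3L) return(list())
  cpp_rings(mg_natoms(mg), mg$bi, mg$bj, as.integer(maxsize))
}

# index of bond between atoms a and b, or 0
mg_bond_index <- function(mg, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  w <- which(mg$bi == lo & mg$bj == hi)
  if (length(w)) w[1] else 0L
}

# Aromaticity perception on the Kekule graph (Hueckel-style electron count).
# Candidate rings: SSSR rings plus unions of fused ring pairs (to catch
# systems such as indolizine whose individual SSSR rings are ambiguous).
# Returns list(atoms = logical(n), bonds = logical(m), rings = list of rings
# perceived aromatic).
mg_aromatic <- function(mg) {
  n <- mg_natoms(mg)
  m <- mg_nbonds(mg)
  out <- list(atoms = logical(n), bonds = logical(m), rings = list())
  rings <- mg_rings(mg)
  if (!length(rings)) return(out)
  # fused pair unions (perimeter cycles)
  cand <- rings
  if (length(rings) > 1L) {
    for (a in seq_len(length(rings) - 1L)) for (b in (a + 1L):length(rings)) {
      shared <- intersect(rings[[a]], rings[[b]])
      if (length(shared) >= 2L) {
        per <- union(rings[[a]], rings[[b]])
        cand[[length(cand) + 1L]] <- per
      }
    }
  }
  bsum <- mg_bondsum(mg)
  # per-atom multiple-bond info
  has_mult <- integer(n)        # number of double/triple bonds at atom
  for (k in seq_len(m)) if (mg$bo[k] > 1L) {
    has_mult[mg$bi[k]] <- has_mult[mg$bi[k]] + 1L
    has_mult[mg$bj[k]] <- has_mult[mg$bj[k]] + 1L
  }
  for (ring in cand) {
    ringset <- ring
    ok <- TRUE
    electrons <- 0L
    for (a in ringset) {
      # bonds from a: doubles inside ring vs exocyclic
      kin <- 0L; kex <- 0L; ktrip <- FALSE
      for (k in seq_len(m)) {
        if (mg$bi[k] != a && mg$bj[k] != a) next
        if (mg$bo[k] == 3L) ktrip <- TRUE
        if (mg$bo[k] <= 1L) next
        other <- if (mg$bi[k] == a) mg$bj[k] else mg$bi[k]
        if (other %in% ringset) kin <- kin + 1L else kex <- kex + 1L
      }
      if (ktrip) { ok <- FALSE; break }
      # cumulated centers (two double bonds) are sp, never aromatic
      if (kin + kex >= 2L) { ok <- FALSE; break }
      if (kin >= 1L) electrons <- electrons + 1L
      else if (kex >= 1L) electrons <- electrons + 0L
      else if (mg$elem[a] %in% c("N", "O", "S")) electrons <- electrons + 2L
      else { ok <- FALSE; break }
    }
    if (ok && electrons %% 4L == 2L) {
      out$rings[[length(out$rings) + 1L]] <- ring
      out$atoms[ring] <- TRUE
    }
  }
  if (any(out$atoms)) {
    ringb <- mg_ring_bonds(mg)
    for (cand in out$rings) {
      sel <- ringb & mg$bi %in% cand & mg$bj %in% cand
      out$bonds[sel] <- TRUE
    }
  }
  out
}

# ----- MOL (SDF) block I/O --------------------------------------------------

mg_to_molblock <- function(mg, title = "molmc") {
  n <- mg_natoms(mg); m <- mg_nbonds(mg)
  lines <- c(title, "  molmc", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    el <- if (mg$elem[i] == "*") "*" else mg$elem[i]
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, el))
  }
  for (k in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mg$bi[k], mg$bj[k], mg$bo[k]))
  }
  # BRICS labels carried as isotopes on dummy atoms
  iso <- which(mg$label > 0L)
  if (length(iso)) {
    for (i in iso) lines <- c(lines, sprintf("M  ISO  1%4d%4d", i, mg$label[i]))
  }
  lines <- c(lines, "M  END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated MOL block")
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  m <- as.integer(substr(counts, 4, 6))
  if (is.na(n) || n < 1L) stop("MOL block without atoms")
  elem <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[4 + i]
    elem[i] <- trimws(substr(ln, 32, 34))
  }
  bi <- bj <- bo <- integer(m)
  for (k in seq_len(m)) {
    ln <- lines[4 + n + k]
    bi[k] <- as.integer(substr(ln, 1, 3))
    bj[k] <- as.integer(substr(ln, 4, 6))
    bo[k] <- as.integer(substr(ln, 7, 9))
  }
  label <- integer(n)
  charge <- integer(n)
  for (ln in lines[-seq_len(4 + n + m)]) {
    if (startsWith(ln, "M  ISO")) {
      cnt <- as.integer(substr(ln, 7, 9))
      for (e in seq_len(cnt)) {
        at <- as.integer(substr(ln, 10 + (e - 1) * 8, 13 + (e - 1) * 8))
        vl <- as.integer(substr(ln, 14 + (e - 1) * 8, 17 + (e - 1) * 8))
        label[at] <- vl
      }
    }
    if (startsWith(ln, "M  CHG")) {
      cnt <- as.integer(substr(ln, 7, 9))
      for (e in seq_len(cnt)) {
        at <- as.integer(substr(ln, 10 + (e - 1) * 8, 13 + (e - 1) * 8))
        vl <- as.integer(substr(ln, 14 + (e - 1) * 8, 17 + (e - 1) * 8))
        charge[at] <- vl
      }
    }
  }
  elem[elem %in% c("Du", "R", "R#", "A")] <- "*"
  mg <- mg_new(elem, bi, bj, bo, label)
  # neutralize: the mutation engine works on neutral atoms; charged input
  # (e.g. protonated amines, carboxylates) is stripped to the neutral parent
  mg
}

# aromatic (order 4) bonds in a MOL block are not produced by OpenBabel for
# our conversions, but guard anyway
normalize_molblock_orders <- function(mg) {
  if (any(mg$bo == 4L)) stop("aromatic bond orders in MOL block are not supported")
  mg
}

# drop explicit hydrogens (keep heavy atoms; H become implicit)
mg_strip_h <- function(mg) {
  keep <- which(mg$elem != "H")
  if (length(keep) == mg_natoms(mg)) return(mg)
  if (!length(keep)) stop("molecule has no heavy atom")
  idx <- integer(mg_natoms(mg)); idx[keep] <- seq_along(keep)
  kb <- which(mg$elem[mg$bi] != "H" & mg$elem[mg$bj] != "H")
  mg_new(mg$elem[keep], idx[mg$bi[kb]], idx[mg$bj[kb]], mg$bo[kb], mg$label[keep])
}

# ----- SMILES via OpenBabel -------------------------------------------------

ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) NA_character_)
  out
}

#' @importFrom ChemmineOB convertFormat
parse_smiles_mg <- function(smiles) {
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) stop("empty SMILES")
  mb <- ob_convert("SMI", "MOL", paste0(smiles, "\n"))
  if (is.na(mb) || !nzchar(mb) || !grepl("V2000", mb))
    stop(sprintf("SMILES '%s' could not be parsed", smiles))
  mg <- parse_molblock(mb)
  mg <- normalize_molblock_orders(mg)
  mg <- mg_strip_h(mg)
  if (!mg_sanitize_ok(mg, require_connected = FALSE))
    stop(sprintf("SMILES '%s' failed sanitization", smiles))
  mg
}

mg_canonical_smiles <- function(mg) {
  out <- ob_convert("MOL", "CAN", mg_to_molblock(mg))
  if (is.na(out)) stop("canonicalization failed")
  s <- strsplit(trimws(out), "[ \t]+")[[1]][1]
  if (is.na(s) || !nzchar(s)) stop("canonicalization produced no output")
  s
}

# ----- fast internal SMILES writer (Kekule, non-canonical) ------------------

mg_write_smiles <- function(mg) {
  n <- mg_natoms(mg)
  adjk <- vector("list", n)
  for (k in seq_len(mg_nbonds(mg))) {
    adjk[[mg$bi[k]]] <- rbind(adjk[[mg$bi[k]]], c(mg$bj[k], mg$bo[k]))
    adjk[[mg$bj[k]]] <- rbind(adjk[[mg$bj[k]]], c(mg$bi[k], mg$bo[k]))
  }
  visited <- logical(n)
  ring_id <- 0L
  open_ring <- list()   # per atom: ring closure digits with bond orders
  # first pass: find ring-closure bonds via DFS tree
  parent <- integer(n)
  closure <- list()
  order_sym <- c("", "=", "#")
  atom_token <- function(i) {
    el <- mg$elem[i]
    if (el == "*") {
      if (mg$label[i] > 0L) sprintf("[%d*]", mg$label[i]) else "[*]"
    } else if (el %in% c("Cl", "Br")) el else el
  }
  emit <- function(i, from, border) {
    visited[i] <<- TRUE
    tok <- ""
    if (from > 0L) tok <- order_sym[border]
    tok <- paste0(tok, atom_token(i))
    # ring closures opened at this atom
    if (!is.null(open_ring[[as.character(i)]])) {
      for (rc in open_ring[[as.character(i)]])
        tok <- paste0(tok, if (rc$bo > 1L) order_sym[rc$bo] else "", rc$id)
      open_ring[[as.character(i)]] <<- NULL
    }
    nb <- adjk[[i]]
    branches <- character(0)
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        w <- nb[r, 1]; bo <- nb[r, 2]
        if (w == from) next
        if (visited[w]) {
          # ring closure: check if already assigned
          key <- paste(min(i, w), max(i, w))
          if (!is.null(closure[[key]])) {
            tok <- paste0(tok, if (bo > 1L) order_sym[bo] else "", closure[[key]])
            closure[[key]] <<- NULL
          } else {
            ring_id <<- ring_id + 1L
            id <- if (ring_id < 10L) as.character(ring_id) else paste0("%", ring_id)
            closure[[key]] <<- id
            tok <- paste0(tok, if (bo > 1L) order_sym[bo] else "", id)
          }
        } else {
          branches <- c(branches, emit(w, i, bo))
        }
      }
    }
    if (length(branches) > 1L) {
      tok <- paste0(tok, paste0("(", branches[-length(branches)], ")", collapse = ""),
                    branches[length(branches)])
    } else if (length(branches) == 1L) {
      tok <- paste0(tok, branches)
    }
    tok
  }
  parts <- character(0)
  for (s in seq_len(n)) if (!visited[s]) parts <- c(parts, emit(s, 0L, 1L))
  paste(parts, collapse = ".")
}

# deterministic tie-break string for fragments
mg_sort_key <- function(mg) paste(mg_write_smiles(mg))

# keep the largest connected fragment (heavy-atom count, then the smaller
# deterministic SMILES string)
mg_largest_fragment <- function(mg) {
  comp <- mg_components(mg)
  ids <- unique(comp)
  if (length(ids) == 1L) return(mg)
  sizes <- vapply(ids, function(cid) sum(comp == cid), integer(1))
  best <- ids[sizes == max(sizes)]
  if (length(best) > 1L) {
    keys <- vapply(best, function(cid) mg_sort_key(mg_subset(mg, which(comp == cid))),
                   character(1))
    best <- best[order(keys)][1]
  } else best <- best[1]
  mg_subset(mg, which(comp == best))
}

mg_subset <- function(mg, keep) {
  keep <- sort(keep)
  idx <- integer(mg_natoms(mg)); idx[keep] <- seq_along(keep)
  kb <- which(mg$bi %in% keep & mg$bj %in% keep)
  mg_new(mg$elem[keep], idx[mg$bi[kb]], idx[mg$bj[kb]], mg$bo[kb], mg$label[keep])
}

mg_add_atom <- function(mg, elem, label = 0L) {
  mg$elem <- c(mg$elem, elem)
  mg$label <- c(mg$label, as.integer(label))
  mg
}

mg_add_bond <- function(mg, a, b, order = 1L) {
  lo <- min(a, b); hi <- max(a, b)
  mg$bi <- c(mg$bi, as.integer(lo))
  mg$bj <- c(mg$bj, as.integer(hi))
  mg$bo <- c(mg$bo, as.integer(order))
  mg
}

mg_remove_bond <- function(mg, k) {
  mg$bi <- mg$bi[-k]; mg$bj <- mg$bj[-k]; mg$bo <- mg$bo[-k]
  mg
}

mg_remove_atoms <- function(mg, drop) {
  mg_subset(mg, setdiff(seq_len(mg_natoms(mg)), drop))
}

# molecular weight including implicit hydrogens
mg_molwt <- function(mg) {
  h <- mg_implicit_h(mg)
  sum(MG_MASS[mg$elem]) + sum(h) * MG_MASS[["H"]]
}
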