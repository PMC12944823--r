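# The nine elementary chemical-move operators and probability-weighted
# proposal.  Every operator edits the Kekule graph, enumerates the feasible
# edits of its kind, draws one uniformly, and guarantees the returned
# molecule sanitizes; an operator with no feasible edit reports
# feasible = FALSE and leaves the input untouched.

# default substituent inventory for the add-group move: common
# medicinal-chemistry substituents
MOVE_GROUPS <- c("CH3", "OH", "NH2", "F", "Cl", "Br", "=O", "OCH3", "SH",
                 "C#N", "CF3")

# elements reachable by atom-type changes and chain insertion
MOVE_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "P")

# move kinds with the standard selection probabilities
MOVE_KINDS <- c(add_group = 0.3, remove_atom = 0.2, change_atom_type = 0.1,
                add_atom_in_chain = 0.15, change_bond_type = 0.025,
                form_ring = 0.025, break_ring = 0.05, toggle_aromatic = 0.05,
                rearrange_bonds = 0.1)

RING_SIZE_MIN <- 3L
RING_SIZE_MAX <- 8L

pick1 <- function(v) v[sample.int(length(v), 1L)]

move_outcome <- function(mg, kind, feasible, detail = "") {
  list(mg = mg, kind = kind, feasible = feasible, detail = detail)
}

# free valence (implicit H count); 0 where valence state is saturated
mg_free_valence <- function(mg) {
  h <- mg_implicit_h(mg)
  h[is.na(h)] <- 0L
  h
}

# ---- add_group -------------------------------------------------------------

group_valence_need <- function(group) if (group == "=O") 2L else 1L

graft_group <- function(mg, site, group) {
  n0 <- mg_natoms(mg)
  switch(group,
    CH3 = mg_add_bond(mg_add_atom(mg, "C"), site, n0 + 1L),
    OH  = mg_add_bond(mg_add_atom(mg, "O"), site, n0 + 1L),
    NH2 = mg_add_bond(mg_add_atom(mg, "N"), site, n0 + 1L),
    F   = mg_add_bond(mg_add_atom(mg, "F"), site, n0 + 1L),
    Cl  = mg_add_bond(mg_add_atom(mg, "Cl"), site, n0 + 1L),
    Br  = mg_add_bond(mg_add_atom(mg, "Br"), site, n0 + 1L),
    SH  = mg_add_bond(mg_add_atom(mg, "S"), site, n0 + 1L),
    `=O` = mg_add_bond(mg_add_atom(mg, "O"), site, n0 + 1L, order = 2L),
    OCH3 = {
      m2 <- mg_add_atom(mg_add_atom(mg, "O"), "C")
      mg_add_bond(mg_add_bond(m2, site, n0 + 1L), n0 + 1L, n0 + 2L)
    },
    `C#N` = {
      m2 <- mg_add_atom(mg_add_atom(mg, "C"), "N")
      mg_add_bond(mg_add_bond(m2, site, n0 + 1L), n0 + 1L, n0 + 2L, order = 3L)
    },
    CF3 = {
      m2 <- mg_add_atom(mg_add_atom(mg_add_atom(mg_add_atom(mg, "C"), "F"), "F"), "F")
      m2 <- mg_add_bond(m2, site, n0 + 1L)
      m2 <- mg_add_bond(m2, n0 + 1L, n0 + 2L)
      m2 <- mg_add_bond(m2, n0 + 1L, n0 + 3L)
      mg_add_bond(m2, n0 + 1L, n0 + 4L)
    },
    stop("unknown group ", group))
}

# terminal branches hanging off an anchor atom: connected subgraphs reachable
# from the anchor through one single bond without re-entering the rest of the
# molecule; used by add_group's "replace another group" form
terminal_branches <- function(mg, max_atoms = 4L) {
  rb <- mg_ring_bonds(mg)
  out <- list()
  comp0 <- length(unique(mg_components(mg)))
  for (k in seq_len(mg_nbonds(mg))) {
    if (rb[k] || mg$bo[k] != 1L) next
    sub <- mg_remove_bond(mg, k)
    comp <- mg_components(sub)
    side_j <- which(comp == comp[mg$bj[k]])
    side_i <- which(comp == comp[mg$bi[k]])
    if (length(side_j) <= max_atoms && length(side_j) < mg_natoms(mg))
      out[[length(out) + 1L]] <- list(anchor = mg$bi[k], drop = side_j)
    if (length(side_i) <= max_atoms && length(side_i) < mg_natoms(mg))
      out[[length(out) + 1L]] <- list(anchor = mg$bj[k], drop = side_i)
  }
  out
}

# the added group replaces another group at the attachment point: an implicit
# hydrogen, or a small terminal substituent which is excised first
move_add_group <- function(mg, groups = MOVE_GROUPS, p_replace = 0.25) {
  replace_branch <- stats::runif(1) < p_replace
  if (replace_branch) {
    brs <- terminal_branches(mg)
    if (length(brs)) {
      br <- brs[[sample.int(length(brs), 1L)]]
      anchor_old <- br$anchor
      keep <- setdiff(seq_len(mg_natoms(mg)), br$drop)
      site <- match(anchor_old, keep)
      base <- mg_subset(mg, keep)
      fv <- mg_free_valence(base)
      ok_groups <- groups[vapply(groups, function(g)
        fv[site] >= group_valence_need(g), logical(1))]
      if (length(ok_groups)) {
        g <- pick1(ok_groups)
        out <- graft_group(base, site, g)
        if (mg_sanitize_ok(out))
          return(move_outcome(out, "add_group", TRUE,
                              sprintf("%s replacing branch at atom %d", g, anchor_old)))
      }
    }
  }
  fv <- mg_free_valence(mg)
  real <- mg$elem != "*"
  ok_groups <- groups[vapply(groups, function(g)
    any(fv >= group_valence_need(g) & real), logical(1))]
  if (!length(ok_groups)) return(move_outcome(mg, "add_group", FALSE))
  g <- pick1(ok_groups)
  sites <- which(fv >= group_valence_need(g) & real)
  site <- pick1(sites)
  out <- graft_group(mg, site, g)
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "add_group", FALSE))
  move_outcome(out, "add_group", TRUE, sprintf("%s at atom %d", g, site))
}

# ---- remove_atom -----------------------------------------------------------

move_remove_atom <- function(mg) {
  real <- which(mg$elem != "*")
  if (length(real) < 2L) return(move_outcome(mg, "remove_atom", FALSE))
  a <- pick1(real)
  out <- mg_largest_fragment(mg_remove_atoms(mg, a))
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "remove_atom", FALSE))
  move_outcome(out, "remove_atom", TRUE, sprintf("removed atom %d (%s)", a, mg$elem[a]))
}

# ---- change_atom_type ------------------------------------------------------

move_change_atom_type <- function(mg, elements = MOVE_ELEMENTS) {
  bs <- mg_bondsum(mg)
  n <- mg_natoms(mg)
  cand_atoms <- which(mg$elem != "*")
  feas <- list()
  for (a in cand_atoms) {
    els <- elements[elements != mg$elem[a]]
    els <- els[vapply(els, function(e) max(MG_VALENCES[[e]]) >= bs[a], logical(1))]
    if (length(els)) feas[[length(feas) + 1L]] <- list(a = a, els = els)
  }
  if (!length(feas)) return(move_outcome(mg, "change_atom_type", FALSE))
  ch <- feas[[sample.int(length(feas), 1L)]]
  e <- pick1(ch$els)
  out <- mg
  out$elem[ch$a] <- e
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "change_atom_type", FALSE))
  move_outcome(out, "change_atom_type", TRUE,
               sprintf("atom %d %s->%s", ch$a, mg$elem[ch$a], e))
}

# ---- add_atom_in_chain -----------------------------------------------------

move_add_atom_in_chain <- function(mg, elements = MOVE_ELEMENTS) {
  m <- mg_nbonds(mg)
  if (!m) return(move_outcome(mg, "add_atom_in_chain", FALSE))
  ok_el <- elements[vapply(elements, function(e)
    any(max(MG_VALENCES[[e]]) >= 2L * mg$bo), logical(1))]
  if (!length(ok_el)) return(move_outcome(mg, "add_atom_in_chain", FALSE))
  e <- pick1(ok_el)
  bonds <- which(2L * mg$bo <= max(MG_VALENCES[[e]]))
  k <- pick1(bonds)
  a <- mg$bi[k]; b <- mg$bj[k]; o <- mg$bo[k]
  out <- mg_remove_bond(mg, k)
  out <- mg_add_atom(out, e)
  x <- mg_natoms(out)
  out <- mg_add_bond(mg_add_bond(out, a, x, o), x, b, o)
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "add_atom_in_chain", FALSE))
  move_outcome(out, "add_atom_in_chain", TRUE,
               sprintf("%s into bond %d-%d", e, a, b))
}

# ---- change_bond_type ------------------------------------------------------

# operates on the Kekule graph: bonds inside aromatic rings are toggled at
# their Kekule order, which locally opens the pi system and lets the search
# edit aromatic rings gradually (re-perception restores aromaticity once a
# valid pattern is complete)
move_change_bond_type <- function(mg) {
  m <- mg_nbonds(mg)
  if (!m) return(move_outcome(mg, "change_bond_type", FALSE))
  cand <- which(mg$bo %in% c(1L, 2L))
  feas <- integer(0)
  for (k in cand) {
    out <- mg
    out$bo[k] <- if (mg$bo[k] == 1L) 2L else 1L
    if (mg_sanitize_ok(out)) feas <- c(feas, k)
  }
  if (!length(feas)) return(move_outcome(mg, "change_bond_type", FALSE))
  k <- pick1(feas)
  out <- mg
  out$bo[k] <- if (mg$bo[k] == 1L) 2L else 1L
  move_outcome(out, "change_bond_type", TRUE,
               sprintf("bond %d-%d %d->%d", mg$bi[k], mg$bj[k], mg$bo[k], out$bo[k]))
}

# ---- form_ring -------------------------------------------------------------

# chains of sufficient length: atom pairs joined by a path of chain
# (non-ring) bonds whose closure gives a ring in the allowed size window
move_form_ring <- function(mg, size_min = RING_SIZE_MIN, size_max = RING_SIZE_MAX) {
  n <- mg_natoms(mg)
  if (n < size_min) return(move_outcome(mg, "form_ring", FALSE))
  fv <- mg_free_valence(mg)
  # at least one endpoint must come from a chain: closing two ring atoms
  # onto each other makes bridged cages rather than the fused/spiro rings
  # seen in drug-like molecules
  ringb <- mg_ring_bonds(mg)
  in_ring <- logical(n)
  if (any(ringb)) in_ring[unique(c(mg$bi[ringb], mg$bj[ringb]))] <- TRUE
  D <- mg_dist(mg)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pairs]
  keep <- !is.na(d) & d >= (size_min - 1L) & d <= (size_max - 1L) &
    fv[pairs[, 1]] >= 1L & fv[pairs[, 2]] >= 1L &
    !(in_ring[pairs[, 1]] & in_ring[pairs[, 2]]) &
    mg$elem[pairs[, 1]] != "*" & mg$elem[pairs[, 2]] != "*"
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(move_outcome(mg, "form_ring", FALSE))
  # draw the ring size uniformly among feasible sizes, then a closure of
  # that size: short-distance pairs vastly outnumber longer ones, and
  # size-uniform sampling keeps 5/6-rings as likely as 3-rings
  d <- D[pairs]
  size <- pick1(unique(d))
  pairs <- pairs[d == size, , drop = FALSE]
  r <- sample.int(nrow(pairs), 1L)
  u <- pairs[r, 1]; v <- pairs[r, 2]
  out <- mg_add_bond(mg, u, v)
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "form_ring", FALSE))
  move_outcome(out, "form_ring", TRUE,
               sprintf("closed ring of size %d (%d-%d)", D[u, v] + 1L, u, v))
}

# ---- break_ring ------------------------------------------------------------

move_break_ring <- function(mg) {
  rb <- which(mg_ring_bonds(mg))
  if (!length(rb)) return(move_outcome(mg, "break_ring", FALSE))
  k <- pick1(rb)
  out <- mg_remove_bond(mg, k)
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "break_ring", FALSE))
  move_outcome(out, "break_ring", TRUE,
               sprintf("cut ring bond %d-%d", mg$bi[k], mg$bj[k]))
}

# ---- toggle_aromatic -------------------------------------------------------

ring_is_listed <- function(ring, rings) {
  key <- paste(sort(ring), collapse = ",")
  any(vapply(rings, function(r) paste(sort(r), collapse = ",") == key, logical(1)))
}

# Try to aromatize one ring: re-kekulize the ring bonds so that every ring
# atom is sp2 and the Hueckel electron count fits.  Ring atoms carrying an
# exocyclic multiple bond keep their ring bonds single and contribute no
# electrons; carbons must take exactly one in-ring double bond; N/S without
# free valence (and O) sit on a lone pair.  Returns the edited graph or NULL.
aromatize_ring <- function(mg, ring, ring_bond_idx) {
  len <- length(ring)
  if (len > 8L || any(mg$elem[ring] == "*")) return(NULL)
  cleared <- mg
  cleared$bo[ring_bond_idx] <- 1L
  bs <- mg_bondsum(cleared)
  fv <- mg_free_valence(cleared)
  # exocyclic multiple bonds per ring atom (on the cleared graph)
  exo <- logical(len)
  for (k in seq_len(mg_nbonds(cleared))) if (cleared$bo[k] > 1L) {
    wi <- match(cleared$bi[k], ring); wj <- match(cleared$bj[k], ring)
    if (!is.na(wi)) exo[wi] <- TRUE
    if (!is.na(wj)) exo[wj] <- TRUE
  }
  # category per ring position: 2 = must take a double, 1 = flexible,
  # 0 = must stay single (lone pair or exocyclic pi)
  catg <- integer(len)
  lone <- numeric(len)   # electron contribution when single-bonded
  for (i in seq_len(len)) {
    a <- ring[i]
    if (exo[i]) { catg[i] <- 0L; lone[i] <- 0 }
    else if (mg$elem[a] == "C") {
      if (fv[a] < 1L) return(NULL)
      catg[i] <- 2L
    } else if (mg$elem[a] %in% c("N", "S", "P")) {
      catg[i] <- if (fv[a] >= 1L) 1L else 0L
      lone[i] <- 2
    } else if (mg$elem[a] == "O") { catg[i] <- 0L; lone[i] <- 2 }
    else return(NULL)
  }
  # ring bond b connects positions b and b+1 (cyclic); enumerate matchings
  nb <- len
  best <- NULL
  for (mask in 0:(2^nb - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(nb - 1L))))
    if (!any(sel) && any(catg == 2L)) next
    # no two adjacent selected bonds
    adj_ok <- TRUE
    for (b in which(sel)) {
      nxt <- if (b == nb) 1L else b + 1L
      if (sel[nxt]) { adj_ok <- FALSE; break }
    }
    if (!adj_ok) next
    cover <- integer(len)
    for (b in which(sel)) {
      p1 <- b; p2 <- if (b == nb) 1L else b + 1L
      cover[p1] <- cover[p1] + 1L; cover[p2] <- cover[p2] + 1L
    }
    if (any(cover > 1L)) next
    if (any(catg == 2L & cover == 0L)) next
    if (any(catg == 0L & cover > 0L)) next
    electrons <- sum(cover) + sum(lone[cover == 0L & catg != 2L])
    if (electrons %% 4 != 2) next
    best <- sel
    break
  }
  if (is.null(best)) return(NULL)
  out <- cleared
  out$bo[ring_bond_idx[best]] <- 2L
  out
}

move_toggle_aromatic <- function(mg) {
  rings <- mg_rings(mg)
  if (!length(rings)) return(move_outcome(mg, "toggle_aromatic", FALSE))
  arom <- mg_aromatic(mg)
  ring <- rings[[sample.int(length(rings), 1L)]]
  len <- length(ring)
  ring_bond_idx <- vapply(seq_len(len), function(i)
    mg_bond_index(mg, ring[i], ring[if (i == len) 1L else i + 1L]), integer(1))
  if (any(ring_bond_idx == 0L)) return(move_outcome(mg, "toggle_aromatic", FALSE))
  if (all(arom$atoms[ring])) {
    # dearomatize: saturate the ring (all ring bonds single)
    out <- mg
    out$bo[ring_bond_idx] <- 1L
    if (!mg_sanitize_ok(out)) return(move_outcome(mg, "toggle_aromatic", FALSE))
    return(move_outcome(out, "toggle_aromatic", TRUE,
                        sprintf("dearomatized ring {%s}", paste(ring, collapse = ","))))
  }
  out <- aromatize_ring(mg, ring, ring_bond_idx)
  if (is.null(out) || !mg_sanitize_ok(out))
    return(move_outcome(mg, "toggle_aromatic", FALSE))
  if (!all(mg_aromatic(out)$atoms[ring]))
    return(move_outcome(mg, "toggle_aromatic", FALSE))
  move_outcome(out, "toggle_aromatic", TRUE,
               sprintf("aromatized ring {%s}", paste(ring, collapse = ",")))
}

# ---- rearrange_bonds -------------------------------------------------------

move_rearrange_bonds <- function(mg) {
  deg <- mg_degree(mg)
  pivots <- which(deg > 2L)
  if (!length(pivots)) return(move_outcome(mg, "rearrange_bonds", FALSE))
  adj <- mg_adj(mg)
  fv <- mg_free_valence(mg)
  feas <- list()
  for (p in pivots) {
    for (s in adj[[p]]) {
      k <- mg_bond_index(mg, p, s)
      o <- mg$bo[k]
      for (nb in adj[[p]]) {
        if (nb == s) next
        if (mg_bond_index(mg, nb, s)) next
        if (fv[nb] < o) next
        feas[[length(feas) + 1L]] <- c(p, s, nb, k, o)
      }
    }
  }
  if (!length(feas)) return(move_outcome(mg, "rearrange_bonds", FALSE))
  ch <- feas[[sample.int(length(feas), 1L)]]
  out <- mg_remove_bond(mg, ch[4])
  out <- mg_add_bond(out, ch[3], ch[2], ch[5])
  if (!mg_sanitize_ok(out)) return(move_outcome(mg, "rearrange_bonds", FALSE))
  move_outcome(out, "rearrange_bonds", TRUE,
               sprintf("bond %d-%d migrated to %d-%d", ch[1], ch[2], ch[3], ch[2]))
}

# ---- proposal --------------------------------------------------------------

MOVE_FUNS <- list(
  add_group = move_add_group,
  remove_atom = move_remove_atom,
  change_atom_type = move_change_atom_type,
  add_atom_in_chain = move_add_atom_in_chain,
  change_bond_type = move_change_bond_type,
  form_ring = move_form_ring,
  break_ring = move_break_ring,
  toggle_aromatic = move_toggle_aromatic,
  rearrange_bonds = move_rearrange_bonds
)

# draw a move kind by probability, apply it; redraw on infeasibility up to
# max_retries times; a fully infeasible proposal is returned with
# feasible = FALSE and counts as a rejected MC step at the engine level
propose_mg <- function(mg, probs = MOVE_KINDS, max_retries = 25L) {
  kinds <- names(probs)
  for (t in seq_len(max_retries)) {
    kind <- kinds[sample.int(length(kinds), 1L, prob = probs)]
    out <- MOVE_FUNS[[kind]](mg)
    if (out$feasible) return(out)
  }
  move_outcome(mg, kind, FALSE, "no feasible move found")
}
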