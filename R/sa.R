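# Synthetic-accessibility score on the published 1 (easy) .. 10 (hard)
# scale: a fragment-contribution term over circular atom environments
# (radius 0-2) plus complexity penalties (size, spiro centers, bridgeheads,
# macrocycles, symmetry), mapped through the published calibration to 1-10.
#
# The fragment contributions are the published frequency-derived scores,
# re-keyed to this package's environment identifiers (inst/extdata/
# sa_env_scores.tsv); environments outside the table fall back to the
# rare-fragment default of -4.

SA_DEFAULT_SCORE <- -4

.molmc_cache <- new.env(parent = emptyenv())

sa_table <- function() {
  if (is.null(.molmc_cache$sa)) {
    path <- system.file("extdata", "sa_env_scores.tsv", package = "molmc")
    if (!nzchar(path) || !file.exists(path)) {
      # during in-source development
      path <- file.path("inst", "extdata", "sa_env_scores.tsv")
    }
    if (file.exists(path)) {
      tb <- utils::read.table(path, header = TRUE, sep = "\t")
      v <- tb$score
      names(v) <- as.character(tb$hash)
      .molmc_cache$sa <- v
    } else .molmc_cache$sa <- numeric(0)
  }
  .molmc_cache$sa
}

# potential stereocenters: sp3 carbons whose four substituents (implicit H
# included) are pairwise distinguishable; branches are compared by a BFS
# signature of the graph with the candidate atom removed
count_stereocenters <- function(mg) {
  n <- mg_natoms(mg)
  deg <- mg_degree(mg)
  h <- mg_implicit_h(mg)
  bs <- mg_bondsum(mg)
  adj <- mg_adj(mg)
  cnt <- 0L
  for (a in seq_len(n)) {
    if (mg$elem[a] != "C") next
    if (bs[a] != deg[a]) next                    # multiple bond -> not sp3-4
    nsub <- deg[a] + h[a]
    if (nsub != 4L || deg[a] < 3L) next          # >=2 implicit H: two equal subs
    sub <- mg_remove_atoms(mg, a)
    keep <- setdiff(seq_len(n), a)
    sigs <- character(0)
    for (nb in adj[[a]]) {
      root <- match(nb, keep)
      dvec <- mg_dist(sub)[root, ]
      reach <- which(!is.na(dvec))
      sig <- paste(sort(paste0(dvec[reach], ":", sub$elem[reach], ":",
                               mg_degree(sub)[reach])), collapse = ";")
      sigs <- c(sigs, sig)
    }
    if (anyDuplicated(sigs) == 0L) cnt <- cnt + 1L
  }
  cnt
}

# spiro atoms: shared by two rings having exactly that atom in common;
# bridgeheads: shared by two rings having >= 3 atoms in common (fused pairs
# sharing one bond are neither)
ring_junction_counts <- function(rings) {
  if (length(rings) < 2L) return(c(spiro = 0L, bridge = 0L))
  spiro <- integer(0); bridge <- integer(0)
  for (i in seq_len(length(rings) - 1L)) for (j in (i + 1L):length(rings)) {
    shared <- intersect(rings[[i]], rings[[j]])
    if (length(shared) == 1L) spiro <- c(spiro, shared)
    if (length(shared) >= 3L) bridge <- c(bridge, setdiff(shared, shared[c(-1, -length(shared))]))
  }
  c(spiro = length(unique(spiro)), bridge = length(unique(bridge)))
}

sa_score_mg <- function(mg) {
  n <- mg_natoms(mg)
  arom <- mg_aromatic(mg)
  keys <- env_keys(mg, radius = 2L, arom = arom)
  D <- mg_dist(mg)
  tab <- sa_table()

  # environment dedup rule: radius-0 environments always count; at radius
  # 1-2 an environment whose bond set equals one already counted is skipped
  bsets <- env_bond_sets(mg, D, radius = 2L)
  counted_keys <- character(0)
  score1 <- 0; nf <- 0L
  for (a in seq_len(n)) {   # radius 0
    k0 <- as.character(env_hash(keys[a, 1]))
    score1 <- score1 + if (!is.na(tab[k0])) tab[k0] else SA_DEFAULT_SCORE
    nf <- nf + 1L
    counted_keys <- c(counted_keys, keys[a, 1])
  }
  seen_sets <- character(0)
  for (r in 1:2) {
    for (a in seq_len(n)) {
      bs <- paste(bsets[[r]][[a]], collapse = ",")
      if (!nzchar(bs)) next          # isolated atom: no grown environment
      if (bs %in% seen_sets) next
      seen_sets <- c(seen_sets, bs)
      kk <- as.character(env_hash(keys[a, r + 1L]))
      score1 <- score1 + if (!is.na(tab[kk])) tab[kk] else SA_DEFAULT_SCORE
      nf <- nf + 1L
      counted_keys <- c(counted_keys, keys[a, r + 1L])
    }
  }
  score1 <- score1 / nf

  rings <- mg_rings(mg)
  jc <- ring_junction_counts(rings)
  n_macro <- sum(vapply(rings, length, integer(1)) > 8L)
  size_penalty <- n^1.005 - n
  stereo_penalty <- log10(count_stereocenters(mg) + 1)
  spiro_penalty <- log10(jc[["spiro"]] + 1)
  bridge_penalty <- log10(jc[["bridge"]] + 1)
  macro_penalty <- if (n_macro > 0L) log10(2) else 0
  score2 <- -size_penalty - stereo_penalty - spiro_penalty - bridge_penalty -
    macro_penalty

  n_distinct <- length(unique(counted_keys))
  score3 <- if (n > n_distinct) log(n / n_distinct) * 0.5 else 0

  raw <- score1 + score2 + score3
  smin <- -4; smax <- 2.5
  sa <- 11 - (raw - smin + 1) / (smax - smin) * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  min(max(sa, 1), 10)
}
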