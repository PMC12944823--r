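# Octanol-water partition estimate (Crippen-style atomic contributions,
# re-keyed to this package's environment identifiers) and the ESOL aqueous
# solubility model.
#
# ESOL: log10(S / mol/L) = 0.16 - 0.63 clogP - 0.0062 MW + 0.066 RB - 0.74 AP
# with MW the molecular weight, RB the rotatable-bond count and AP the
# aromatic proportion of heavy atoms.

crippen_table <- function() {
  if (is.null(.molmc_cache$crippen)) {
    path <- system.file("extdata", "crippen_env.tsv", package = "molmc")
    if (!nzchar(path) || !file.exists(path))
      path <- file.path("inst", "extdata", "crippen_env.tsv")
    if (file.exists(path)) {
      tb <- utils::read.table(path, header = TRUE, sep = "\t")
      out <- list()
      for (r in 0:2) {
        sub <- tb[tb$radius == r, ]
        v <- sub$value
        names(v) <- as.character(sub$hash)
        out[[r + 1L]] <- v
      }
      elem <- tb[tb$radius == -1L, ]
      ev <- elem$value
      names(ev) <- as.character(elem$hash)   # element symbol hashes as names
      out$elem <- ev
      .molmc_cache$crippen <- out
    } else .molmc_cache$crippen <- list(numeric(0), numeric(0), numeric(0),
                                        elem = numeric(0))
  }
  .molmc_cache$crippen
}

# per-atom contribution: deepest environment key found in the table wins
crippen_logp_mg <- function(mg, arom = mg_aromatic(mg)) {
  tab <- crippen_table()
  keys <- env_keys(mg, radius = 2L, arom = arom)
  total <- 0
  for (a in seq_len(mg_natoms(mg))) {
    v <- NA_real_
    for (r in c(3L, 2L, 1L)) {
      hit <- tab[[r]][as.character(env_hash(keys[a, r]))]
      if (!is.na(hit)) { v <- hit; break }
    }
    if (is.na(v)) {
      hit <- tab$elem[mg$elem[a]]
      v <- if (!is.na(hit)) hit else 0
    }
    total <- total + v
  }
  unname(total)
}

esol_score_mg <- function(mg, arom = mg_aromatic(mg)) {
  logp <- crippen_logp_mg(mg, arom)
  mw <- mg_molwt(mg)
  rb <- count_rotatable_bonds(mg, arom = arom)
  ap <- aromatic_proportion(mg, arom)
  0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rb - 0.74 * ap
}
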