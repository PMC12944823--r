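# Quantitative estimate of drug-likeness: weighted geometric mean of
# asymmetric-double-sigmoid desirability functions over eight properties
# (MW, logP, HBA, HBD, PSA, rotatable bonds, aromatic rings, structural
# alerts), with a variant that omits the molecular-weight desirability and
# renormalizes the remaining weights.

QED_ADS <- list(
  MW    = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,
            E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP = c(A = 3.172690585, B = 137.8624751, C = 2.534937431, D = 4.581497897,
            E = 0.822739154, F = 0.576295591, DMAX = 131.3186604),
  HBA   = c(A = 2.948620388, B = 160.4605972, C = 3.615294657, D = 4.435986202,
            E = 0.290141953, F = 1.300669958, DMAX = 148.7763046),
  HBD   = c(A = 1.618662227, B = 1010.051101, C = 0.985094388, D = 0.000000001,
            E = 0.713820843, F = 0.920922555, DMAX = 258.1632616),
  PSA   = c(A = 1.876861559, B = 125.2232657, C = 62.90773554, D = 87.83366614,
            E = 12.01999824, F = 28.51324732, DMAX = 104.5686167),
  ROTB  = c(A = 0.010000000, B = 272.4121427, C = 2.558379970, D = 1.565547684,
            E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM  = c(A = 3.217788970, B = 957.7374108, C = 2.274627939, D = 0.000000001,
            E = 1.317690384, F = 0.375760881, DMAX = 312.3372610),
  ALERTS = c(A = 0.010000000, B = 1199.094025, C = -0.09002883, D = 0.000000001,
             E = 0.185904477, F = 0.875193782, DMAX = 417.7253140)
)

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                 ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p[["C"]] + p[["D"]] / 2) / p[["E"]])
  e2 <- 1 + exp(-(x - p[["C"]] - p[["D"]] / 2) / p[["F"]])
  (p[["A"]] + p[["B"]] / e1 * (1 - 1 / e2)) / p[["DMAX"]]
}

qed_alert_patterns <- function() {
  if (is.null(.molmc_cache$alerts)) {
    path <- system.file("extdata", "qed_structural_alerts.smarts", package = "molmc")
    if (!nzchar(path) || !file.exists(path))
      path <- file.path("inst", "extdata", "qed_structural_alerts.smarts")
    pats <- readLines(path)
    pats <- pats[!startsWith(pats, "#") & nzchar(pats)]
    .molmc_cache$alerts <- pats
  }
  .molmc_cache$alerts
}

# count structural alerts via OpenBabel SMARTS matching on the Kekule MOL
# block; component-level patterns (dot-separated repeats) are counted from
# their single-component match counts
count_alerts <- function(mg) {
  pats <- qed_alert_patterns()
  mb <- paste0(mg_to_molblock(brics_cap(mg)), "$$$$\n")
  ref <- NULL
  ChemmineOB::forEachMol("SDF", mb, function(m) ref <<- m)
  if (is.null(ref)) return(0L)
  refs <- list(ref)
  elems <- unique(mg$elem)
  hits <- 0L
  for (p in pats) {
    if (grepl("F\\.F\\.F\\.F", p)) {
      if (sum(mg$elem == "F") >= 4L) hits <- hits + 1L
      next
    }
    if (grepl(".", p, fixed = TRUE)) {
      parts <- strsplit(p, ".", fixed = TRUE)[[1]]
      if (length(unique(parts)) == 1L) {
        cnt <- tryCatch(ChemmineOB::smartsSearch_OB(refs, parts[1]),
                        error = function(e) 0L)
        if (!is.na(cnt) && cnt >= length(parts)) hits <- hits + 1L
        next
      }
    }
    cnt <- tryCatch(suppressWarnings(ChemmineOB::smartsSearch_OB(refs, p)),
                    error = function(e) 0L)
    if (length(cnt) && !is.na(cnt) && cnt > 0) hits <- hits + 1L
  }
  hits
}

qed_properties_mg <- function(mg, arom = mg_aromatic(mg)) {
  list(MW = mg_molwt(mg),
       ALOGP = crippen_logp_mg(mg, arom),
       HBA = count_hba(mg, arom),
       HBD = count_hbd(mg),
       PSA = tpsa_mg(mg, arom),
       ROTB = count_rotatable_bonds(mg, arom = arom),
       AROM = count_aromatic_rings(mg, arom),
       ALERTS = count_alerts(mg))
}

qed_from_properties <- function(props, drop_mw = TRUE,
                                weights = QED_WEIGHTS) {
  keep <- names(weights)
  if (drop_mw) keep <- setdiff(keep, "MW")
  d <- vapply(keep, function(nm) qed_ads(props[[nm]], QED_ADS[[nm]]), numeric(1))
  d <- pmax(d, 1e-12)
  w <- weights[keep]
  exp(sum(w * log(d)) / sum(w))
}

# drug-likeness with the molecular-weight desirability omitted
qed_no_mw_mg <- function(mg, arom = mg_aromatic(mg)) {
  qed_from_properties(qed_properties_mg(mg, arom), drop_mw = TRUE)
}

# full eight-property variant (used for cross-checks)
qed_full_mg <- function(mg, arom = mg_aromatic(mg)) {
  qed_from_properties(qed_properties_mg(mg, arom), drop_mw = FALSE)
}
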