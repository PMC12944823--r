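# Composite design objective: confidence-weighted structure-prediction score
# plus synthetic-accessibility, solubility and drug-likeness biases,
#
#   score = 0.8 * confidence + 0.1 * SAnorm + 0.05 * ESOLnorm + 0.05 * QED
#
# with SA treated as maximal below a threshold (default 5 on the 1-10
# scale) and ESOL mapped affinely onto [0,1] between calibrated bounds.

# ESOL normalization bounds calibrated by least squares against the three
# reference design runs' printed score components (see
# calibrateEsolNormalization); SA threshold default consistent with those
# rows behaving as maximal
SA_THRESHOLD_DEFAULT <- 5.0
ESOL_LO_DEFAULT <- -13.705
ESOL_HI_DEFAULT <- -1.486

normalize_sa_value <- function(sa_raw, threshold = SA_THRESHOLD_DEFAULT) {
  stopifnot(threshold < 10)
  out <- ifelse(sa_raw <= threshold, 1, (10 - sa_raw) / (10 - threshold))
  pmin(pmax(out, 0), 1)
}

normalize_esol_value <- function(esol_raw, lo = ESOL_LO_DEFAULT,
                                 hi = ESOL_HI_DEFAULT) {
  stopifnot(lo < hi)
  pmin(pmax((esol_raw - lo) / (hi - lo), 0), 1)
}

# least-squares calibration of the ESOL normalization bounds from reference
# rows (printed composite + components); returns c(lo, hi)
calibrate_esol_normalization <- function(reference = NULL,
                                         weights = c(0.8, 0.1, 0.05, 0.05),
                                         sa_threshold = SA_THRESHOLD_DEFAULT) {
  if (is.null(reference)) {
    path <- system.file("extdata", "design_reference_scores.tsv", package = "molmc")
    if (!nzchar(path) || !file.exists(path))
      path <- file.path("inst", "extdata", "design_reference_scores.tsv")
    reference <- utils::read.delim(path)
  }
  sa_norm <- normalize_sa_value(reference$sa_raw, sa_threshold)
  norm <- (reference$composite - weights[1] * reference$confidence -
             weights[2] * sa_norm - weights[4] * reference$qed) / weights[3]
  fit <- stats::lm(norm ~ reference$esol_raw)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  lo <- -b / a
  c(lo = lo, hi = lo + 1 / a)
}

# internal composite breakdown on a molecular graph
composite_breakdown_mg <- function(mg, confidence,
                                   weights = c(0.8, 0.1, 0.05, 0.05),
                                   sa_threshold = SA_THRESHOLD_DEFAULT,
                                   esol_lo = ESOL_LO_DEFAULT,
                                   esol_hi = ESOL_HI_DEFAULT) {
  arom <- mg_aromatic(mg)
  sa_raw <- sa_score_mg(mg)
  esol_raw <- esol_score_mg(mg, arom)
  qed <- qed_no_mw_mg(mg, arom)
  sa_norm <- normalize_sa_value(sa_raw, sa_threshold)
  esol_norm <- normalize_esol_value(esol_raw, esol_lo, esol_hi)
  composite <- weights[1] * confidence + weights[2] * sa_norm +
    weights[3] * esol_norm + weights[4] * qed
  list(confidence = confidence, sa_raw = sa_raw, sa_norm = sa_norm,
       esol_raw = esol_raw, esol_norm = esol_norm, qed = qed,
       composite = composite)
}

# deterministic mock structure-prediction backend: a smooth, bounded
# confidence landscape over simple descriptors (heavy atoms, H-bond donors
# and acceptors, aromatic rings) peaking at a configurable optimum, so the
# search engine has a climbable objective without an external co-folding
# model
mock_confidence_mg <- function(mg, optimum = c(natoms = 22, hbd = 2,
                                               hba = 4, rings = 2),
                               scales = c(natoms = 12, hbd = 2.5,
                                          hba = 3.5, rings = 1.8)) {
  arom <- mg_aromatic(mg)
  d <- c(natoms = mg_natoms(mg), hbd = count_hbd(mg),
         hba = count_hba(mg, arom), rings = length(mg_rings(mg)))
  z <- (d - optimum[names(d)]) / scales[names(d)]
  exp(-0.5 * sum(z^2))
}
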