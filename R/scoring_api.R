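# Exported scoring surface: fingerprints, dice similarity, the property
# scores, normalizers, the composite objective and backend methods.

#' Atom-pair fingerprint
#'
#' Count-based Carhart atom-pair fingerprint: each heavy-atom pair
#' contributes one feature combining the two atom types (element, heavy
#' degree, pi-electron count; aromatic atoms count one pi electron) and
#' their topological distance (up to 30 bonds).  Invariant to atom ordering
#' and to the Kekule assignment of aromatic rings.
#'
#' @param compound a \linkS4class{Compound}
#' @return sorted integer vector of pair codes (with multiplicity)
#' @examples
#' fp <- atomPairFingerprint(parseSmiles("CCO"))
#' @export
atomPairFingerprint <- function(compound) ap_fingerprint_mg(compound@graph)

#' Dice similarity of two compounds
#'
#' Dice coefficient on count fingerprints,
#' \eqn{2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)};
#' symmetric, in [0,1], and 1 exactly when the fingerprints are identical.
#'
#' @param a,b \linkS4class{Compound}s (or raw fingerprint vectors)
#' @return dice similarity in [0,1]
#' @examples
#' diceSimilarity(parseSmiles("c1ccccc1"), parseSmiles("Cc1ccccc1"))
#' @export
diceSimilarity <- function(a, b) {
  fa <- if (is(a, "Compound")) ap_fingerprint_mg(a@graph) else a
  fb <- if (is(b, "Compound")) ap_fingerprint_mg(b@graph) else b
  dice_codes(fa, fb)
}

#' Synthetic-accessibility score
#'
#' Fragment-contribution estimate of synthetic accessibility on the 1
#' (easy) to 10 (hard) scale, combining contributions of circular atom
#' environments with size, stereo-center, spiro, bridgehead, macrocycle and
#' symmetry penalties.
#'
#' @param compound a \linkS4class{Compound}
#' @return SA score in [1,10]
#' @examples
#' saScore(parseSmiles("c1ccccc1"))
#' @export
saScore <- function(compound) sa_score_mg(compound@graph)

#' ESOL aqueous-solubility estimate
#'
#' Linear model of estimated log10 solubility (mol/L) over computed logP,
#' molecular weight, rotatable-bond count and aromatic proportion.
#'
#' @param compound a \linkS4class{Compound}
#' @return estimated log10 solubility
#' @examples
#' esolScore(parseSmiles("CCO"))
#' @export
esolScore <- function(compound) esol_score_mg(compound@graph)

#' Octanol-water partition estimate
#' @param compound a \linkS4class{Compound}
#' @return Crippen-style logP estimate
#' @export
logP <- function(compound) crippen_logp_mg(compound@graph)

#' Drug-likeness without the molecular-weight factor
#'
#' Weighted geometric mean of the QED desirability functions with the
#' molecular-weight desirability omitted and the remaining weights
#' renormalized.
#'
#' @param compound a \linkS4class{Compound}
#' @return drug-likeness in [0,1]
#' @examples
#' qedNoMW(parseSmiles("Cc1ccccc1"))
#' @export
qedNoMW <- function(compound) qed_no_mw_mg(compound@graph)

#' Normalize an SA score to [0,1]
#'
#' SA is treated as maximal (1.0) at or below the threshold and decays
#' linearly to 0 at SA = 10.
#'
#' @param saRaw SA value(s) on the 1-10 scale
#' @param threshold the plateau threshold (default 5)
#' @export
normalizeSA <- function(saRaw, threshold = SA_THRESHOLD_DEFAULT)
  normalize_sa_value(saRaw, threshold)

#' Normalize an ESOL value to [0,1]
#'
#' Affine map between calibrated bounds, clamped to [0,1].  The default
#' bounds come from \code{calibrateEsolNormalization}.
#'
#' @param esolRaw ESOL value(s)
#' @param lo,hi normalization bounds (lo < hi)
#' @export
normalizeESOL <- function(esolRaw, lo = ESOL_LO_DEFAULT, hi = ESOL_HI_DEFAULT)
  normalize_esol_value(esolRaw, lo, hi)

#' Calibrate the ESOL normalization bounds
#'
#' Least-squares fit of the affine ESOL normalization against reference
#' design runs whose composite scores and components are printed in the
#' packaged reference table: the normalized ESOL implied by each row is
#' back-solved from the composite identity and regressed on the raw ESOL.
#'
#' @param reference optional data frame (columns composite, confidence,
#'   sa_raw, esol_raw, qed); defaults to the packaged reference rows
#' @return named vector c(lo, hi)
#' @export
calibrateEsolNormalization <- function(reference = NULL)
  calibrate_esol_normalization(reference)

#' Predict backend confidence
#'
#' @param backend a \linkS4class{PredictorBackend}
#' @param protein protein sequence string (single-letter amino acids)
#' @param compound a \linkS4class{Compound} or SMILES string
#' @return confidence in [0,1]
#' @export
setGeneric("predictConfidence", function(backend, protein, compound)
  standardGeneric("predictConfidence"))

#' @rdname predictConfidence
#' @export
setMethod("predictConfidence", "MockBackend", function(backend, protein, compound) {
  mg <- if (is(compound, "Compound")) compound@graph else parse_smiles_mg(compound)
  mock_confidence_mg(mg, optimum = backend@optimum, scales = backend@scales)
})

#' Deterministic mock predictor backend
#'
#' A smooth, bounded confidence landscape over simple molecular descriptors
#' (heavy-atom count, H-bond donors, acceptors, ring count), equal to 1 at
#' the configured optimum and decaying with descriptor distance.  It gives
#' the search engine a climbable, reproducible objective for testing and
#' protocol development without a co-folding model; it returns no structure.
#'
#' @param optimum named descriptor vector (natoms, hbd, hba, rings)
#' @param scales named falloff scales
#' @return a \linkS4class{MockBackend}
#' @examples
#' b <- mockBackend()
#' predictConfidence(b, "MKV", parseSmiles("c1ccccc1"))
#' @export
mockBackend <- function(optimum = c(natoms = 22, hbd = 2, hba = 4, rings = 2),
                        scales = c(natoms = 12, hbd = 2.5, hba = 3.5,
                                   rings = 1.8)) {
  new("MockBackend", optimum = optimum, scales = scales)
}

#' Composite design score of a compound
#'
#' Evaluates the full breakdown of the composite objective
#' \eqn{0.8\,\mathrm{conf} + 0.1\,\mathrm{SA} + 0.05\,\mathrm{ESOL} +
#' 0.05\,\mathrm{QED}} (all components normalized to [0,1]).
#'
#' @param compound a \linkS4class{Compound}
#' @param backend a \linkS4class{PredictorBackend}
#' @param protein protein sequence passed to the backend
#' @param weights a \linkS4class{CompositeWeights}
#' @param saThreshold SA plateau threshold
#' @param esolBounds ESOL normalization bounds c(lo, hi)
#' @return a \linkS4class{ScoreBreakdown}
#' @examples
#' compositeScore(parseSmiles("Cc1ccccc1"), mockBackend(), "MKV")
#' @export
compositeScore <- function(compound, backend, protein = "",
                           weights = compositeWeights(),
                           saThreshold = SA_THRESHOLD_DEFAULT,
                           esolBounds = c(ESOL_LO_DEFAULT, ESOL_HI_DEFAULT)) {
  conf <- predictConfidence(backend, protein, compound)
  if (!is.finite(conf) || conf < 0 || conf > 1)
    stop("backend returned an invalid confidence: ", conf)
  br <- composite_breakdown_mg(compound@graph, conf,
                               weights = c(weights@wConf, weights@wSa,
                                           weights@wEsol, weights@wQed),
                               sa_threshold = saThreshold,
                               esol_lo = esolBounds[1], esol_hi = esolBounds[2])
  new("ScoreBreakdown", confidence = br$confidence, saRaw = br$sa_raw,
      saNorm = br$sa_norm, esolRaw = br$esol_raw, esolNorm = br$esol_norm,
      qed = br$qed, composite = br$composite)
}
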