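clamp01 <- function(x) pmin(1, pmax(0, x))

#' Normalize knowledge-based energy scores to [0,1]
#'
#' Length-normalised linear maps for the three potentials with published
#' constants:
#' \deqn{DFIRE2: -P / (1.971 L)}
#' \deqn{RWplus: -P / (232.6 L)}
#' \deqn{RF\_CB\_SRS\_OD: (700 - P) / (1000 + 0.4823 L)}
#' Results below 0 are set to 0 and above 1 to 1. The remaining raw
#' energies (dope, goap, opus) use configurable \code{-P/(c L)} maps with
#' the same clamping; proq2/modelevaluator/qprob are passed through
#' clamped, being QA scores already on [0,1].
#'
#' @param raw named list or vector of raw external scores (names among
#'   dfire2, rwplus, rf_cb_srs_od, dope, goap, opus, proq2,
#'   modelevaluator, qprob); entries may be absent or NA.
#' @param L target sequence length (>= 1).
#' @param linearScales named divisors for the dope/goap/opus maps.
#' @return named numeric vector keyed by feature key (DFIRE2, RWPLUS,
#'   ...), one entry per present input score, each in [0,1].
#' @export
normalizeEnergyScores <- function(raw, L,
                                  linearScales = LINEAR_SCALE_DEFAULTS) {
  if (length(L) != 1L || !is.finite(L) || L < 1) stop("L must be >= 1")
  raw <- unlist(raw)
  out <- numeric(0)
  for (nm in names(raw)) {
    key <- tolower(nm)
    if (!key %in% names(EXTERNAL_SCORE_KINDS)) next
    p <- as.numeric(raw[[nm]])
    if (is.na(p)) next
    v <- switch(key,
                dfire2 = -p / (1.971 * L),
                rwplus = -p / (232.6 * L),
                rf_cb_srs_od = (700 - p) / (1000 + 0.4823 * L),
                dope = -p / (linearScales[["dope"]] * L),
                goap = -p / (linearScales[["goap"]] * L),
                opus = -p / (linearScales[["opus"]] * L),
                p)  # passthrough scores
    out[EXTERNAL_TO_KEY[[key]]] <- clamp01(v)
  }
  out
}

#' Surface (nonpolar exposure) score
#'
#' Fraction of the model's total accessible area contributed by exposed
#' nonpolar residues (A,V,L,I,P,F,M,W,G,C). 0 when the model has no
#' accessible area at all.
#'
#' @param sasa result of \code{shrakeRupleySasa()}.
#' @param model the \linkS4class{ProteinModel} the SASA belongs to.
#' @return SU in [0,1].
#' @export
surfaceScore <- function(sasa, model) {
  seqv <- strsplit(model@sequence, "")[[1]]
  tot <- sum(sasa$absolute)
  if (tot <= 0) return(0)
  sel <- sasa$exposed & seqv %in% NONPOLAR_AA
  clamp01(sum(sasa$absolute[sel]) / tot)
}

#' Exposed mass score
#'
#' Mass fraction of exposed residues, using average residue masses (Da).
#'
#' @inheritParams surfaceScore
#' @return EM in [0,1].
#' @export
exposedMassScore <- function(sasa, model) {
  seqv <- strsplit(model@sequence, "")[[1]]
  mass <- unname(RESIDUE_MASS[seqv])
  clamp01(sum(mass[sasa$exposed]) / sum(mass))
}

#' Exposed surface score
#'
#' Total accessible area divided by the summed per-residue maximum-ASA
#' reference, clamped to [0,1].
#'
#' @param sasa result of \code{shrakeRupleySasa()}.
#' @param model the model (for its sequence).
#' @return ES in [0,1].
#' @export
exposedSurfaceScore <- function(sasa, model) {
  seqv <- strsplit(model@sequence, "")[[1]]
  ref <- sum(MAX_ASA[seqv])
  if (ref <= 0) return(0)
  clamp01(sum(sasa$absolute) / ref)
}

#' Solvent-accessibility agreement score
#'
#' Fraction of residues whose 2-state exposed ("e") / buried ("b") label
#' in the model matches the sequence-based prediction.
#'
#' @param sasa result of \code{shrakeRupleySasa()}.
#' @param saPred 2-state string over {e,b} of length L.
#' @return SA in [0,1].
#' @export
saAgreementScore <- function(sasa, saPred) {
  pred <- strsplit(tolower(saPred), "")[[1]]
  if (length(pred) != length(sasa$exposed))
    stop("solvent-accessibility prediction length != model length")
  modelLab <- ifelse(sasa$exposed, "e", "b")
  mean(modelLab == pred)
}

#' Secondary-structure similarity (Q3) score
#'
#' @param ssModel 3-state string assigned from the model structure.
#' @param ssPred 3-state string predicted from sequence.
#' @return SS in [0,1]: fraction of identical positions.
#' @export
ssSimilarityScore <- function(ssModel, ssPred) {
  a <- strsplit(toupper(ssModel), "")[[1]]
  b <- strsplit(toupper(ssPred), "")[[1]]
  if (length(a) != length(b)) stop("secondary-structure string length mismatch")
  mean(a == b)
}

#' Secondary-structure penalty score
#'
#' Over positions predicted helix or strand, the fraction whose model
#' label matches the prediction; oriented so higher is better. Neutral
#' 0.5 when no position is predicted H/E.
#'
#' @inheritParams ssSimilarityScore
#' @return SP in [0,1].
#' @export
ssPenaltyScore <- function(ssModel, ssPred) {
  a <- strsplit(toupper(ssModel), "")[[1]]
  b <- strsplit(toupper(ssPred), "")[[1]]
  if (length(a) != length(b)) stop("secondary-structure string length mismatch")
  sel <- b %in% c("H", "E")
  if (!any(sel)) return(0.5)
  mean(a[sel] == b[sel])
}

#' Euclidean compactness score
#'
#' Mean pairwise CA-CA distance divided by the maximum possible chain
#' span 3.8 (L - 1) Angstrom (a fully extended chain of 3.8 A virtual
#' bonds), clamped to [0,1]. Low values = compact, high = extended.
#'
#' @param distMat L x L CA distance matrix.
#' @param L number of residues (>= 2).
#' @return EC in [0,1].
#' @export
euclideanCompactScore <- function(distMat, L = nrow(distMat)) {
  if (L < 2) stop("compactness needs at least 2 residues")
  m <- as.matrix(distMat)
  clamp01(mean(m[upper.tri(m)]) / (3.8 * (L - 1)))
}

#' Assemble the feature vector for one model
#'
#' Computes the seven structural features (surface, exposed mass, exposed
#' surface, accessibility agreement, secondary-structure similarity and
#' penalty, compactness), normalizes whatever external scores are
#' available, and imputes every remaining entry with the neutral value
#' 0.5. Missing inputs are never fatal.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param external named raw external scores for this model (or NULL).
#' @param ssPred,saPred predicted strings (or NA): 3-state {H,E,C} and
#'   2-state {e,b}.
#' @param ssModel optional precomputed model 3-state string (e.g. a
#'   reduced DSSP string) overriding the internal assigner.
#' @param featureSet "full16" or "deepqa9".
#' @param sasa optional precomputed \code{shrakeRupleySasa()} result.
#' @param linearScales divisors for the dope/goap/opus linear maps.
#' @return a \linkS4class{FeatureVector}.
#' @export
assembleFeatureVector <- function(model, external = NULL,
                                  ssPred = NA_character_,
                                  saPred = NA_character_,
                                  ssModel = NULL,
                                  featureSet = c("full16", "deepqa9"),
                                  sasa = NULL,
                                  linearScales = LINEAR_SCALE_DEFAULTS) {
  featureSet <- match.arg(featureSet)
  keys <- featureSetKeys(featureSet)
  L <- nResidues(model)
  vals <- stats::setNames(rep(0.5, length(keys)), keys)
  prov <- stats::setNames(rep("imputed", length(keys)), keys)

  if (is.null(sasa)) sasa <- shrakeRupleySasa(model)
  if (is.null(ssModel)) ssModel <- assignSecondaryStructure(model)

  put <- function(key, value, from) {
    if (key %in% keys && !is.na(value)) {
      vals[key] <<- clamp01(value)
      prov[key] <<- from
    }
  }
  put("SU", surfaceScore(sasa, model), "computed")
  put("EM", exposedMassScore(sasa, model), "computed")
  put("ES", exposedSurfaceScore(sasa, model), "computed")
  if (L >= 2) put("EC", euclideanCompactScore(distanceMatrix(model), L),
                  "computed")
  if (!is.na(saPred)) put("SA", saAgreementScore(sasa, saPred), "computed")
  if (!is.na(ssPred)) {
    put("SS", ssSimilarityScore(ssModel, ssPred), "computed")
    put("SP", ssPenaltyScore(ssModel, ssPred), "computed")
  }
  if (!is.null(external)) {
    ext <- normalizeEnergyScores(external, L, linearScales)
    for (k in names(ext)) put(k, ext[[k]], "external")
  }
  new("FeatureVector", values = vals, provenance = prov,
      featureSet = featureSet)
}

#' Feature matrix for a whole pool
#'
#' Runs \code{assembleFeatureVector()} on every model of a pool, pulling
#' each model's external score row from the pool's score table when
#' present.
#'
#' @param pool a \linkS4class{ModelPool}.
#' @param featureSet "full16" or "deepqa9".
#' @param linearScales divisors for the dope/goap/opus linear maps.
#' @return numeric matrix (models x features) with model-id rownames.
#' @export
poolFeatureMatrix <- function(pool, featureSet = c("full16", "deepqa9"),
                              linearScales = LINEAR_SCALE_DEFAULTS) {
  featureSet <- match.arg(featureSet)
  keys <- featureSetKeys(featureSet)
  models <- poolModels(pool)
  ext <- pool@externalScores
  rows <- lapply(models, function(m) {
    raw <- NULL
    if (!is.null(ext)) {
      i <- match(modelId(m), ext$model)
      if (!is.na(i)) raw <- as.list(ext[i, setdiff(names(ext), "model")])
    }
    featureValues(assembleFeatureVector(
      m, external = raw, ssPred = pool@ssPred, saPred = pool@saPred,
      featureSet = featureSet, linearScales = linearScales))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(models)
  colnames(mat) <- keys
  mat
}

#' Write / read a feature matrix as TSV
#'
#' @param mat matrix from \code{poolFeatureMatrix()}.
#' @param path TSV path ("model" id column + ordered feature columns).
#' @return invisibly the path / the matrix.
#' @export
writeFeatureTable <- function(mat, path) {
  df <- data.frame(model = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), "model"), drop = FALSE])
  rownames(mat) <- df$model
  mat
}
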