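#' @import methods
NULL

AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
            MSE = "M", UNK = "X")

AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
            X = "UNK")

#' Protein structural model
#'
#' An ordered single-chain protein model: one row per atom, one-letter
#' sequence, 1-based strictly increasing residue numbering. Every residue
#' must carry a CA atom with finite coordinates.
#'
#' @slot modelId single string identifying the model.
#' @slot sequence one-letter amino-acid sequence (string of length L).
#' @slot resno integer vector of residue numbers, one per residue,
#'   strictly increasing.
#' @slot atoms data.frame with columns \code{resno}, \code{elety}
#'   (atom name, e.g. "CA"), \code{x}, \code{y}, \code{z}.
#'
#' @exportClass ProteinModel
setClass("ProteinModel",
         representation(modelId = "character",
                        sequence = "character",
                        resno = "integer",
                        atoms = "data.frame"))

setValidity("ProteinModel", function(object) {
  msg <- character()
  seqv <- strsplit(object@sequence, "")[[1]]
  L <- length(object@resno)
  if (length(object@modelId) != 1L || !nzchar(object@modelId))
    msg <- c(msg, "modelId must be one non-empty string")
  if (length(seqv) != L)
    msg <- c(msg, sprintf("sequence length (%d) != number of residues (%d)",
                          length(seqv), L))
  if (!all(seqv %in% c(AA1, "X")))
    msg <- c(msg, "sequence contains letters outside the 20-letter alphabet + X")
  if (L > 1 && any(diff(object@resno) <= 0))
    msg <- c(msg, "residue numbers must be strictly increasing")
  need <- c("resno", "elety", "x", "y", "z")
  if (!all(need %in% names(object@atoms))) {
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  } else {
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      msg <- c(msg, "atom coordinates must be finite")
    ca <- object@atoms$resno[object@atoms$elety == "CA"]
    miss <- setdiff(object@resno, ca)
    if (length(miss))
      msg <- c(msg, paste("residue(s) missing CA atom:",
                          paste(miss, collapse = ", ")))
    if (!all(object@atoms$resno %in% object@resno))
      msg <- c(msg, "atoms reference residue numbers absent from resno")
  }
  if (length(msg)) msg else TRUE
})

#' Pool of models for one target
#'
#' Holds the decoy models of a single target, optionally the native
#' structure and per-model external score rows, and optional predicted
#' secondary structure / solvent accessibility strings for the target
#' sequence.
#'
#' @slot targetId single string.
#' @slot models named list of \linkS4class{ProteinModel} (names = model ids).
#' @slot native a \linkS4class{ProteinModel} or NULL.
#' @slot externalScores data.frame with a \code{model} column plus raw
#'   score columns, or NULL.
#' @slot ssPred 3-state {H,E,C} string of target length, or NA.
#' @slot saPred 2-state {e,b} string of target length, or NA.
#'
#' @exportClass ModelPool
setClass("ModelPool",
         representation(targetId = "character",
                        models = "list",
                        native = "ANY",
                        externalScores = "ANY",
                        ssPred = "character",
                        saPred = "character"),
         prototype(native = NULL, externalScores = NULL,
                   ssPred = NA_character_, saPred = NA_character_))

setValidity("ModelPool", function(object) {
  msg <- character()
  ids <- vapply(object@models, modelId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate model ids in pool")
  if (!is.null(object@native)) {
    if (!is(object@native, "ProteinModel"))
      msg <- c(msg, "native must be a ProteinModel or NULL")
    else {
      seqs <- unique(vapply(object@models, modelSequence, character(1)))
      if (length(seqs) && !all(seqs == modelSequence(object@native)))
        msg <- c(msg, "native sequence differs from model sequences")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Feature vector for one model
#'
#' Named scores in [0,1] over a configured feature set, with a provenance
#' flag per entry: "computed" (from structure), "external" (normalized
#' external score) or "imputed" (missing input, neutral 0.5).
#'
#' @slot values named numeric vector, all entries in [0,1].
#' @slot provenance named character vector, same names as \code{values}.
#' @slot featureSet feature-set name, "full16" or "deepqa9".
#'
#' @exportClass FeatureVector
setClass("FeatureVector",
         representation(values = "numeric",
                        provenance = "character",
                        featureSet = "character"))

setValidity("FeatureVector", function(object) {
  msg <- character()
  keys <- featureSetKeys(object@featureSet)
  if (!identical(names(object@values), keys))
    msg <- c(msg, "values must be named exactly by the configured feature keys, in order")
  if (!identical(names(object@provenance), keys))
    msg <- c(msg, "provenance must mirror the feature keys")
  if (any(!is.finite(object@values)) ||
      any(object@values < 0) || any(object@values > 1))
    msg <- c(msg, "all feature values must lie in [0,1]")
  if (!all(object@provenance %in% c("computed", "external", "imputed")))
    msg <- c(msg, "provenance flags must be computed/external/imputed")
  if (length(msg)) msg else TRUE
})

#' Deep belief network quality regressor
#'
#' Two stacked restricted Boltzmann machine layers and a logistic output
#' node. Feed-forward prediction applies the logistic function at both
#' hidden layers and the output, so predictions always lie in (0,1).
#'
#' @slot rbm1 list(W, vbias, hbias): input -> N1 layer.
#' @slot rbm2 list(W, vbias, hbias): N1 -> N2 layer.
#' @slot outW numeric vector of length N2 (output weights).
#' @slot outB single numeric (output bias).
#' @slot featureSet feature-set name the model expects.
#' @slot config the \code{dbnTrainConfig()} list used in training.
#' @slot metadata list: seed, epochs, final training MSE, timestamps.
#'
#' @exportClass DBNModel
setClass("DBNModel",
         representation(rbm1 = "list", rbm2 = "list",
                        outW = "numeric", outB = "numeric",
                        featureSet = "character",
                        config = "list", metadata = "list"))

setValidity("DBNModel", function(object) {
  msg <- character()
  w1 <- object@rbm1$W; w2 <- object@rbm2$W
  if (!is.matrix(w1) || !is.matrix(w2))
    msg <- c(msg, "rbm layers must carry weight matrices")
  else {
    if (ncol(w1) != nrow(w2))
      msg <- c(msg, "rbm1 hidden dimension must match rbm2 visible dimension")
    if (length(object@outW) != ncol(w2))
      msg <- c(msg, "output weight length must match rbm2 hidden dimension")
    if (!all(is.finite(w1)) || !all(is.finite(w2)) ||
        !all(is.finite(object@outW)) || !is.finite(object@outB))
      msg <- c(msg, "all weights must be finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinModel", function(object) {
  cat(sprintf("ProteinModel '%s': %d residues, %d atoms\n",
              object@modelId, length(object@resno), nrow(object@atoms)))
  cat("  sequence:", abbreviateSeq(object@sequence), "\n")
})

setMethod("show", "ModelPool", function(object) {
  cat(sprintf("ModelPool '%s': %d models%s%s\n", object@targetId,
              length(object@models),
              if (!is.null(object@native)) ", native present" else "",
              if (!is.null(object@externalScores)) ", external scores present" else ""))
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector [%s]\n", object@featureSet))
  print(round(object@values, 4))
})

setMethod("show", "DBNModel", function(object) {
  cat(sprintf("DBNModel: %d -> %d -> %d -> 1 (feature set '%s')\n",
              nrow(object@rbm1$W), ncol(object@rbm1$W),
              ncol(object@rbm2$W), object@featureSet))
  if (!is.null(object@metadata$finalMSE))
    cat(sprintf("  final training MSE: %.5f\n", object@metadata$finalMSE))
})

abbreviateSeq <- function(s) {
  if (nchar(s) <= 40) s else paste0(substr(s, 1, 37), "...")
}
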