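#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the package classes.
#' @return The requested component: a string for \code{modelId} /
#'   \code{modelSequence}, an integer for \code{nResidues}, a numeric
#'   matrix for \code{caCoords} (L x 3, CA atoms in residue order),
#'   a data.frame for \code{atomTable}, a named list for \code{poolModels},
#'   a \linkS4class{ProteinModel} or NULL for \code{poolNative},
#'   a named numeric vector for \code{featureValues} and a named
#'   character vector for \code{featureProvenance}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("modelSequence", function(x) standardGeneric("modelSequence"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("poolModels", function(x) standardGeneric("poolModels"))
#' @rdname accessors
#' @export
setGeneric("poolNative", function(x) standardGeneric("poolNative"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureProvenance", function(x) standardGeneric("featureProvenance"))

#' @rdname accessors
setMethod("modelId", "ProteinModel", function(x) x@modelId)
#' @rdname accessors
setMethod("modelSequence", "ProteinModel", function(x) x@sequence)
#' @rdname accessors
setMethod("nResidues", "ProteinModel", function(x) length(x@resno))
#' @rdname accessors
setMethod("caCoords", "ProteinModel", function(x) {
  ca <- x@atoms[x@atoms$elety == "CA", , drop = FALSE]
  ca <- ca[match(x@resno, ca$resno), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- x@resno
  m
})
#' @rdname accessors
setMethod("atomTable", "ProteinModel", function(x) x@atoms)
#' @rdname accessors
setMethod("poolModels", "ModelPool", function(x) x@models)
#' @rdname accessors
setMethod("poolNative", "ModelPool", function(x) x@native)
#' @rdname accessors
setMethod("featureValues", "FeatureVector", function(x) x@values)
#' @rdname accessors
setMethod("featureProvenance", "FeatureVector", function(x) x@provenance)
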