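#' @rdname accessors
#' @export
setGeneric("smilesOf", function(x) standardGeneric("smilesOf"))

#' @rdname accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname accessors
#' @export
setGeneric("tokenIds", function(x) standardGeneric("tokenIds"))

#' @rdname accessors
#' @export
setGeneric("atomTokenPositions", function(x) standardGeneric("atomTokenPositions"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname accessors
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))

#' @rdname accessors
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("alignmentPairs", function(x) standardGeneric("alignmentPairs"))

#' @rdname accessors
#' @export
setGeneric("maskedGraphIdx", function(x) standardGeneric("maskedGraphIdx"))

#' @rdname accessors
#' @export
setGeneric("maskedSmilesIdx", function(x) standardGeneric("maskedSmilesIdx"))

#' @rdname accessors
#' @export
setGeneric("maskedTokenPositions", function(x) standardGeneric("maskedTokenPositions"))

#' @rdname accessors
#' @export
setGeneric("maskedNodeFlags", function(x) standardGeneric("maskedNodeFlags"))

#' @rdname accessors
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @rdname accessors
#' @export
setGeneric("tokenToId", function(x) standardGeneric("tokenToId"))

#' Accessors for tandemol S4 objects
#'
#' Small read-only accessors for the package's data containers.
#'
#' @param x a `Vocabulary`, `TokenizedSmiles`, `MolGraph`, `AtomAlignment`
#'   or `MaskPlan` object.
#' @return The requested slot content; `alignmentPairs` returns a two-column
#'   integer matrix of (tokenPosition, nodeIndex) pairs.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("smilesOf", "TokenizedSmiles", function(x) x@smiles)
#' @rdname accessors
#' @export
setMethod("smilesOf", "MolGraph", function(x) x@smiles)
#' @rdname accessors
#' @export
setMethod("tokens", "TokenizedSmiles", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("tokenIds", "TokenizedSmiles", function(x) x@tokenIds)
#' @rdname accessors
#' @export
setMethod("atomTokenPositions", "TokenizedSmiles", function(x) x@atomTokenPositions)
#' @rdname accessors
#' @export
setMethod("nAtoms", "MolGraph", function(x) x@nAtoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "AtomAlignment", function(x) x@nAtoms)
#' @rdname accessors
#' @export
setMethod("nAtoms", "MaskPlan", function(x) x@nAtoms)
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "MolGraph", function(x) x@nodeFeatures)
#' @rdname accessors
#' @export
setMethod("edgeFeatures", "MolGraph", function(x) x@edgeFeatures)
#' @rdname accessors
#' @export
setMethod("edgeList", "MolGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("atomTable", "MolGraph", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("alignmentPairs", "AtomAlignment", function(x) {
  cbind(tokenPosition = x@tokenPositions, nodeIndex = seq_len(x@nAtoms))
})
#' @rdname accessors
#' @export
setMethod("maskedGraphIdx", "MaskPlan", function(x) x@maskedGraph)
#' @rdname accessors
#' @export
setMethod("maskedSmilesIdx", "MaskPlan", function(x) x@maskedSmiles)
#' @rdname accessors
#' @export
setMethod("maskedTokenPositions", "MaskPlan", function(x) x@tokenPositions)
#' @rdname accessors
#' @export
setMethod("maskedNodeFlags", "MaskPlan", function(x) x@maskedNodeFlags)
#' @rdname accessors
#' @export
setMethod("vocabSize", "Vocabulary", function(x) length(x@ids))
#' @rdname accessors
#' @export
setMethod("tokenToId", "Vocabulary", function(x) x@ids)
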