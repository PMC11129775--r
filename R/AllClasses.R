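#' @import methods
NULL

#' Token vocabulary for SMILES sequences
#'
#' Maps every token string observed in a corpus to a dense integer id.
#' Ids run 1..V with the three reserved tokens first: pad (1), mask (2)
#' and unknown (3). Built by [buildVocabulary()] and serialized to JSON
#' by [saveVocabulary()] / [loadVocabulary()].
#'
#' @slot ids named integer vector; names are token strings, values the ids.
#' @export
setClass("Vocabulary", representation(ids = "integer"))

setValidity("Vocabulary", function(object) {
  v <- object@ids
  msgs <- character(0)
  if (is.null(names(v)) || anyNA(names(v)) || any(names(v) == ""))
    msgs <- c(msgs, "all ids must be named by token strings")
  if (anyDuplicated(names(v)))
    msgs <- c(msgs, "token names must be unique")
  if (length(v) && !identical(sort(unname(v)), seq_len(length(v))))
    msgs <- c(msgs, "ids must be dense 1..V")
  for (tok in c(".pad.", ".mask.", ".unk.")) {
    if (!tok %in% names(v)) msgs <- c(msgs, paste0("reserved token ", tok, " missing"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Tokenized SMILES string
#'
#' A lossless tokenization of one SMILES string: concatenating `tokens`
#' reproduces the input exactly. `atomTokenPositions` lists (1-based,
#' strictly increasing) the token indices that hold atom tokens; the k-th
#' entry corresponds to the k-th heavy atom of the molecule, which is the
#' basis of the atom-index alignment between the SMILES and the graph.
#'
#' @slot smiles the input string.
#' @slot tokens character vector of tokens in order.
#' @slot tokenIds integer vector of vocabulary ids, same length as tokens.
#' @slot atomTokenPositions integer vector of atom-token indices.
#' @export
setClass("TokenizedSmiles", representation(
  smiles = "character",
  tokens = "character",
  tokenIds = "integer",
  atomTokenPositions = "integer"
))

setValidity("TokenizedSmiles", function(object) {
  msgs <- character(0)
  if (length(object@smiles) != 1L) msgs <- c(msgs, "smiles must be length 1")
  if (!identical(paste0(object@tokens, collapse = ""), object@smiles))
    msgs <- c(msgs, "tokens must concatenate to the original smiles")
  if (length(object@tokenIds) != length(object@tokens))
    msgs <- c(msgs, "tokenIds and tokens must have equal length")
  p <- object@atomTokenPositions
  if (length(p)) {
    if (any(p < 1L | p > length(object@tokens)))
      msgs <- c(msgs, "atomTokenPositions out of range")
    else {
      if (is.unsorted(p, strictly = TRUE))
        msgs <- c(msgs, "atomTokenPositions must be strictly increasing")
      if (!all(vapply(object@tokens[p], classifyToken, character(1)) == "atom"))
        msgs <- c(msgs, "every atomTokenPosition must hold an atom token")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Molecular graph with node and edge features
#'
#' Heavy-atom graph of one molecule. Node index order equals the order in
#' which atoms appear in the source SMILES string (this is what makes the
#' atom-index alignment with the tokenized SMILES a trivial bijection).
#' Edges are directed and each bond contributes both directions.
#'
#' @slot smiles source SMILES string.
#' @slot nAtoms number of heavy atoms.
#' @slot nodeFeatures numeric matrix [nAtoms x F_v]; see [featurizeGraph()]
#'   for the schema.
#' @slot edges integer matrix [nEdges x 2] of (from, to) node indices.
#' @slot edgeFeatures numeric matrix [nEdges x F_e].
#' @slot atoms data.frame of per-atom annotations (element, aromatic,
#'   charge, hcount, chirality, degree, inRing) used by scaffolds and
#'   synthetic labels.
#' @export
setClass("MolGraph", representation(
  smiles = "character",
  nAtoms = "integer",
  nodeFeatures = "matrix",
  edges = "matrix",
  edgeFeatures = "matrix",
  atoms = "data.frame"
))

setValidity("MolGraph", function(object) {
  msgs <- character(0)
  n <- object@nAtoms
  if (nrow(object@nodeFeatures) != n) msgs <- c(msgs, "nodeFeatures rows != nAtoms")
  if (!all(is.finite(object@nodeFeatures))) msgs <- c(msgs, "nodeFeatures must be finite")
  e <- object@edges
  if (nrow(e) != nrow(object@edgeFeatures)) msgs <- c(msgs, "edges/edgeFeatures row mismatch")
  if (nrow(e)) {
    if (any(e < 1L | e > n)) msgs <- c(msgs, "edge endpoint out of range")
    # both directions of every bond must be present
    key <- paste(e[, 1], e[, 2])
    rev <- paste(e[, 2], e[, 1])
    if (!all(rev %in% key)) msgs <- c(msgs, "each bond must appear in both directions")
    if (!all(is.finite(object@edgeFeatures))) msgs <- c(msgs, "edgeFeatures must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Atom-index alignment between SMILES tokens and graph nodes
#'
#' The order-preserving bijection between atom-token positions in a
#' tokenized SMILES and node indices in the molecular graph: the k-th atom
#' token corresponds to node k. Produced by [alignAtoms()].
#'
#' @slot tokenPositions integer vector; entry k is the token index of the
#'   k-th atom token (so the pairs are (tokenPositions[k], k)).
#' @slot nAtoms number of atoms (= length of tokenPositions).
#' @export
setClass("AtomAlignment", representation(
  tokenPositions = "integer",
  nAtoms = "integer"
))

setValidity("AtomAlignment", function(object) {
  msgs <- character(0)
  if (length(object@tokenPositions) != object@nAtoms)
    msgs <- c(msgs, "tokenPositions length must equal nAtoms")
  if (length(object@tokenPositions) > 1L &&
      is.unsorted(object@tokenPositions, strictly = TRUE))
    msgs <- c(msgs, "tokenPositions must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' Coordinated mask plan for one molecule
#'
#' The masked atom-index sets for the two modalities, drawn in the shared
#' atom-index space established by [alignAtoms()]. Under the default
#' non-overlapping strategy (overlap rho = 0) the SMILES set is disjoint
#' from the graph set, so each modality retains an unmasked view of every
#' atom the other modality hides.
#'
#' @slot maskedGraph integer vector I_G of masked node indices.
#' @slot maskedSmiles integer vector I_S of masked atom indices (atoms whose
#'   SMILES tokens are masked).
#' @slot tokenPositions integer vector of token indices corresponding to
#'   maskedSmiles (mapped through the alignment).
#' @slot maskedNodeFlags logical vector of length nAtoms, TRUE at I_G.
#' @slot nAtoms number of atoms in the molecule.
#' @slot seed integer seed the plan was drawn with.
#' @export
setClass("MaskPlan", representation(
  maskedGraph = "integer",
  maskedSmiles = "integer",
  tokenPositions = "integer",
  maskedNodeFlags = "logical",
  nAtoms = "integer",
  seed = "integer"
))

setValidity("MaskPlan", function(object) {
  msgs <- character(0)
  n <- object@nAtoms
  if (any(object@maskedGraph < 1L | object@maskedGraph > n))
    msgs <- c(msgs, "maskedGraph indices out of range")
  if (any(object@maskedSmiles < 1L | object@maskedSmiles > n))
    msgs <- c(msgs, "maskedSmiles indices out of range")
  if (anyDuplicated(object@maskedGraph)) msgs <- c(msgs, "maskedGraph has duplicates")
  if (anyDuplicated(object@maskedSmiles)) msgs <- c(msgs, "maskedSmiles has duplicates")
  if (length(object@maskedNodeFlags) != n)
    msgs <- c(msgs, "maskedNodeFlags length must equal nAtoms")
  if (!identical(which(object@maskedNodeFlags), sort(object@maskedGraph)))
    msgs <- c(msgs, "maskedNodeFlags must mark exactly maskedGraph")
  if (length(object@tokenPositions) != length(object@maskedSmiles))
    msgs <- c(msgs, "tokenPositions must map maskedSmiles one-to-one")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary of", length(object@ids), "tokens (3 reserved)\n")
})

setMethod("show", "TokenizedSmiles", function(object) {
  cat("TokenizedSmiles:", object@smiles, "\n",
      length(object@tokens), "tokens,",
      length(object@atomTokenPositions), "atom tokens\n")
})

setMethod("show", "MolGraph", function(object) {
  cat("MolGraph:", object@smiles, "\n ",
      object@nAtoms, "atoms,", nrow(object@edges) / 2, "bonds; F_v =",
      ncol(object@nodeFeatures), ", F_e =", ncol(object@edgeFeatures), "\n")
})

setMethod("show", "AtomAlignment", function(object) {
  cat("AtomAlignment of", object@nAtoms, "atoms\n")
})

setMethod("show", "MaskPlan", function(object) {
  cat("MaskPlan:", length(object@maskedGraph), "graph-masked,",
      length(object@maskedSmiles), "SMILES-masked of",
      object@nAtoms, "atoms (overlap",
      length(intersect(object@maskedGraph, object@maskedSmiles)), ")\n")
})
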