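#' Align SMILES atom tokens with graph nodes
#'
#' Establishes the order-preserving bijection between atom-token positions
#' in a tokenized SMILES and node indices in the molecular graph built from
#' the same string: the k-th atom token maps to node k. Because the graph
#' is constructed from the identical (non-canonicalized) string, the
#' bijection is exact whenever both objects derive from the same SMILES.
#'
#' @param ts a [TokenizedSmiles-class] object.
#' @param g a [MolGraph-class] object built from the same SMILES.
#' @return an [AtomAlignment-class] object.
#' @examples
#' v <- buildVocabulary("CC(=O)O")
#' ts <- tokenizeSmiles("CC(=O)O", v)
#' g <- featurizeGraph("CC(=O)O")
#' alignmentPairs(alignAtoms(ts, g))
#' @export
alignAtoms <- function(ts, g) {
  stopifnot(is(ts, "TokenizedSmiles"), is(g, "MolGraph"))
  pos <- atomTokenPositions(ts)
  if (length(pos) != nAtoms(g))
    stop("alignment mismatch: ", length(pos), " atom tokens vs ",
         nAtoms(g), " graph nodes for SMILES ", smilesOf(ts), call. = FALSE)
  new("AtomAlignment", tokenPositions = pos, nAtoms = nAtoms(g))
}
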