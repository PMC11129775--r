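# Bemis-Murcko scaffolds.
#
# The scaffold of a molecule is its ring systems plus the linker atoms
# connecting them, obtained by iteratively pruning terminal (degree-1)
# atoms. Scaffold identity is a canonical graph key computed with igraph's
# canonical permutation over atom colors (element + aromaticity), annotated
# with bond orders. Acyclic molecules, whose classical scaffold is empty,
# are keyed by their own canonical heavy-atom graph so that structurally
# distinct acyclic molecules form distinct scaffold groups.

.canonical_graph_key <- function(labels, edges_i, edges_j, orders) {
  n <- length(labels)
  if (n == 1L) return(paste0(labels, "|"))
  ig <- igraph::make_graph(edges = as.vector(rbind(edges_i, edges_j)),
                           n = n, directed = FALSE)
  colors <- as.integer(factor(labels, levels = sort(unique(labels))))
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  # perm[v] = new index of vertex v
  new_labels <- character(n)
  new_labels[perm] <- labels
  if (length(edges_i)) {
    a <- pmin(perm[edges_i], perm[edges_j])
    b <- pmax(perm[edges_i], perm[edges_j])
    ord <- order(a, b)
    ekey <- paste(a[ord], b[ord], orders[ord], sep = ":", collapse = ",")
  } else ekey <- ""
  paste0(paste(new_labels, collapse = "."), "|", ekey)
}

.bond_order_code <- function(fe_row) {
  # edge-feature columns 1:5 = single, double, triple, aromatic, other
  c("1", "2", "3", "a", "x")[which.max(fe_row[1:5])]
}

#' Bemis-Murcko scaffold key of a molecule
#'
#' Computes a canonical string identifying the molecule's scaffold (ring
#' systems + linkers). Two molecules share a key iff their scaffolds are
#' isomorphic as labeled graphs. For acyclic molecules the key is prefixed
#' `acyclic:` and covers the whole heavy-atom graph.
#'
#' @param smiles a SMILES string.
#' @return character scaffold key.
#' @export
scaffoldKey <- function(smiles) {
  g <- featurizeGraph(smiles)
  at <- atomTable(g)
  n <- nAtoms(g)
  e <- edgeList(g)
  ef <- edgeFeatures(g)
  und <- which(e[, 1] < e[, 2])
  ei <- e[und, 1]; ej <- e[und, 2]
  orders <- vapply(und, function(k) .bond_order_code(ef[k, ]), "")
  labels <- paste0(at$element, ifelse(at$aromatic, "~", ""))
  if (!any(at$inRing))
    return(paste0("acyclic:", .canonical_graph_key(labels, ei, ej, orders)))
  keep <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    for (k in seq_along(ei)) if (keep[ei[k]] && keep[ej[k]]) {
      deg[ei[k]] <- deg[ei[k]] + 1L
      deg[ej[k]] <- deg[ej[k]] + 1L
    }
    leaf <- keep & deg <= 1L
    if (!any(leaf)) break
    keep[leaf] <- FALSE
  }
  sub <- which(keep)
  remap <- match(seq_len(n), sub)
  ke <- which(keep[ei] & keep[ej])
  .canonical_graph_key(labels[sub], remap[ei[ke]], remap[ej[ke]], orders[ke])
}
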