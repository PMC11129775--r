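# Molecular graph featurization.
#
# Feature schema (fixed, documented widths):
#   node features, F_v = 28 columns
#     [1:12]  element one-hot over .ELEMENTS (last column = other)
#     [13:18] degree one-hot 0..5 (capped at 5)
#     [19]    formal charge (numeric)
#     [20]    aromatic flag
#     [21:23] chirality one-hot (none, @, @@)
#     [24:28] attached-H count one-hot 0..4 (capped at 4)
#   edge features, F_e = 10 columns
#     [1:5]   bond type one-hot (single, double, triple, aromatic, other)
#     [6]     conjugation flag
#     [7]     ring membership
#     [8:10]  stereo one-hot (none, up, down)

.ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")

#' Node and edge feature widths
#'
#' Fixed widths of the node (`F_v`) and edge (`F_e`) feature matrices
#' produced by [featurizeGraph()].
#' @return an integer.
#' @export
nodeFeatureWidth <- function() 28L

#' @rdname nodeFeatureWidth
#' @export
edgeFeatureWidth <- function() 10L

.one_hot <- function(idx, width) {
  v <- numeric(width)
  v[idx] <- 1
  v
}

#' Featurize a SMILES string into a molecular graph
#'
#' Parses the SMILES and builds the heavy-atom graph whose node order equals
#' the order of atom tokens in the string (implicit hydrogens are folded
#' into node features; explicit H inside brackets stays part of its bracket
#' atom). Every bond contributes a directed edge in both directions. See the
#' schema comment in the package source and the methods vignette for the
#' exact feature layout.
#'
#' @param smiles a single SMILES string.
#' @return a [MolGraph-class] object.
#' @examples
#' g <- featurizeGraph("CC(=O)O")
#' nAtoms(g)          # 4
#' nrow(edgeList(g))  # 6 directed edges = 3 bonds
#' @export
featurizeGraph <- function(smiles) {
  toks <- .tokenize_raw(smiles)
  parsed <- .parse_smiles(toks, smiles)
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  n <- length(atoms)
  nb <- length(bonds)

  deg <- integer(n)
  osum <- numeric(n)
  for (b in bonds) {
    deg[b$i] <- deg[b$i] + 1L
    deg[b$j] <- deg[b$j] + 1L
    osum[b$i] <- osum[b$i] + b$order
    osum[b$j] <- osum[b$j] + b$order
  }

  hcount <- integer(n)
  for (k in seq_len(n)) {
    a <- atoms[[k]]
    hcount[k] <- if (a$bracket) a$hcount
                 else .implicit_h(if (a$aromatic) tolower(a$element) else a$element,
                                  osum[k])
  }

  # ring membership via bridge detection
  edge_in_ring <- logical(nb)
  if (nb) {
    ig <- igraph::make_graph(
      edges = as.vector(vapply(bonds, function(b) c(b$i, b$j), numeric(2))),
      n = n, directed = FALSE)
    br <- igraph::bridges(ig)
    edge_in_ring <- !(seq_len(nb) %in% as.integer(br))
  }
  atom_in_ring <- logical(n)
  for (k in seq_len(nb)) if (edge_in_ring[k]) {
    atom_in_ring[bonds[[k]]$i] <- TRUE
    atom_in_ring[bonds[[k]]$j] <- TRUE
  }

  # conjugation: aromatic bonds, or bonds where each endpoint carries
  # another incident bond of order >= 2 (or aromatic), or multiple bonds
  # adjacent to another multiple/aromatic bond
  multi_at <- integer(n)  # count of incident bonds with order >= 1.5
  for (b in bonds) if (b$order >= 1.5) {
    multi_at[b$i] <- multi_at[b$i] + 1L
    multi_at[b$j] <- multi_at[b$j] + 1L
  }
  conj <- vapply(bonds, function(b) {
    if (b$aromatic) return(TRUE)
    own <- if (b$order >= 1.5) 1L else 0L
    (multi_at[b$i] - own) >= 1L && (multi_at[b$j] - own) >= 1L ||
      (b$order >= 2 && ((multi_at[b$i] - own) >= 1L || (multi_at[b$j] - own) >= 1L))
  }, logical(1))

  Fv <- matrix(0, nrow = n, ncol = nodeFeatureWidth())
  for (k in seq_len(n)) {
    a <- atoms[[k]]
    e_idx <- match(a$element, .ELEMENTS)
    if (is.na(e_idx)) e_idx <- length(.ELEMENTS) + 1L
    chir_idx <- match(a$chirality, c("none", "@", "@@"))
    Fv[k, ] <- c(.one_hot(e_idx, 12L),
                 .one_hot(min(deg[k], 5L) + 1L, 6L),
                 a$charge,
                 as.numeric(a$aromatic),
                 .one_hot(chir_idx, 3L),
                 .one_hot(min(hcount[k], 4L) + 1L, 5L))
  }

  if (nb) {
    ef1 <- matrix(0, nrow = nb, ncol = edgeFeatureWidth())
    e1 <- matrix(0L, nrow = nb, ncol = 2L)
    for (k in seq_len(nb)) {
      b <- bonds[[k]]
      type_idx <- if (b$aromatic) 4L
                  else if (b$order == 1) 1L
                  else if (b$order == 2) 2L
                  else if (b$order == 3) 3L
                  else 5L
      st_idx <- match(b$stereo, c("none", "up", "down"))
      ef1[k, ] <- c(.one_hot(type_idx, 5L), as.numeric(conj[k]),
                    as.numeric(edge_in_ring[k]), .one_hot(st_idx, 3L))
      e1[k, ] <- c(b$i, b$j)
    }
    edges <- rbind(e1, e1[, 2:1, drop = FALSE])
    efeat <- rbind(ef1, ef1)
  } else {
    edges <- matrix(integer(0), nrow = 0, ncol = 2)
    efeat <- matrix(numeric(0), nrow = 0, ncol = edgeFeatureWidth())
  }
  colnames(edges) <- c("from", "to")

  atom_df <- data.frame(
    element = vapply(atoms, function(a) a$element, ""),
    aromatic = vapply(atoms, function(a) a$aromatic, TRUE),
    charge = vapply(atoms, function(a) as.integer(a$charge), 1L),
    hcount = hcount,
    chirality = vapply(atoms, function(a) a$chirality, ""),
    degree = deg,
    inRing = atom_in_ring,
    stringsAsFactors = FALSE)

  new("MolGraph", smiles = smiles, nAtoms = as.integer(n),
      nodeFeatures = Fv, edges = edges, edgeFeatures = efeat,
      atoms = atom_df)
}
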