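# Deterministic synthetic-molecule generator.
#
# Molecules are assembled from a fragment grammar (chain atoms, aliphatic
# and aromatic rings, halogen and charged terminals, counterion components)
# with per-atom valence bookkeeping, and the SMILES string is written by the
# generator itself, so every candidate is valid by construction. Each
# emitted molecule is still validated through tokenize + featurize + align
# before it is accepted. Generation is a pure function of the spec.

.CHAIN_ELEMENTS <- c("C", "C", "C", "C", "N", "N", "O", "S")  # weighted draw
.MAX_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                  F = 1, Cl = 1, Br = 1, I = 1)

# ring fragment templates: elements, aromatic flag, explicit H (for [nH]),
# free valence per atom
.RING_FRAGMENTS <- list(
  benzene   = list(elements = rep("C", 6), aromatic = TRUE,  hExpl = rep(NA, 6), free = rep(1, 6)),
  pyridine  = list(elements = c("N", rep("C", 5)), aromatic = TRUE, hExpl = rep(NA, 6), free = c(0, rep(1, 5))),
  pyrrole   = list(elements = c("N", rep("C", 4)), aromatic = TRUE, hExpl = c(1, rep(NA, 4)), free = c(0, rep(1, 4))),
  thiophene = list(elements = c("S", rep("C", 4)), aromatic = TRUE, hExpl = rep(NA, 5), free = c(0, rep(1, 4))),
  furan     = list(elements = c("O", rep("C", 4)), aromatic = TRUE, hExpl = rep(NA, 5), free = c(0, rep(1, 4))),
  cyclohexane  = list(elements = rep("C", 6), aromatic = FALSE, hExpl = rep(NA, 6), free = rep(2, 6)),
  cyclopentane = list(elements = rep("C", 5), aromatic = FALSE, hExpl = rep(NA, 5), free = rep(2, 5)),
  cyclopropane = list(elements = rep("C", 3), aromatic = FALSE, hExpl = rep(NA, 3), free = rep(2, 3))
)

.COUNTERIONS <- c("[Cl-]", "[Br-]", "[Na+]", "[K+]", "[I-]")
.CHARGED_TERMINALS <- list(
  list(element = "O", charge = -1L, hExpl = 0L),   # [O-]
  list(element = "N", charge = 1L, hExpl = 3L),    # [NH3+]
  list(element = "S", charge = -1L, hExpl = 0L))   # [S-]

#' Specification for the synthetic-molecule generator
#'
#' @param nMolecules number of molecules to generate.
#' @param seed integer seed; generation is deterministic per spec.
#' @param sizeRange integer range of heavy-atom counts per molecule (a
#'   counterion component, when drawn, may add one atom above the maximum).
#' @param rings,branches,bracketAtoms,ions,aromatics,multibonds feature
#'   toggles; with all toggles on the corpus is guaranteed to contain at
#'   least one molecule exhibiting each feature.
#' @return a `GenSpec` list.
#' @export
genSpec <- function(nMolecules = 100L, seed = 1L, sizeRange = c(8L, 40L),
                    rings = TRUE, branches = TRUE, bracketAtoms = TRUE,
                    ions = TRUE, aromatics = TRUE, multibonds = TRUE) {
  stopifnot(nMolecules >= 1L, length(sizeRange) == 2L,
            sizeRange[1] >= 1L, sizeRange[2] >= sizeRange[1])
  if (rings && sizeRange[2] < 3L)
    stop("sizeRange too small to contain rings", call. = FALSE)
  structure(list(nMolecules = as.integer(nMolecules), seed = as.integer(seed),
                 sizeRange = as.integer(sizeRange), rings = rings,
                 branches = branches, bracketAtoms = bracketAtoms,
                 ions = ions, aromatics = aromatics, multibonds = multibonds),
            class = "GenSpec")
}

# --- internal molecule builder ------------------------------------------

.new_mol <- function() {
  env <- new.env(parent = emptyenv())
  env$element <- character(0); env$aromatic <- logical(0)
  env$charge <- integer(0); env$hExpl <- integer(0)
  env$free <- numeric(0); env$comp <- integer(0)
  env$bonds <- list()
  env
}

.add_atom <- function(m, element, aromatic = FALSE, charge = 0L,
                      hExpl = NA_integer_, free = NULL, comp = 1L) {
  if (is.null(free)) free <- .MAX_VALENCE[[element]]
  m$element <- c(m$element, element)
  m$aromatic <- c(m$aromatic, aromatic)
  m$charge <- c(m$charge, as.integer(charge))
  m$hExpl <- c(m$hExpl, as.integer(hExpl))
  m$free <- c(m$free, free)
  m$comp <- c(m$comp, comp)
  length(m$element)
}

.add_bond <- function(m, i, j, order) {
  m$bonds[[length(m$bonds) + 1L]] <- c(i = i, j = j, order = order)
  m$free[i] <- m$free[i] - if (order == 1.5) 1 else order
  m$free[j] <- m$free[j] - if (order == 1.5) 1 else order
}

.add_ring <- function(m, attach_to = NA_integer_) {
  frag <- .RING_FRAGMENTS[[sample.int(length(.RING_FRAGMENTS), 1L)]]
  k <- length(frag$elements)
  start <- sample.int(k, 1L)  # rotate so substitution points vary
  ord <- c(start:k, seq_len(start - 1L))
  cp <- if (is.na(attach_to)) max(c(m$comp, 0L)) + 1L else m$comp[attach_to]
  idx <- integer(k)
  for (t in seq_len(k)) {
    p <- ord[t]
    idx[t] <- .add_atom(m, frag$elements[p], frag$aromatic, 0L,
                        frag$hExpl[p], free = frag$free[p], comp = cp)
  }
  border <- if (frag$aromatic) 1.5 else 1
  for (t in seq_len(k))
    .add_bond(m, idx[t], idx[if (t == k) 1L else t + 1L], border)
  # ring bonds are already accounted for in the template free valences
  for (t in seq_len(k)) m$free[idx[t]] <- frag$free[ord[t]]
  if (!is.na(attach_to)) {
    site <- idx[which(m$free[idx] >= 1)[1]]
    .add_bond(m, attach_to, site, 1)
  }
  idx
}

.n_atoms_mol <- function(m) length(m$element)

.build_molecule <- function(target_size, spec, force = character(0)) {
  m <- .new_mol()
  want <- function(f) isTRUE(spec[[f]]) || f %in% force
  # seed component
  if (want("rings") && (("rings" %in% force) || stats::runif(1) < 0.55)) {
    .add_ring(m)
  } else {
    .add_atom(m, sample(.CHAIN_ELEMENTS, 1L))
  }
  guard <- 0L
  while (.n_atoms_mol(m) < target_size && guard < 10L * target_size) {
    guard <- guard + 1L
    open <- which(m$free >= 1)
    if (!length(open)) break
    site <- if (length(open) == 1L) open else sample(open, 1L)
    room <- target_size - .n_atoms_mol(m)
    u <- stats::runif(1)
    if (want("rings") && room >= 6L && u < 0.12) {
      .add_ring(m, attach_to = site)
    } else if (want("bracketAtoms") && u < 0.18) {
      t <- .CHARGED_TERMINALS[[sample.int(length(.CHARGED_TERMINALS), 1L)]]
      j <- .add_atom(m, t$element, FALSE, t$charge, t$hExpl, free = 1,
                     comp = m$comp[site])
      .add_bond(m, site, j, 1)
    } else if (u < 0.30) {
      hal <- sample(c("F", "Cl", "Cl", "Br", "I"), 1L)
      j <- .add_atom(m, hal, comp = m$comp[site])
      .add_bond(m, site, j, 1)
    } else {
      el <- sample(.CHAIN_ELEMENTS, 1L)
      order <- 1
      if (want("multibonds") && !m$aromatic[site] && m$free[site] >= 2 &&
          .MAX_VALENCE[[el]] >= 2) {
        v <- stats::runif(1)
        if (("multibonds" %in% force) || v < 0.18)
          order <- if (m$free[site] >= 3 && .MAX_VALENCE[[el]] >= 3 && v < 0.05) 3 else 2
      }
      j <- .add_atom(m, el, comp = m$comp[site])
      .add_bond(m, site, j, order)
    }
  }
  if (want("ions") && (("ions" %in% force) || stats::runif(1) < 0.20)) {
    ion <- sample(.COUNTERIONS, 1L)
    attr(m, "counterion") <- ion
  }
  m
}

# --- SMILES writer -------------------------------------------------------

.atom_token <- function(m, i) {
  el <- m$element[i]
  arom <- m$aromatic[i]
  sym <- if (arom) tolower(el) else el
  needs_bracket <- m$charge[i] != 0L || !is.na(m$hExpl[i])
  if (!needs_bracket) return(sym)
  h <- if (!is.na(m$hExpl[i]) && m$hExpl[i] > 0L) {
    if (m$hExpl[i] == 1L) "H" else paste0("H", m$hExpl[i])
  } else ""
  ch <- if (m$charge[i] > 0L) {
    if (m$charge[i] == 1L) "+" else paste0("+", m$charge[i])
  } else if (m$charge[i] < 0L) {
    if (m$charge[i] == -1L) "-" else paste0("-", abs(m$charge[i]))
  } else ""
  paste0("[", sym, h, ch, "]")
}

.bond_symbol <- function(order, arom_i, arom_j) {
  if (order == 1) { if (arom_i && arom_j) "-" else "" }
  else if (order == 1.5) { if (arom_i && arom_j) "" else ":" }
  else if (order == 2) "="
  else if (order == 3) "#"
  else "$"
}

.write_component <- function(m, comp_atoms, adj) {
  n_total <- length(m$element)
  visited <- logical(n_total)
  ring_closures <- vector("list", n_total)  # per atom: list of (digit, sym)
  next_digit <- 0L
  tree_children <- vector("list", n_total)
  # DFS to classify tree edges vs ring-closure edges
  used_bond <- logical(length(m$bonds))
  order_of <- function(bid) m$bonds[[bid]]["order"]
  dfs_stack <- comp_atoms[1]
  visited[comp_atoms[1]] <- TRUE
  stack <- list(comp_atoms[1])
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (entry in adj[[v]]) {
      w <- entry[1]; bid <- entry[2]
      if (used_bond[bid]) next
      used_bond[bid] <- TRUE
      if (!visited[w]) {
        visited[w] <- TRUE
        tree_children[[v]] <- c(tree_children[[v]], list(c(w, bid)))
        stack[[length(stack) + 1L]] <- w
      } else {
        next_digit <- next_digit + 1L
        d <- if (next_digit < 10L) as.character(next_digit)
             else paste0("%", next_digit)
        o <- m$bonds[[bid]][["order"]]
        sym <- .bond_symbol(o, m$aromatic[v], m$aromatic[w])
        ring_closures[[v]] <- c(ring_closures[[v]], list(c(d, sym)))
        ring_closures[[w]] <- c(ring_closures[[w]], list(c(d, "")))
      }
    }
  }
  emit <- function(v) {
    out <- .atom_token(m, v)
    for (rc in ring_closures[[v]]) out <- paste0(out, rc[2], rc[1])
    kids <- tree_children[[v]]
    if (length(kids)) {
      for (t in seq_along(kids)) {
        w <- kids[[t]][1]; bid <- kids[[t]][2]
        o <- m$bonds[[bid]][["order"]]
        sym <- .bond_symbol(o, m$aromatic[v], m$aromatic[w])
        sub <- paste0(sym, emit(w))
        out <- paste0(out, if (t < length(kids)) paste0("(", sub, ")") else sub)
      }
    }
    out
  }
  emit(comp_atoms[1])
}

.mol_to_smiles <- function(m) {
  n <- length(m$element)
  adj <- vector("list", n)
  for (bid in seq_along(m$bonds)) {
    b <- m$bonds[[bid]]
    adj[[b[["i"]]]] <- c(adj[[b[["i"]]]], list(c(b[["j"]], bid)))
    adj[[b[["j"]]]] <- c(adj[[b[["j"]]]], list(c(b[["i"]], bid)))
  }
  comps <- unique(m$comp)
  parts <- vapply(comps, function(cp)
    .write_component(m, which(m$comp == cp), adj), "")
  s <- paste(parts, collapse = ".")
  ci <- attr(m, "counterion")
  if (!is.null(ci)) s <- paste(s, ci, sep = ".")
  s
}

# --- public API ----------------------------------------------------------

.validate_molecule <- function(s) {
  out <- tryCatch({
    toks <- .tokenize_raw(s)
    g <- featurizeGraph(s)
    n_atom_tokens <- sum(vapply(toks, classifyToken, "") == "atom")
    identical(paste0(toks, collapse = ""), s) && n_atom_tokens == nAtoms(g)
  }, error = function(e) FALSE)
  isTRUE(out)
}

.heavy_atom_count <- function(s) {
  toks <- .tokenize_raw(s)
  sum(vapply(toks, classifyToken, "") == "atom")
}

.has_feature <- function(s, feature) {
  toks <- .tokenize_raw(s)
  switch(feature,
    rings = any(grepl("^%?[0-9]", toks)),
    branches = "(" %in% toks,
    bracketAtoms = any(startsWith(toks, "[")),
    ions = any(grepl("^\\[.*[+-]", toks)),
    aromatics = any(toks %in% c("b", "c", "n", "o", "p", "s")) ||
      any(grepl("^\\[[0-9]*[bcnops]", toks)),
    multibonds = any(toks %in% c("=", "#")))
}

#' Generate a synthetic SMILES corpus
#'
#' Deterministically assembles valid, diverse molecules from a fragment
#' grammar. Every emitted SMILES tokenizes losslessly, parses into a graph,
#' and satisfies the atom-token/node alignment precondition. With all
#' feature toggles on, the corpus contains at least one molecule exhibiting
#' each toggled feature (rings, branches, bracket atoms, ions, aromatics,
#' double/triple bonds).
#'
#' @param spec a [genSpec()] object.
#' @return character vector of `spec$nMolecules` SMILES strings.
#' @examples
#' generateCorpus(genSpec(5, seed = 1))
#' @export
generateCorpus <- function(spec) {
  stopifnot(inherits(spec, "GenSpec"))
  force_features <- c("rings", "branches", "bracketAtoms", "ions",
                      "aromatics", "multibonds")
  force_features <- force_features[vapply(force_features,
                                          function(f) isTRUE(spec[[f]]), TRUE)]
  .with_seed(spec$seed, {
    out <- character(spec$nMolecules)
    for (i in seq_len(spec$nMolecules)) {
      # the first molecules force one toggled feature each, guaranteeing
      # coverage for any corpus size
      force <- if (i <= length(force_features)) force_features[i] else character(0)
      for (try in 1:25) {
        target <- sample(seq(spec$sizeRange[1], spec$sizeRange[2]), 1L)
        m <- .build_molecule(target, spec, force = force)
        s <- .mol_to_smiles(m)
        if (.validate_molecule(s) &&
            .heavy_atom_count(s) >= spec$sizeRange[1] &&
            (!length(force) || .has_feature(s, force))) break
        s <- NA_character_
      }
      if (is.na(s)) stop("generator failed to produce a valid molecule",
                         call. = FALSE)
      out[i] <- s
    }
    out
  })
}

#' Generate a labeled synthetic dataset
#'
#' For classification the label is the indicator of a counted structural
#' motif: the molecule contains at least one ring. For regression the label
#' is a linear function of atom counts plus Gaussian noise:
#' `y = -1 + 0.2 n_C + 0.7 n_hetero + 0.35 n_ringatoms + N(0, noiseSd)`.
#' The coefficients and noise sd are recorded in the `manifest` attribute.
#' For classification, ring presence is balanced by construction (each
#' molecule's ring toggle is a fair coin flip).
#'
#' @param spec a [genSpec()] object.
#' @param taskKind `"classification"` or `"regression"`.
#' @param noiseSd Gaussian noise sd for regression labels (default 0.1).
#' @return data.frame with columns `smiles` and `label`, attribute
#'   `taskKind`, and attribute `manifest` describing the label function.
#' @export
generateLabeled <- function(spec, taskKind = c("classification", "regression"),
                            noiseSd = 0.1) {
  stopifnot(inherits(spec, "GenSpec"))
  taskKind <- match.arg(taskKind)
  coefs <- c(intercept = -1, carbon = 0.2, hetero = 0.7, ringAtom = 0.35)
  .with_seed(spec$seed + 1L, {
    smiles <- character(spec$nMolecules)
    labels <- numeric(spec$nMolecules)
    for (i in seq_len(spec$nMolecules)) {
      if (taskKind == "classification") {
        # balance ring presence with a fair coin
        want_ring <- stats::runif(1) < 0.5
        sub <- spec
        sub$rings <- want_ring
        sub$aromatics <- want_ring && spec$aromatics
        for (try in 1:25) {
          target <- sample(seq(spec$sizeRange[1], spec$sizeRange[2]), 1L)
          m <- .build_molecule(target, sub,
                               force = if (want_ring) "rings" else character(0))
          s <- .mol_to_smiles(m)
          if (.validate_molecule(s) &&
              .heavy_atom_count(s) >= spec$sizeRange[1] &&
              .has_feature(s, "rings") == want_ring) break
          s <- NA_character_
        }
        if (is.na(s)) stop("generator failed", call. = FALSE)
        smiles[i] <- s
        labels[i] <- as.numeric(want_ring)
      } else {
        for (try in 1:25) {
          target <- sample(seq(spec$sizeRange[1], spec$sizeRange[2]), 1L)
          m <- .build_molecule(target, spec)
          s <- .mol_to_smiles(m)
          if (.validate_molecule(s) &&
              .heavy_atom_count(s) >= spec$sizeRange[1]) break
          s <- NA_character_
        }
        if (is.na(s)) stop("generator failed", call. = FALSE)
        smiles[i] <- s
        at <- atomTable(featurizeGraph(s))
        y <- coefs[["intercept"]] +
          coefs[["carbon"]] * sum(at$element == "C") +
          coefs[["hetero"]] * sum(at$element != "C") +
          coefs[["ringAtom"]] * sum(at$inRing)
        labels[i] <- y + stats::rnorm(1, 0, noiseSd)
      }
    }
    df <- data.frame(smiles = smiles, label = labels, stringsAsFactors = FALSE)
    attr(df, "taskKind") <- taskKind
    attr(df, "manifest") <- list(taskKind = taskKind,
                                 label = if (taskKind == "classification")
                                   "contains >= 1 ring" else "linear atom-count",
                                 coefficients = as.list(coefs),
                                 noiseSd = if (taskKind == "regression") noiseSd else NULL)
    df
  })
}
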