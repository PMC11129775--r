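# Internal SMILES parser.
#
# Builds the heavy-atom bond graph directly from the token stream, which
# guarantees that node order equals the order in which atom tokens appear in
# the string -- the property the atom-index alignment relies on. No
# canonicalization is performed for the same reason. Aromaticity is taken
# from lowercase/bracket notation (no perception); explicit [H] atoms are
# rejected so the atom-token/node bijection stays exact.

# smallest standard valence >= bonded electron count, per element
.DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1,
  b = 3, c = 4, n = c(3, 5), o = 2, p = c(3, 5), s = c(2, 4, 6)
)

.parse_bracket <- function(token) {
  inner <- substr(token, 2L, nchar(token) - 1L)
  rest <- inner
  take <- function(re) {
    m <- regexpr(re, rest, perl = TRUE)
    if (m == 1L) {
      hit <- regmatches(rest, m)
      rest <<- substring(rest, attr(m, "match.length") + 1L)
      hit
    } else NA_character_
  }
  take("^[0-9]+")  # isotope, parsed and ignored
  elem <- take("^([A-Z][a-z]?|[bcnops]|\\*)")
  if (is.na(elem)) stop("invalid bracket atom: ", token, call. = FALSE)
  if (elem %in% c("H", "D", "T"))
    stop("explicit hydrogen atoms are not supported: ", token, call. = FALSE)
  chir <- take("^@@|^@")
  if (is.na(chir)) chir <- "none"
  h <- take("^H[0-9]*")
  hcount <- if (is.na(h)) 0L else if (h == "H") 1L else as.integer(substring(h, 2L))
  chg <- take("^(\\+\\+|--|\\+[0-9]*|-[0-9]*)")
  charge <- if (is.na(chg)) 0L else switch(chg,
    "+" = 1L, "++" = 2L, "-" = -1L, "--" = -2L,
    {
      sign <- if (startsWith(chg, "+")) 1L else -1L
      sign * as.integer(substring(chg, 2L))
    })
  take("^:[0-9]+")  # atom map, ignored
  if (nzchar(rest)) stop("invalid bracket atom: ", token, call. = FALSE)
  aromatic <- elem %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  list(element = if (aromatic) toupper(elem) else elem,
       aromatic = aromatic, charge = charge, hcount = hcount,
       chirality = chir, bracket = TRUE)
}

.parse_plain_atom <- function(token) {
  aromatic <- token %in% c("b", "c", "n", "o", "p", "s")
  list(element = if (aromatic) toupper(token) else token,
       aromatic = aromatic, charge = 0L, hcount = NA_integer_,
       chirality = "none", bracket = FALSE)
}

.bond_from_symbol <- function(sym, arom1, arom2) {
  if (is.null(sym)) {
    if (arom1 && arom2) return(list(order = 1.5, aromatic = TRUE, stereo = "none"))
    return(list(order = 1, aromatic = FALSE, stereo = "none"))
  }
  switch(sym,
    "-" = list(order = 1, aromatic = FALSE, stereo = "none"),
    "=" = list(order = 2, aromatic = FALSE, stereo = "none"),
    "#" = list(order = 3, aromatic = FALSE, stereo = "none"),
    ":" = list(order = 1.5, aromatic = TRUE, stereo = "none"),
    "/" = list(order = 1, aromatic = FALSE, stereo = "up"),
    "\\" = list(order = 1, aromatic = FALSE, stereo = "down"),
    "~" = list(order = 1, aromatic = FALSE, stereo = "none"),
    "$" = list(order = 4, aromatic = FALSE, stereo = "none"),
    stop("unknown bond symbol: ", sym, call. = FALSE))
}

# Parse a token stream into atoms + bonds. Errors on malformed input.
.parse_smiles <- function(tokens, smiles) {
  bad <- function(why) stop("invalid SMILES (", why, "): ", smiles, call. = FALSE)
  atoms <- list()
  bonds <- list()      # each: list(i, j, order, aromatic, stereo)
  prev <- NA_integer_
  pending <- NULL      # pending bond symbol
  stack <- list()      # saved (prev, n_atoms_at_push)
  rings <- list()      # ring-closure key -> list(atom, sym)

  add_bond <- function(i, j, sym) {
    b <- .bond_from_symbol(sym, atoms[[i]]$aromatic, atoms[[j]]$aromatic)
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = b$order,
                                         aromatic = b$aromatic, stereo = b$stereo)
  }

  for (tok in tokens) {
    cls <- classifyToken(tok)
    if (cls == "atom") {
      a <- if (startsWith(tok, "[")) .parse_bracket(tok) else .parse_plain_atom(tok)
      atoms[[length(atoms) + 1L]] <- a
      idx <- length(atoms)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      else if (!is.null(pending)) bad("bond symbol with no preceding atom")
      pending <- NULL
      prev <- idx
    } else if (cls == "bond") {
      if (!is.null(pending)) bad("two consecutive bond symbols")
      if (is.na(prev)) bad("bond symbol with no preceding atom")
      pending <- tok
    } else if (tok == "(") {
      if (is.na(prev)) bad("branch opened before any atom")
      if (!is.null(pending)) bad("bond symbol before branch open")
      stack[[length(stack) + 1L]] <- list(prev = prev, natoms = length(atoms))
    } else if (tok == ")") {
      if (!length(stack)) bad("unmatched closing parenthesis")
      if (!is.null(pending)) bad("dangling bond symbol at branch close")
      top <- stack[[length(stack)]]
      if (top$natoms == length(atoms)) bad("empty branch")
      stack[[length(stack)]] <- NULL
      prev <- top$prev
    } else if (tok == ".") {
      if (!is.null(pending)) bad("bond symbol before dot")
      prev <- NA_integer_
    } else {  # ring closure digit or %nn
      if (is.na(prev)) bad("ring closure before any atom")
      key <- tok
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        if (op$atom == prev) bad("ring bond to the same atom")
        sym <- if (!is.null(pending)) pending else op$sym
        if (!is.null(pending) && !is.null(op$sym) && pending != op$sym)
          bad("conflicting ring-bond symbols")
        add_bond(op$atom, prev, sym)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, sym = pending)
      }
      pending <- NULL
    }
  }
  if (length(stack)) bad("unclosed parenthesis")
  if (length(rings)) bad("unclosed ring bond")
  if (!is.null(pending)) bad("dangling bond symbol")
  if (!length(atoms)) bad("no atoms")
  if (length(bonds)) {
    key <- vapply(bonds, function(b) paste(sort(c(b$i, b$j)), collapse = "-"), "")
    if (anyDuplicated(key)) bad("duplicate bond")
  }
  list(atoms = atoms, bonds = bonds)
}

# implicit hydrogen count for an organic-subset atom
.implicit_h <- function(element, order_sum) {
  val <- .DEFAULT_VALENCE[[element]]
  if (is.null(val)) return(0L)
  used <- floor(order_sum)
  v <- val[val >= used]
  if (!length(v)) return(0L)
  as.integer(v[1] - used)
}
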