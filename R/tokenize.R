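# SMILES tokenization and vocabulary construction.
#
# The tokenizer follows the community-standard SMILES regex: bracket
# expressions are single tokens, Cl/Br are two-character tokens, %nn ring
# closures are one token. Tokenization is lossless by construction and an
# input containing any character the grammar does not cover is rejected.

.SMILES_TOKEN_RE <- paste0(
  "\\[[^][]*\\]",          # bracket atom, e.g. [Fe+3], [nH], [O-]
  "|Br|Cl",                # two-character organic-subset atoms
  "|%[0-9]{2}",            # two-digit ring closure
  "|[BCNOPSFI]",           # single-character organic-subset atoms
  "|[bcnops]",             # aromatic atoms
  "|[-=#:/\\\\~$]",        # bond symbols
  "|[().]",                # branches and dot disconnection
  "|[0-9]"                 # single-digit ring closure
)

.ATOM_PLAIN <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                 "b", "c", "n", "o", "p", "s")
.BOND_TOKENS <- c("-", "=", "#", ":", "/", "\\", "~", "$")

.RESERVED <- c(pad = ".pad.", mask = ".mask.", unk = ".unk.")

#' Classify a SMILES token
#'
#' Assigns each tokenizer output to one of three classes: `atom`
#' (organic-subset element symbols, aromatic lowercase symbols, and any
#' bracketed expression such as `[Fe+3]`), `bond` (`-`, `=`, `#`, `:`, `/`,
#' `\`, `~`, `$`), or `other` (ring-closure digits including `%nn`,
#' parentheses and the dot). Only atom tokens take part in the atom-index
#' alignment and are eligible for masking.
#'
#' @param token a single token string as produced by [tokenizeSmiles()].
#' @return one of `"atom"`, `"bond"`, `"other"`.
#' @examples
#' classifyToken("[Cl-]")  # atom
#' classifyToken("#")      # bond
#' classifyToken("1")      # other
#' @export
classifyToken <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  if (startsWith(token, "[")) return("atom")
  if (token %in% .ATOM_PLAIN) return("atom")
  if (token %in% .BOND_TOKENS) return("bond")
  "other"
}

.tokenize_raw <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("invalid SMILES: empty or not a single string", call. = FALSE)
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(smiles))
    stop("invalid SMILES (untokenizable characters): ", smiles, call. = FALSE)
  toks
}

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into tokens losslessly (concatenating the tokens
#' reproduces the input), looks every token up in the vocabulary (unknown
#' tokens map to the reserved unknown id), and records which token positions
#' hold atom tokens. The input must parse as a molecule: tokenization alone
#' does not validate ring closures or branches, so the string is also run
#' through the molecular-graph parser and rejected if malformed.
#'
#' @param smiles a single SMILES string.
#' @param vocab a [Vocabulary-class] object.
#' @return a [TokenizedSmiles-class] object.
#' @examples
#' v <- buildVocabulary(c("CC(=O)O", "c1ccccc1"))
#' ts <- tokenizeSmiles("CC(=O)O", v)
#' tokens(ts)
#' atomTokenPositions(ts)
#' @export
tokenizeSmiles <- function(smiles, vocab) {
  stopifnot(is(vocab, "Vocabulary"))
  toks <- .tokenize_raw(smiles)
  # reject malformed molecules (unbalanced parens, unclosed rings, ...)
  .parse_smiles(toks, smiles)
  ids <- unname(vocab@ids[toks])
  ids[is.na(ids)] <- vocab@ids[[.RESERVED[["unk"]]]]
  atom_pos <- which(vapply(toks, classifyToken, character(1)) == "atom")
  new("TokenizedSmiles", smiles = smiles, tokens = toks,
      tokenIds = as.integer(ids), atomTokenPositions = as.integer(atom_pos))
}

#' Build a vocabulary from a SMILES corpus
#'
#' Scans every tokenizable SMILES in the corpus and collects all observed
#' tokens, plus the three reserved tokens (pad, mask, unknown) which always
#' take ids 1, 2, 3. Observed tokens are assigned ids in lexicographic
#' order, so the mapping is deterministic across runs and platforms.
#'
#' @param corpus character vector of SMILES strings.
#' @return a [Vocabulary-class] object.
#' @examples
#' v <- buildVocabulary(c("CC", "CO"))
#' tokenToId(v)
#' @export
buildVocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  toks <- unique(unlist(lapply(corpus, .tokenize_raw), use.names = FALSE))
  toks <- sort(toks, method = "radix")
  all_toks <- c(unname(.RESERVED), toks)
  ids <- stats::setNames(seq_along(all_toks), all_toks)
  new("Vocabulary", ids = ids)
}

#' Reserved vocabulary ids
#'
#' @param vocab a [Vocabulary-class] object.
#' @return the integer id of the pad, mask or unknown token.
#' @export
padId <- function(vocab) vocab@ids[[.RESERVED[["pad"]]]]

#' @rdname padId
#' @export
maskId <- function(vocab) vocab@ids[[.RESERVED[["mask"]]]]

#' @rdname padId
#' @export
unkId <- function(vocab) vocab@ids[[.RESERVED[["unk"]]]]

#' Serialize a vocabulary to JSON
#'
#' @param vocab a [Vocabulary-class] object.
#' @param path file path to write to / read from.
#' @return `loadVocabulary` returns a [Vocabulary-class]; `saveVocabulary`
#'   returns `path` invisibly.
#' @export
saveVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "Vocabulary"))
  jsonlite::write_json(as.list(vocab@ids), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveVocabulary
#' @export
loadVocabulary <- function(path) {
  x <- jsonlite::read_json(path)
  new("Vocabulary", ids = stats::setNames(as.integer(unlist(x)), names(x)))
}
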