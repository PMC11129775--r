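# Corpus and property-table I/O.
#
# SMILES corpus: plain text, one SMILES per line, '#'-prefixed comment lines
# and blank lines ignored. Property tables: CSV with header; column "smiles"
# required; every remaining column is one task; empty cells are missing
# labels (NA).

#' Read a SMILES corpus file
#'
#' @param path path to a plain-text file with one SMILES per line. Blank
#'   lines and lines starting with `#` are skipped.
#' @return character vector of SMILES strings.
#' @export
readSmilesFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a SMILES corpus file
#'
#' @param smiles character vector of SMILES strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSmilesFile <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

#' Read a labeled property table
#'
#' Reads a CSV with a required `smiles` column; all remaining columns are
#' numeric task labels (binary labels are 0/1, empty cells are missing).
#' Rows whose SMILES does not parse are dropped with a warning reporting the
#' line numbers.
#'
#' @param path path to the CSV file.
#' @param taskKind `"classification"` or `"regression"`; stored as the
#'   `taskKind` attribute of the result.
#' @return a data.frame with column `smiles` plus one numeric column per
#'   task, and attribute `taskKind`.
#' @export
readPropertyTable <- function(path, taskKind = c("classification", "regression")) {
  taskKind <- match.arg(taskKind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"smiles" %in% names(df)) stop("missing 'smiles' column in ", path, call. = FALSE)
  if (ncol(df) < 2L) stop("no label columns in ", path, call. = FALSE)
  ok <- vapply(df$smiles, function(s)
    !inherits(tryCatch(featurizeGraph(s), error = identity), "error"), TRUE)
  if (any(!ok)) {
    warning("dropped ", sum(!ok), " unparseable row(s) at line(s): ",
            paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  label_cols <- setdiff(names(df), "smiles")
  for (cl in label_cols) df[[cl]] <- as.numeric(df[[cl]])
  all_missing <- apply(is.na(df[label_cols]), 1L, all)
  if (any(all_missing)) {
    warning("dropped ", sum(all_missing), " row(s) with no labels", call. = FALSE)
    df <- df[!all_missing, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "taskKind") <- taskKind
  df
}

#' Write a labeled property table
#'
#' @param records data.frame as returned by [readPropertyTable()] or
#'   [generateLabeled()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePropertyTable <- function(records, path) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
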