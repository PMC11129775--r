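# Reconstruction objectives: masked-token cross-entropy for the SMILES
# branch, scaled cosine error for the graph branch, and their unweighted sum.

#' Masked-token cross-entropy
#'
#' Mean cross-entropy of the per-position token logits against the original
#' token ids, restricted to the masked positions. With no masked positions
#' the loss is defined as 0 with a warning.
#'
#' @param logits numeric matrix [N_S x V].
#' @param targetIds integer vector of original token ids (length N_S).
#' @param maskedPositions integer vector of masked token positions.
#' @return non-negative scalar.
#' @examples
#' logits <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
#' entropyLoss(logits, c(1L, 2L), 1:2)  # ~ 0
#' @export
entropyLoss <- function(logits, targetIds, maskedPositions) {
  stopifnot(is.matrix(logits), length(targetIds) == nrow(logits))
  if (!length(maskedPositions)) {
    warning("no masked positions; entropy loss defined as 0", call. = FALSE)
    return(0)
  }
  sub <- logits[maskedPositions, , drop = FALSE]
  mx <- apply(sub, 1L, max)
  lse <- mx + log(rowSums(exp(sub - mx)))
  picked <- sub[cbind(seq_along(maskedPositions), targetIds[maskedPositions])]
  mean(lse - picked)
}

#' Scaled cosine error
#'
#' Mean over masked rows of `(1 - cos(xhat_i, x_i))^gamma`. Zero-norm rows
#' are stabilized with a small epsilon and flagged with a warning.
#'
#' @param xhat reconstructed feature matrix.
#' @param x original feature matrix (same shape).
#' @param maskedPositions integer vector of masked row indices.
#' @param gamma sharpening exponent (>= 1; default 2).
#' @param eps norm stabilizer.
#' @return non-negative scalar.
#' @examples
#' x <- diag(3)
#' sceLoss(x, x, 1:3)              # 0
#' sceLoss(-x, x, 1:3, gamma = 1)  # 2
#' @export
sceLoss <- function(xhat, x, maskedPositions, gamma = 2, eps = 1e-8) {
  stopifnot(is.matrix(xhat), identical(dim(xhat), dim(x)), gamma >= 1)
  if (!length(maskedPositions)) {
    warning("no masked positions; SCE loss defined as 0", call. = FALSE)
    return(0)
  }
  A <- xhat[maskedPositions, , drop = FALSE]
  B <- x[maskedPositions, , drop = FALSE]
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na < eps) || any(nb < eps))
    warning("zero-norm row in SCE loss; epsilon-stabilized", call. = FALSE)
  cs <- rowSums(A * B) / (pmax(na, eps) * pmax(nb, eps))
  mean((1 - cs)^gamma)
}

#' Combine the two reconstruction losses
#'
#' The total pre-training objective is the plain (unweighted) sum of the
#' SMILES entropy loss and the graph scaled-cosine-error loss.
#'
#' @param lEn entropy loss value.
#' @param lSce SCE loss value.
#' @param nMaskedSmiles,nMaskedGraph masked-position counts for the report.
#' @return a `LossReport` list with fields `l_en`, `l_sce`, `l_total`,
#'   `n_masked_smiles`, `n_masked_graph`.
#' @export
totalLoss <- function(lEn, lSce, nMaskedSmiles = NA_integer_,
                      nMaskedGraph = NA_integer_) {
  if (!is.finite(lEn) || !is.finite(lSce))
    stop("non-finite loss component", call. = FALSE)
  structure(list(l_en = lEn, l_sce = lSce, l_total = lEn + lSce,
                 n_masked_smiles = nMaskedSmiles,
                 n_masked_graph = nMaskedGraph),
            class = "LossReport")
}

#' @export
print.LossReport <- function(x, ...) {
  cat(sprintf("LossReport: total %.4f (entropy %.4f + sce %.4f); masked %s/%s\n",
              x$l_total, x$l_en, x$l_sce,
              x$n_masked_smiles, x$n_masked_graph))
  invisible(x)
}
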