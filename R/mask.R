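# Coordinated (non-overlapping) mask sampling.
#
# Default strategy: draw I_G uniformly among the nodes, then draw I_S from
# the complement of I_G in the shared atom-index space, so that
# I_S \cap I_G = {} (overlap rho = 0, the operation P of the masking
# strategy). The generalized variant forces exactly round(rho * |I_S|)
# members of I_S to come from I_G, which reduces to the default at rho = 0
# and to I_S being a subset of I_G at rho = 1 (when feasible).

# run expr with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Number of atoms to mask at a given ratio
#'
#' Rounding rule for the per-molecule masked count: `max(1, round(r * n))`
#' for `r > 0` and `n >= 1`, else 0. The floor of one masked atom guarantees
#' a reconstruction signal even on very small molecules.
#'
#' @param r mask ratio in \[0, 1\].
#' @param n number of atoms.
#' @return integer masked count.
#' @export
maskedCount <- function(r, n) {
  stopifnot(r >= 0, n >= 0)
  if (r == 0 || n == 0) return(0L)
  max(1L, as.integer(round(r * n)))
}

#' Sample a coordinated mask plan
#'
#' Draws the masked node set I_G (size `maskedCount(rG, n)`) uniformly
#' without replacement, then the masked SMILES atom set I_S (size
#' `maskedCount(rS, n)`) with exactly `round(overlap * |I_S|)` members from
#' I_G and the remainder from its complement. Both ratios are taken over all
#' atoms of the molecule, so `rS` means the same thing at every overlap
#' setting. The plan is a pure function of (alignment, rG, rS, overlap,
#' seed); the caller's RNG stream is untouched.
#'
#' @param align an [AtomAlignment-class] object.
#' @param rG graph mask ratio (default 0.25, the pre-training default).
#' @param rS SMILES mask ratio (default 0.15).
#' @param overlap overlap ratio rho in \[0, 1\] between the two masked sets
#'   (default 0: non-overlapping masking).
#' @param seed integer seed.
#' @return a [MaskPlan-class] object.
#' @examples
#' v <- buildVocabulary("CC(=O)O")
#' ts <- tokenizeSmiles("CC(=O)O", v)
#' al <- alignAtoms(ts, featurizeGraph("CC(=O)O"))
#' p <- sampleMasks(al, seed = 1)
#' intersect(maskedGraphIdx(p), maskedSmilesIdx(p))  # empty at rho = 0
#' @export
sampleMasks <- function(align, rG = 0.25, rS = 0.15, overlap = 0, seed) {
  stopifnot(is(align, "AtomAlignment"), rG >= 0, rS >= 0,
            overlap >= 0, overlap <= 1)
  n <- nAtoms(align)
  kG <- maskedCount(rG, n)
  kS <- maskedCount(rS, n)
  kOv <- as.integer(round(overlap * kS))
  if (kS - kOv > n - kG)
    stop("infeasible mask plan: need ", kS - kOv,
         " non-overlapping SMILES-masked atoms but only ", n - kG,
         " unmasked nodes exist", call. = FALSE)
  if (kOv > kG)
    stop("infeasible mask plan: need ", kOv,
         " overlapping atoms but only ", kG, " nodes are masked", call. = FALSE)
  sets <- .with_seed(as.integer(seed), {
    iG <- sort(sample.int(n, kG))
    from_g <- if (kOv > 0) sample(iG, kOv) else integer(0)
    comp <- setdiff(seq_len(n), iG)
    from_c <- if (kS - kOv > 0) sample(comp, kS - kOv) else integer(0)
    list(iG = iG, iS = sort(c(from_g, from_c)))
  })
  flags <- logical(n)
  flags[sets$iG] <- TRUE
  new("MaskPlan",
      maskedGraph = as.integer(sets$iG),
      maskedSmiles = as.integer(sets$iS),
      tokenPositions = align@tokenPositions[sets$iS],
      maskedNodeFlags = flags,
      nAtoms = n, seed = as.integer(seed))
}

#' Apply a mask plan to the two modalities
#'
#' Produces the corrupted inputs for pre-training: the token-id sequence
#' with the mask id substituted at the token positions mapped from I_S, and
#' the node-feature matrix with rows in I_G zeroed (the graph encoder
#' replaces flagged rows by its learnable mask embedding). All other entries
#' are identical to the originals.
#'
#' @param ts a [TokenizedSmiles-class] object.
#' @param g the matching [MolGraph-class].
#' @param plan a [MaskPlan-class] for the same molecule.
#' @param maskTokenId integer vocabulary id of the mask token.
#' @return list with `maskedTokenIds` (integer vector), `maskedNodeFeatures`
#'   (numeric matrix) and `maskedNodeFlags` (logical vector).
#' @export
applyMasks <- function(ts, g, plan, maskTokenId) {
  stopifnot(is(ts, "TokenizedSmiles"), is(g, "MolGraph"), is(plan, "MaskPlan"))
  if (nAtoms(g) != nAtoms(plan) ||
      length(atomTokenPositions(ts)) != nAtoms(plan))
    stop("mask plan does not match this molecule", call. = FALSE)
  pos <- maskedTokenPositions(plan)
  if (length(pos) && any(pos > length(tokens(ts))))
    stop("internal consistency error: token position out of range", call. = FALSE)
  ids <- tokenIds(ts)
  ids[pos] <- as.integer(maskTokenId)
  X <- nodeFeatures(g)
  flags <- maskedNodeFlags(plan)
  X[flags, ] <- 0
  list(maskedTokenIds = ids, maskedNodeFeatures = X, maskedNodeFlags = flags)
}

#' Summarize realized mask statistics over many plans
#'
#' @param plans list of [MaskPlan-class] objects.
#' @return list with `mean_graph_ratio` = sum |I_G| / sum n_atoms,
#'   `mean_smiles_ratio` = sum |I_S| / sum n_atoms, and `realized_overlap`
#'   = sum |I_S inter I_G| / sum |I_S| (0/0 convention: 0).
#' @export
auditMasks <- function(plans) {
  if (!length(plans)) stop("empty plan list", call. = FALSE)
  nA <- sum(vapply(plans, nAtoms, 1L))
  nG <- sum(vapply(plans, function(p) length(maskedGraphIdx(p)), 1L))
  nS <- sum(vapply(plans, function(p) length(maskedSmilesIdx(p)), 1L))
  nOv <- sum(vapply(plans, function(p)
    length(intersect(maskedGraphIdx(p), maskedSmilesIdx(p))), 1L))
  list(mean_graph_ratio = nG / nA,
       mean_smiles_ratio = nS / nA,
       realized_overlap = if (nS == 0) 0 else nOv / nS)
}
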