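# Model architecture: SMILES transformer encoder, communicative node-edge
# message-passing graph encoder, unified fusion backbone, and the two
# reconstruction decoders. Forward passes are built on the autodiff tape;
# the exported encode*/decode*/fuse functions run a fresh tape in eval mode
# and return plain matrices.

#' Fused cross-modality embeddings
#'
#' Per-token embeddings for the concatenated (SMILES tokens first, then
#' graph nodes) sequence, with the split boundary recorded.
#'
#' @slot embeddings numeric matrix [(N_S + N_G) x d].
#' @slot split integer N_S: rows 1..split are SMILES positions.
#' @export
setClass("FusedEmbeddings", representation(embeddings = "matrix", split = "integer"))

setValidity("FusedEmbeddings", function(object) {
  if (object@split < 0 || object@split > nrow(object@embeddings))
    return("split must lie in [0, nrow(embeddings)]")
  if (!all(is.finite(object@embeddings))) return("embeddings must be finite")
  TRUE
})

setMethod("show", "FusedEmbeddings", function(object) {
  cat("FusedEmbeddings:", nrow(object@embeddings), "x", ncol(object@embeddings),
      "(split at", object@split, ")\n")
})

#' Model configuration
#'
#' @param d embedding width (divisible by `nHeads`).
#' @param nHeads number of attention heads.
#' @param nLayersSmiles transformer layers in the SMILES encoder.
#' @param nLayersGraph message-passing layers in the graph encoder.
#' @param nLayersBackbone self-attention blocks in the fusion backbone
#'   (0 gives the identity limit: concatenation + modality embeddings only).
#' @param nLayersGraphDecoder isomorphism-style layers in the graph decoder.
#' @param maxSeqLen maximum SMILES token-sequence length.
#' @param dropout dropout probability used during training.
#' @param vocabSize vocabulary size (set from the corpus vocabulary).
#' @return a validated `ModelConfig` list.
#' @export
modelConfig <- function(d = 64L, nHeads = 2L, nLayersSmiles = 2L,
                        nLayersGraph = 2L, nLayersBackbone = 2L,
                        nLayersGraphDecoder = 1L, maxSeqLen = 256L,
                        dropout = 0, vocabSize) {
  stopifnot(d >= 1L, nHeads >= 1L, d %% nHeads == 0L,
            nLayersSmiles >= 1L, nLayersGraph >= 1L, nLayersBackbone >= 0L,
            nLayersGraphDecoder >= 1L, maxSeqLen >= 1L,
            dropout >= 0, dropout < 1, vocabSize >= 4L)
  structure(list(d = as.integer(d), nHeads = as.integer(nHeads),
                 nLayersSmiles = as.integer(nLayersSmiles),
                 nLayersGraph = as.integer(nLayersGraph),
                 nLayersBackbone = as.integer(nLayersBackbone),
                 nLayersGraphDecoder = as.integer(nLayersGraphDecoder),
                 maxSeqLen = as.integer(maxSeqLen), dropout = dropout,
                 vocabSize = as.integer(vocabSize)),
            class = "ModelConfig")
}

.xavier <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

.zeros_row <- function(d) matrix(0, 1L, d)
.ones_row <- function(d) matrix(1, 1L, d)

.init_block <- function(p, prefix, d) {
  p[[paste0(prefix, ".ln1.g")]] <- .ones_row(d)
  p[[paste0(prefix, ".ln1.b")]] <- .zeros_row(d)
  for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(prefix, ".", w)]] <- .xavier(d, d)
  for (b in c("bq", "bk", "bv", "bo")) p[[paste0(prefix, ".", b)]] <- .zeros_row(d)
  p[[paste0(prefix, ".ln2.g")]] <- .ones_row(d)
  p[[paste0(prefix, ".ln2.b")]] <- .zeros_row(d)
  p[[paste0(prefix, ".W1")]] <- .xavier(d, 4L * d)
  p[[paste0(prefix, ".b1")]] <- .zeros_row(4L * d)
  p[[paste0(prefix, ".W2")]] <- .xavier(4L * d, d)
  p[[paste0(prefix, ".b2")]] <- .zeros_row(d)
  p
}

#' Initialize a model
#'
#' Creates all learnable parameters (Xavier-initialized, deterministic per
#' seed) for the two encoders, the fusion backbone and the two decoders.
#' The returned object is an environment so the training loop can update
#' weights in place.
#'
#' @param config a [modelConfig()] object.
#' @param seed integer seed for weight initialization.
#' @return an object of class `tandemolModel` (an environment with `params`,
#'   `config`, and `step` fields).
#' @export
initModel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ModelConfig"))
  d <- config$d
  Fv <- nodeFeatureWidth(); Fe <- edgeFeatureWidth()
  p <- list()
  .with_seed(as.integer(seed), {
    # SMILES encoder
    p[["s.tok_emb"]] <- .xavier(config$vocabSize, d)
    p[["s.pos_emb"]] <- .xavier(config$maxSeqLen, d)
    for (l in seq_len(config$nLayersSmiles))
      p <- .init_block(p, paste0("s.block", l), d)
    p[["s.ln_f.g"]] <- .ones_row(d); p[["s.ln_f.b"]] <- .zeros_row(d)
    # graph encoder
    p[["g.node_proj.W"]] <- .xavier(Fv, d); p[["g.node_proj.b"]] <- .zeros_row(d)
    p[["g.edge_proj.W"]] <- .xavier(Fe, d); p[["g.edge_proj.b"]] <- .zeros_row(d)
    p[["g.mask_emb"]] <- .xavier(1L, d)
    for (l in seq_len(config$nLayersGraph)) {
      pre <- paste0("g.layer", l)
      p[[paste0(pre, ".Wq")]] <- .xavier(d, d)
      p[[paste0(pre, ".Wk")]] <- .xavier(d, d)
      p[[paste0(pre, ".Wv")]] <- .xavier(d, d)
      p[[paste0(pre, ".Wn")]] <- .xavier(2L * d, d)
      p[[paste0(pre, ".bn")]] <- .zeros_row(d)
      p[[paste0(pre, ".ln_n.g")]] <- .ones_row(d)
      p[[paste0(pre, ".ln_n.b")]] <- .zeros_row(d)
      p[[paste0(pre, ".We")]] <- .xavier(2L * d, d)
      p[[paste0(pre, ".be")]] <- .zeros_row(d)
      p[[paste0(pre, ".ln_e.g")]] <- .ones_row(d)
      p[[paste0(pre, ".ln_e.b")]] <- .zeros_row(d)
    }
    # fusion backbone
    p[["f.A_S"]] <- .xavier(1L, d)
    p[["f.A_G"]] <- .xavier(1L, d)
    for (l in seq_len(config$nLayersBackbone))
      p <- .init_block(p, paste0("f.block", l), d)
    # SMILES decoder (language-model head)
    p[["ds.W1"]] <- .xavier(d, d); p[["ds.b1"]] <- .zeros_row(d)
    p[["ds.ln.g"]] <- .ones_row(d); p[["ds.ln.b"]] <- .zeros_row(d)
    p[["ds.Wout"]] <- .xavier(d, config$vocabSize)
    p[["ds.bout"]] <- .zeros_row(config$vocabSize)
    # graph decoder (re-mask + isomorphism-style message passing)
    p[["dg.mask_emb"]] <- .xavier(1L, d)
    for (l in seq_len(config$nLayersGraphDecoder)) {
      pre <- paste0("dg.layer", l)
      p[[paste0(pre, ".eps")]] <- matrix(0, 1L, 1L)
      p[[paste0(pre, ".W1")]] <- .xavier(d, d)
      p[[paste0(pre, ".b1")]] <- .zeros_row(d)
      p[[paste0(pre, ".W2")]] <- .xavier(d, d)
      p[[paste0(pre, ".b2")]] <- .zeros_row(d)
    }
    p[["dg.Wrec"]] <- .xavier(d, Fv)
    p[["dg.brec"]] <- .zeros_row(Fv)
  })
  model <- new.env(parent = emptyenv())
  model$params <- p
  model$config <- config
  model$step <- 0L
  class(model) <- "tandemolModel"
  model
}

#' @export
print.tandemolModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("tandemolModel: d =", x$config$d, ",", length(x$params),
      "parameter tensors,", np, "parameters, step", x$step, "\n")
  invisible(x)
}

# parameter-store helper: lazily wraps params as tape leaves, remembers ids
param_binder <- function(tp, params) {
  ids <- new.env(parent = emptyenv())
  P <- function(name) {
    id <- ids[[name]]
    if (is.null(id)) {
      val <- params[[name]]
      if (is.null(val)) stop("unknown parameter: ", name, call. = FALSE)
      id <- tp_leaf(tp, val)
      ids[[name]] <- id
    }
    id
  }
  attr(P, "ids") <- ids
  P
}

param_grads <- function(P, grads) {
  ids <- attr(P, "ids")
  out <- list()
  for (nm in ls(ids)) {
    g <- grads[[ids[[nm]]]]
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

# ---- transformer pieces --------------------------------------------------

# multi-head self-attention sublayer; maskAdd: constant additive logit
# matrix (e.g. -1e9 at padding columns) or NULL
.fwd_mhsa <- function(tp, P, x, prefix, cfg, maskAdd = NULL) {
  d <- cfg$d; nh <- cfg$nHeads; dh <- d %/% nh
  q <- tp_add_rowvec(tp, tp_matmul(tp, x, P(paste0(prefix, ".Wq"))), P(paste0(prefix, ".bq")))
  k <- tp_add_rowvec(tp, tp_matmul(tp, x, P(paste0(prefix, ".Wk"))), P(paste0(prefix, ".bk")))
  v <- tp_add_rowvec(tp, tp_matmul(tp, x, P(paste0(prefix, ".Wv"))), P(paste0(prefix, ".bv")))
  heads <- NULL
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- tp_cols(tp, q, cols)
    kh <- tp_cols(tp, k, cols)
    vh <- tp_cols(tp, v, cols)
    logits <- tp_mul_const(tp, tp_matmul_bt(tp, qh, kh), 1 / sqrt(dh))
    attn <- tp_softmax_rows(tp, logits, maskAdd)
    oh <- tp_matmul(tp, attn, vh)
    heads <- if (is.null(heads)) oh else tp_concat_cols(tp, heads, oh)
  }
  tp_add_rowvec(tp, tp_matmul(tp, heads, P(paste0(prefix, ".Wo"))), P(paste0(prefix, ".bo")))
}

# pre-norm transformer block: x + MHSA(LN(x)); x + FFN(LN(x))
.fwd_block <- function(tp, P, x, prefix, cfg, maskAdd = NULL) {
  h <- tp_layernorm_rows(tp, x, P(paste0(prefix, ".ln1.g")), P(paste0(prefix, ".ln1.b")))
  x <- tp_add(tp, x, .fwd_mhsa(tp, P, h, prefix, cfg, maskAdd))
  h <- tp_layernorm_rows(tp, x, P(paste0(prefix, ".ln2.g")), P(paste0(prefix, ".ln2.b")))
  h <- tp_add_rowvec(tp, tp_matmul(tp, h, P(paste0(prefix, ".W1"))), P(paste0(prefix, ".b1")))
  h <- tp_gelu(tp, h)
  h <- tp_add_rowvec(tp, tp_matmul(tp, h, P(paste0(prefix, ".W2"))), P(paste0(prefix, ".b2")))
  tp_add(tp, x, h)
}

# attention mask matrix: -1e9 logits into padding key columns
.attn_mask_matrix <- function(attentionMask) {
  n <- length(attentionMask)
  M <- matrix(0, n, n)
  M[, !attentionMask] <- -1e9
  M
}

.fwd_smiles_encoder <- function(tp, P, tokenIds, cfg, attentionMask = NULL) {
  n <- length(tokenIds)
  if (n > cfg$maxSeqLen)
    stop("sequence of length ", n, " exceeds maxSeqLen ", cfg$maxSeqLen,
         call. = FALSE)
  emb <- tp_rows(tp, P("s.tok_emb"), tokenIds)
  pos <- tp_rows(tp, P("s.pos_emb"), seq_len(n))
  x <- tp_add(tp, emb, pos)
  maskAdd <- if (is.null(attentionMask)) NULL else .attn_mask_matrix(attentionMask)
  for (l in seq_len(cfg$nLayersSmiles))
    x <- .fwd_block(tp, P, x, paste0("s.block", l), cfg, maskAdd)
  tp_layernorm_rows(tp, x, P("s.ln_f.g"), P("s.ln_f.b"))
}

# communicative node-edge message passing; masked nodes enter as the
# learnable mask embedding
.fwd_graph_encoder <- function(tp, P, X, flags, edges, efeat, cfg) {
  n <- nrow(X)
  if (nrow(edges) && (any(edges < 1L) || any(edges > n)))
    stop("dangling edge index", call. = FALSE)
  h <- tp_add_rowvec(tp, tp_matmul(tp, tp_leaf(tp, X), P("g.node_proj.W")),
                     P("g.node_proj.b"))
  if (any(flags)) {
    keep <- matrix(as.numeric(!flags), n, cfg$d)
    h <- tp_mul_const(tp, h, keep)
    h <- tp_add(tp, h, tp_outer_const(tp, as.numeric(flags), P("g.mask_emb")))
  }
  ne <- nrow(edges)
  if (ne == 0L) {
    for (l in seq_len(cfg$nLayersGraph)) {
      pre <- paste0("g.layer", l)
      z <- tp_concat_cols(tp, h, tp_mul_const(tp, h, 0))
      upd <- tp_gelu(tp, tp_add_rowvec(tp, tp_matmul(tp, z, P(paste0(pre, ".Wn"))),
                                       P(paste0(pre, ".bn"))))
      h <- tp_layernorm_rows(tp, tp_add(tp, h, upd),
                             P(paste0(pre, ".ln_n.g")), P(paste0(pre, ".ln_n.b")))
    }
    return(h)
  }
  src <- edges[, 1L]; tgt <- edges[, 2L]
  e <- tp_add_rowvec(tp, tp_matmul(tp, tp_leaf(tp, efeat), P("g.edge_proj.W")),
                     P("g.edge_proj.b"))
  for (l in seq_len(cfg$nLayersGraph)) {
    pre <- paste0("g.layer", l)
    # attention-weighted aggregation of incoming edge states per target node
    q <- tp_matmul(tp, h, P(paste0(pre, ".Wq")))
    kk <- tp_matmul(tp, e, P(paste0(pre, ".Wk")))
    scores <- tp_mul_const(tp, tp_rowdot(tp, tp_rows(tp, q, tgt), kk),
                           1 / sqrt(cfg$d))
    alpha <- tp_group_softmax(tp, scores, tgt)
    vv <- tp_matmul(tp, e, P(paste0(pre, ".Wv")))
    msg <- tp_rowsum_groups(tp, tp_scale_rows(tp, vv, alpha), tgt, n)
    z <- tp_concat_cols(tp, h, msg)
    upd <- tp_gelu(tp, tp_add_rowvec(tp, tp_matmul(tp, z, P(paste0(pre, ".Wn"))),
                                     P(paste0(pre, ".bn"))))
    h <- tp_layernorm_rows(tp, tp_add(tp, h, upd),
                           P(paste0(pre, ".ln_n.g")), P(paste0(pre, ".ln_n.b")))
    # edge update from the (updated) source node state and the edge state
    ze <- tp_concat_cols(tp, tp_rows(tp, h, src), e)
    eupd <- tp_gelu(tp, tp_add_rowvec(tp, tp_matmul(tp, ze, P(paste0(pre, ".We"))),
                                      P(paste0(pre, ".be"))))
    e <- tp_layernorm_rows(tp, tp_add(tp, e, eupd),
                           P(paste0(pre, ".ln_e.g")), P(paste0(pre, ".ln_e.b")))
  }
  h
}

.fwd_fuse <- function(tp, P, fs, fg, cfg, maskAdd = NULL) {
  ns <- nrow(tp_val(tp, fs))
  fs <- tp_add_rowvec(tp, fs, P("f.A_S"))
  fg <- tp_add_rowvec(tp, fg, P("f.A_G"))
  x <- tp_concat_rows(tp, fs, fg)
  for (l in seq_len(cfg$nLayersBackbone))
    x <- .fwd_block(tp, P, x, paste0("f.block", l), cfg, maskAdd)
  list(node = x, split = ns)
}

.fwd_smiles_decoder <- function(tp, P, x, cfg) {
  h <- tp_add_rowvec(tp, tp_matmul(tp, x, P("ds.W1")), P("ds.b1"))
  h <- tp_gelu(tp, h)
  h <- tp_layernorm_rows(tp, h, P("ds.ln.g"), P("ds.ln.b"))
  tp_add_rowvec(tp, tp_matmul(tp, h, P("ds.Wout")), P("ds.bout"))
}

# graph decoder: re-mask flagged rows with a fresh learnable embedding so
# the decoder cannot shortcut from leaked encoder features, then
# isomorphism-style message passing, then project d -> F_v
.fwd_graph_decoder <- function(tp, P, x, flags, edges, cfg) {
  n <- nrow(tp_val(tp, x))
  if (any(flags)) {
    keep <- matrix(as.numeric(!flags), n, cfg$d)
    x <- tp_mul_const(tp, x, keep)
    x <- tp_add(tp, x, tp_outer_const(tp, as.numeric(flags), P("dg.mask_emb")))
  }
  for (l in seq_len(cfg$nLayersGraphDecoder)) {
    pre <- paste0("dg.layer", l)
    agg <- if (nrow(edges)) {
      tp_rowsum_groups(tp, tp_rows(tp, x, edges[, 1L]), edges[, 2L], n)
    } else tp_mul_const(tp, x, 0)
    scale <- tp_add_const(tp, P(paste0(pre, ".eps")), 1)
    h <- tp_add(tp, tp_scale_scalar(tp, x, scale), agg)
    h <- tp_gelu(tp, tp_add_rowvec(tp, tp_matmul(tp, h, P(paste0(pre, ".W1"))),
                                   P(paste0(pre, ".b1"))))
    x <- tp_add_rowvec(tp, tp_matmul(tp, h, P(paste0(pre, ".W2"))),
                       P(paste0(pre, ".b2")))
  }
  tp_add_rowvec(tp, tp_matmul(tp, x, P("dg.Wrec")), P("dg.brec"))
}

# ---- public eval-mode API ------------------------------------------------

#' Scaled dot-product self-attention
#'
#' `softmax(Q K^T / sqrt(d)) V` with row-wise softmax; optional boolean
#' `keyMask` marks valid key positions (padding keys receive -1e9 logits).
#'
#' @param Q,K,V conforming numeric matrices (K and V with equal row counts,
#'   Q and K with equal width d).
#' @param keyMask optional logical vector, length nrow(K); FALSE = padding.
#' @return numeric matrix [nrow(Q) x ncol(V)].
#' @examples
#' Q <- matrix(rnorm(8), 2); K <- matrix(rnorm(16), 4); V <- diag(4)
#' rowSums(attr(selfAttention(Q, K, V), "weights"))  # all 1
#' @export
selfAttention <- function(Q, K, V, keyMask = NULL) {
  stopifnot(is.matrix(Q), is.matrix(K), is.matrix(V),
            ncol(Q) == ncol(K), nrow(K) == nrow(V), ncol(Q) > 0)
  logits <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(keyMask)) {
    stopifnot(length(keyMask) == nrow(K))
    logits[, !keyMask] <- -1e9
  }
  mx <- apply(logits, 1L, max)
  E <- exp(logits - mx)
  W <- E / rowSums(E)
  out <- W %*% V
  attr(out, "weights") <- W
  out
}

#' Encode a (masked) SMILES token-id sequence
#'
#' Runs the transformer SMILES encoder in eval mode: learned token + position
#' embeddings followed by pre-norm multi-head self-attention blocks.
#'
#' @param model a [initModel()] object.
#' @param tokenIds integer vector of vocabulary ids (mask id at masked
#'   positions).
#' @param attentionMask optional logical vector (FALSE = padding); padding
#'   positions are excluded from attention.
#' @return numeric matrix [N_S x d].
#' @export
encodeSmiles <- function(model, tokenIds, attentionMask = NULL) {
  stopifnot(inherits(model, "tandemolModel"))
  if (any(tokenIds < 1L | tokenIds > model$config$vocabSize))
    stop("token id out of vocabulary range", call. = FALSE)
  tp <- tape_new()
  P <- param_binder(tp, model$params)
  tp_val(tp, .fwd_smiles_encoder(tp, P, tokenIds, model$config, attentionMask))
}

#' Encode a (masked) molecular graph
#'
#' Runs the communicative node-edge message-passing encoder in eval mode:
#' per layer, edge states are updated from incident node states and node
#' states from attention-weighted aggregation of incoming edge states.
#' Flagged (masked) nodes enter as a learnable mask embedding.
#'
#' @param model a [initModel()] object.
#' @param X node-feature matrix [N_G x F_v] (masked rows zeroed).
#' @param flags logical vector of length N_G marking masked nodes.
#' @param edges integer matrix [nEdges x 2] of directed edges.
#' @param efeat edge-feature matrix [nEdges x F_e].
#' @return numeric matrix [N_G x d].
#' @export
encodeGraph <- function(model, X, flags, edges, efeat) {
  stopifnot(inherits(model, "tandemolModel"), nrow(X) == length(flags))
  tp <- tape_new()
  P <- param_binder(tp, model$params)
  tp_val(tp, .fwd_graph_encoder(tp, P, X, flags, edges, efeat, model$config))
}

#' Fuse the two modality embeddings through the unified backbone
#'
#' Adds a learnable modality embedding to each modality (a single d-vector
#' broadcast over the modality's positions), concatenates SMILES rows first,
#' and processes the joint sequence with multi-head self-attention blocks so
#' every position can attend across modalities.
#'
#' @param model a [initModel()] object.
#' @param FS SMILES embeddings [N_S x d].
#' @param FG graph embeddings [N_G x d].
#' @return a [FusedEmbeddings-class] with split = N_S.
#' @export
fuseEmbeddings <- function(model, FS, FG) {
  stopifnot(inherits(model, "tandemolModel"),
            ncol(FS) == model$config$d, ncol(FG) == model$config$d)
  tp <- tape_new()
  P <- param_binder(tp, model$params)
  out <- .fwd_fuse(tp, P, tp_leaf(tp, FS), tp_leaf(tp, FG), model$config)
  new("FusedEmbeddings", embeddings = tp_val(tp, out$node),
      split = as.integer(out$split))
}

#' Decode SMILES-position embeddings into token logits
#'
#' Language-model head: linear + GELU + layer norm + projection to the
#' vocabulary.
#'
#' @param model a [initModel()] object.
#' @param FpS backbone output rows for the SMILES positions [N_S x d].
#' @return logits matrix [N_S x vocabSize].
#' @export
decodeSmiles <- function(model, FpS) {
  stopifnot(inherits(model, "tandemolModel"), ncol(FpS) == model$config$d)
  tp <- tape_new()
  P <- param_binder(tp, model$params)
  tp_val(tp, .fwd_smiles_decoder(tp, P, tp_leaf(tp, FpS), model$config))
}

#' Decode graph-position embeddings into reconstructed node features
#'
#' Re-masks the flagged rows with a fresh learnable embedding (so the
#' decoder input at masked rows is independent of the encoder output there),
#' applies a lightweight isomorphism-style message-passing stack, and
#' projects d to F_v.
#'
#' @param model a [initModel()] object.
#' @param FpG backbone output rows for the graph positions [N_G x d].
#' @param flags logical vector marking masked nodes.
#' @param edges integer edge matrix [nEdges x 2].
#' @param efeat edge features (unused by the decoder; accepted for interface
#'   symmetry with the encoder).
#' @return reconstructed node-feature matrix [N_G x F_v].
#' @export
decodeGraph <- function(model, FpG, flags, edges, efeat = NULL) {
  stopifnot(inherits(model, "tandemolModel"), ncol(FpG) == model$config$d,
            nrow(FpG) == length(flags))
  tp <- tape_new()
  P <- param_binder(tp, model$params)
  tp_val(tp, .fwd_graph_decoder(tp, P, tp_leaf(tp, FpG), flags, edges,
                                model$config))
}
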