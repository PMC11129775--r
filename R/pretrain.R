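# Self-supervised pre-training loop: corpus preparation, coordinated
# masking, joint forward through both encoders + fusion backbone + both
# decoders, reconstruction losses, AdamW updates, logging and checkpoints.

#' Pre-training configuration
#'
#' Defaults: graph mask ratio 25%, SMILES mask ratio 15%, overlap 0
#' (non-overlapping masking), AdamW with base learning rate 1e-3. The
#' default 90000 iterations targets a production-scale run; tests use far
#' fewer.
#'
#' @param corpus path to a SMILES file, or a character vector of SMILES.
#' @param rG graph mask ratio.
#' @param rS SMILES mask ratio.
#' @param overlap overlap ratio rho between the two masked sets.
#' @param iterations number of optimizer steps.
#' @param batchSize molecules per step.
#' @param lr AdamW base learning rate.
#' @param weightDecay AdamW decoupled weight decay.
#' @param gamma SCE sharpening exponent.
#' @param seed master seed; per-step mask seeds and batch composition are
#'   derived from it by a counter-based scheme, so runs are reproducible and
#'   resumable.
#' @param checkpointDir directory for checkpoints (created if needed).
#' @param logFile optional JSON-lines log path.
#' @param logEvery,checkpointEvery logging/checkpoint periods in steps.
#' @param model a [modelConfig()] object, or NULL for the default small
#'   configuration (d = 64, 2 heads, 2+2+2 layers).
#' @return a `PretrainConfig` list.
#' @export
pretrainConfig <- function(corpus, rG = 0.25, rS = 0.15, overlap = 0,
                           iterations = 90000L, batchSize = 8L, lr = 1e-3,
                           weightDecay = 0.01, gamma = 2, seed = 1L,
                           checkpointDir = tempfile("ckpt"),
                           logFile = NULL, logEvery = 10L,
                           checkpointEvery = 1000L, model = NULL) {
  stopifnot(iterations >= 1L, batchSize >= 1L, lr > 0, rG >= 0, rS >= 0,
            overlap >= 0, overlap <= 1)
  structure(list(corpus = corpus, rG = rG, rS = rS, overlap = overlap,
                 iterations = as.integer(iterations),
                 batchSize = as.integer(batchSize), lr = lr,
                 weightDecay = weightDecay, gamma = gamma,
                 seed = as.integer(seed), checkpointDir = checkpointDir,
                 logFile = logFile, logEvery = as.integer(logEvery),
                 checkpointEvery = as.integer(checkpointEvery),
                 model = model),
            class = "PretrainConfig")
}

#' Prepare a corpus for pre-training
#'
#' Tokenizes, featurizes and aligns every molecule once; molecules failing
#' any stage are filtered out with a rejection report so the training step
#' function is total.
#'
#' @param smiles character vector of SMILES.
#' @param vocab optional [Vocabulary-class]; built from the usable corpus if
#'   NULL.
#' @return list with `mols` (per-molecule list of TokenizedSmiles, MolGraph,
#'   AtomAlignment), `vocab`, and `rejected` (data.frame of failures).
#' @export
prepareCorpus <- function(smiles, vocab = NULL) {
  if (!length(smiles)) stop("empty corpus", call. = FALSE)
  ok <- logical(length(smiles))
  reasons <- character(length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch({
      g <- featurizeGraph(smiles[i])
      toks <- .tokenize_raw(smiles[i])
      npos <- sum(vapply(toks, classifyToken, "") == "atom")
      if (npos != nAtoms(g))
        stop("alignment mismatch: ", npos, " atom tokens vs ", nAtoms(g), " nodes")
      TRUE
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) ok[i] <- TRUE else reasons[i] <- res
  }
  if (!any(ok))
    stop("no usable molecules in corpus; rejections:\n",
         paste(utils::head(reasons[!ok], 5L), collapse = "\n"), call. = FALSE)
  usable <- smiles[ok]
  if (is.null(vocab)) vocab <- buildVocabulary(usable)
  mols <- lapply(usable, function(s) {
    ts <- tokenizeSmiles(s, vocab)
    g <- featurizeGraph(s)
    list(ts = ts, g = g, align = alignAtoms(ts, g))
  })
  rejected <- data.frame(index = which(!ok), smiles = smiles[!ok],
                         reason = reasons[!ok], stringsAsFactors = FALSE)
  list(mols = mols, vocab = vocab, rejected = rejected)
}

# counter-based per-molecule mask seed: reproducible and resume-safe
.mask_seed <- function(masterSeed, step, i) {
  ((masterSeed %% 100003L) * 7919 + step * 131 + i * 17) %% 2147483629
}

# forward + loss for one molecule on an existing tape; returns nodes and
# masked counts
.fwd_pretrain_mol <- function(tp, P, mol, plan, vocab, cfg, gamma) {
  masked <- applyMasks(mol$ts, mol$g, plan, maskId(vocab))
  edges <- edgeList(mol$g)
  efeat <- edgeFeatures(mol$g)
  flags <- masked$maskedNodeFlags
  fs <- .fwd_smiles_encoder(tp, P, masked$maskedTokenIds, cfg)
  fg <- .fwd_graph_encoder(tp, P, masked$maskedNodeFeatures, flags,
                           edges, efeat, cfg)
  fused <- .fwd_fuse(tp, P, fs, fg, cfg)
  ns <- fused$split
  ng <- nAtoms(mol$g)
  FpS <- tp_rows(tp, fused$node, seq_len(ns))
  FpG <- tp_rows(tp, fused$node, ns + seq_len(ng))
  logits <- .fwd_smiles_decoder(tp, P, FpS, cfg)
  recon <- .fwd_graph_decoder(tp, P, FpG, flags, edges, cfg)
  ce <- tp_ce_masked(tp, logits, tokenIds(mol$ts), maskedTokenPositions(plan))
  sce <- tp_sce_masked(tp, recon, nodeFeatures(mol$g), maskedGraphIdx(plan),
                       gamma = gamma)
  list(ce = ce, sce = sce,
       kS = length(maskedSmilesIdx(plan)), kG = length(maskedGraphIdx(plan)))
}

#' One pre-training step
#'
#' Draws fresh mask plans for the batch (seeds derived from the master seed
#' and the step counter), runs the joint forward pass, computes the two
#' reconstruction losses pooled over all masked positions in the batch,
#' backpropagates, and applies one AdamW update.
#'
#' @param batch list of prepared molecules (elements of
#'   `prepareCorpus()$mols`).
#' @param model a `tandemolModel` (updated in place).
#' @param config a [pretrainConfig()] object.
#' @param vocab the corpus [Vocabulary-class].
#' @param opt internal optimizer state (created by the caller loop).
#' @return a `LossReport` with an extra `plans` attribute (the step's mask
#'   plans, for auditing).
#' @export
pretrainStep <- function(batch, model, config, vocab, opt) {
  cfg <- model$config
  model$step <- model$step + 1L
  tp <- tape_new(4096L)
  P <- param_binder(tp, model$params)
  plans <- vector("list", length(batch))
  ce_acc <- NULL; sce_acc <- NULL
  tot_kS <- 0L; tot_kG <- 0L
  for (i in seq_along(batch)) {
    mol <- batch[[i]]
    plan <- sampleMasks(mol$align, config$rG, config$rS, config$overlap,
                        seed = .mask_seed(config$seed, model$step, i))
    plans[[i]] <- plan
    out <- .fwd_pretrain_mol(tp, P, mol, plan, vocab, cfg, config$gamma)
    ce_w <- tp_mul_const(tp, out$ce, out$kS)
    sce_w <- tp_mul_const(tp, out$sce, out$kG)
    ce_acc <- if (is.null(ce_acc)) ce_w else tp_add(tp, ce_acc, ce_w)
    sce_acc <- if (is.null(sce_acc)) sce_w else tp_add(tp, sce_acc, sce_w)
    tot_kS <- tot_kS + out$kS; tot_kG <- tot_kG + out$kG
  }
  l_en <- tp_mul_const(tp, ce_acc, 1 / max(tot_kS, 1L))
  l_sce <- tp_mul_const(tp, sce_acc, 1 / max(tot_kG, 1L))
  total <- tp_add(tp, l_en, l_sce)
  grads <- tp_backward(tp, total)
  model$params <- adamw_step(opt, model$params, param_grads(P, grads))
  rep <- totalLoss(as.vector(tp_val(tp, l_en)), as.vector(tp_val(tp, l_sce)),
                   tot_kS, tot_kG)
  attr(rep, "plans") <- plans
  rep
}

#' Run pre-training
#'
#' Loads and validates the corpus, builds the vocabulary, initializes (or
#' resumes) the model, and runs the masked-reconstruction training loop with
#' periodic JSON-lines logging and checkpointing. Runs with the same config
#' and seed produce identical loss curves; resuming from a checkpoint
#' reproduces the uninterrupted run exactly.
#'
#' @param config a [pretrainConfig()] object.
#' @param resumeFrom optional checkpoint path to resume from.
#' @return the final checkpoint path (invisibly, with the model as attribute
#'   `model` and the loss history as attribute `history`).
#' @export
runPretraining <- function(config, resumeFrom = NULL) {
  stopifnot(inherits(config, "PretrainConfig"))
  smiles <- if (is.character(config$corpus) && length(config$corpus) == 1L &&
                file.exists(config$corpus)) readSmilesFile(config$corpus)
            else config$corpus
  if (!is.null(resumeFrom)) {
    ck <- readRDS(resumeFrom)
    vocab <- new("Vocabulary", ids = ck$vocab)
    prep <- prepareCorpus(smiles, vocab)
    model <- new.env(parent = emptyenv())
    model$params <- ck$params
    model$config <- ck$modelConfig
    model$step <- ck$step
    class(model) <- "tandemolModel"
    opt <- adamw_restore(ck$opt)
  } else {
    prep <- prepareCorpus(smiles)
    vocab <- prep$vocab
    mcfg <- if (is.null(config$model))
      modelConfig(vocabSize = vocabSize(vocab))
    else { config$model$vocabSize <- vocabSize(vocab); config$model }
    model <- initModel(mcfg, seed = config$seed)
    opt <- adamw_new(lr = config$lr, weightDecay = config$weightDecay)
  }
  if (nrow(prep$rejected))
    message("excluded ", nrow(prep$rejected), " unusable molecule(s) at corpus load")
  nmol <- length(prep$mols)
  dir.create(config$checkpointDir, showWarnings = FALSE, recursive = TRUE)
  history <- list()
  ckpath <- NULL
  while (model$step < config$iterations) {
    idx <- .with_seed(.mask_seed(config$seed, model$step + 1L, 0L),
                      sample.int(nmol, config$batchSize, replace = config$batchSize > nmol))
    rep <- pretrainStep(prep$mols[idx], model, config, vocab, opt)
    if (model$step %% config$logEvery == 0L || model$step == config$iterations) {
      aud <- auditMasks(attr(rep, "plans"))
      entry <- list(iteration = model$step, l_en = rep$l_en, l_sce = rep$l_sce,
                    l_total = rep$l_total,
                    realized_graph_ratio = aud$mean_graph_ratio,
                    realized_smiles_ratio = aud$mean_smiles_ratio,
                    realized_overlap = aud$realized_overlap)
      history[[length(history) + 1L]] <- entry
      if (!is.null(config$logFile))
        cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
            file = config$logFile, append = TRUE, sep = "")
    }
    if (model$step %% config$checkpointEvery == 0L ||
        model$step == config$iterations)
      ckpath <- saveCheckpoint(model, opt, vocab, config)
  }
  structure(invisible(ckpath), model = model, history = history)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized archive holding the weights, the
#' optimizer state, the step counter, the model configuration and the
#' vocabulary.
#'
#' @param model a `tandemolModel`.
#' @param opt optimizer state.
#' @param vocab the corpus [Vocabulary-class].
#' @param config the [pretrainConfig()] used.
#' @return `saveCheckpoint` returns the checkpoint path; `loadCheckpoint`
#'   returns a list with `model`, `opt`, `vocab`.
#' @export
saveCheckpoint <- function(model, opt, vocab, config) {
  path <- file.path(config$checkpointDir,
                    sprintf("checkpoint_%06d.rds", model$step))
  saveRDS(list(version = 1L, step = model$step, params = model$params,
               opt = adamw_state(opt), modelConfig = model$config,
               vocab = tokenToId(vocab)), path)
  path
}

#' @rdname saveCheckpoint
#' @param path checkpoint path.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$params <- ck$params
  model$config <- ck$modelConfig
  model$step <- ck$step
  class(model) <- "tandemolModel"
  list(model = model, opt = adamw_restore(ck$opt),
       vocab = new("Vocabulary", ids = ck$vocab))
}

#' Extract the pre-trained graph encoder
#'
#' Returns the graph-encoder weights alone (the backbone is discarded:
#' downstream property prediction fine-tunes the graph encoder only).
#'
#' @param x a checkpoint path or a `tandemolModel`.
#' @return a `graphEncoder` list with `params` (the `g.*` tensors) and
#'   `config`.
#' @export
exportGraphEncoder <- function(x) {
  model <- if (inherits(x, "tandemolModel")) x else loadCheckpoint(x)$model
  keep <- grep("^g\\.", names(model$params), value = TRUE)
  structure(list(params = model$params[keep], config = model$config),
            class = "graphEncoder")
}
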