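# Downstream protocol: scaffold/random splitting, property heads on the
# pre-trained graph encoder, training with early stopping, and metrics.

#' Scaffold split
#'
#' Partitions a labeled dataset into train/validation/test by Bemis-Murcko
#' scaffold groups: groups are sorted by size (largest first, ties by
#' scaffold key) and greedily assigned to the split whose remaining relative
#' deficit is largest (ties resolved train, then validation, then test).
#' Whole groups are never split, so no scaffold appears in two splits.
#'
#' @param records data.frame with a `smiles` column.
#' @param fractions train/valid/test fractions (default 8:1:1).
#' @param seed retained for interface compatibility; assignment is
#'   deterministic and the seed only influences nothing beyond recorded
#'   metadata.
#' @return a `SplitAssignment` list with `train`, `valid`, `test` index
#'   vectors, the `scaffolds` map, `fractions` and `seed`.
#' @export
scaffoldSplit <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records),
            length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to split", call. = FALSE)
  keys <- vapply(records$smiles, scaffoldKey, "")
  groups <- split(seq_len(n), keys)
  sizes <- vapply(groups, length, 1L)
  ord <- order(-sizes, names(groups), method = "radix")
  groups <- groups[ord]
  target <- fractions * n
  if (length(groups[[1]]) > target[1])
    warning("largest scaffold group (", length(groups[[1]]),
            " molecules) exceeds the train target; assigned to train",
            call. = FALSE)
  counts <- c(0, 0, 0)
  assign <- vector("list", 3L)
  for (grp in groups) {
    deficit <- (target - counts) / pmax(target, 1e-9)
    k <- which.max(deficit)  # ties: train, valid, test (in order)
    assign[[k]] <- c(assign[[k]], grp)
    counts[k] <- counts[k] + length(grp)
  }
  structure(list(train = sort(assign[[1]]), valid = sort(assign[[2]]),
                 test = sort(assign[[3]]), scaffolds = groups,
                 fractions = fractions, seed = as.integer(seed)),
            class = "SplitAssignment")
}

#' Random split
#'
#' Uniform shuffle partition into train/valid/test; deterministic per seed.
#'
#' @inheritParams scaffoldSplit
#' @return a `SplitAssignment` list.
#' @export
randomSplit <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.data.frame(records), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(records)
  perm <- .with_seed(as.integer(seed), sample.int(n))
  n_va <- round(fractions[2] * n)
  n_te <- round(fractions[3] * n)
  n_tr <- n - n_va - n_te
  structure(list(train = sort(perm[seq_len(n_tr)]),
                 valid = sort(perm[n_tr + seq_len(n_va)]),
                 test = sort(perm[n_tr + n_va + seq_len(n_te)]),
                 scaffolds = NULL, fractions = fractions,
                 seed = as.integer(seed)),
            class = "SplitAssignment")
}

#' Evaluate predictions
#'
#' Classification: ROC-AUC in percent, averaged over tasks that have at
#' least one positive and one negative label (tasks with a single class are
#' excluded with a warning; if all are excluded, an error). Regression: RMSE
#' (default) or MAE. Missing labels are excluded pairwise.
#'
#' @param predictions numeric vector or matrix [n x tasks] of scores.
#' @param labels numeric vector or matrix of the same shape; classification
#'   labels in `{0, 1}` or NA.
#' @param taskKind `"classification"` or `"regression"`.
#' @param metric `"rmse"` or `"mae"` for regression.
#' @return scalar metric.
#' @export
evaluatePredictions <- function(predictions, labels,
                                taskKind = c("classification", "regression"),
                                metric = c("rmse", "mae")) {
  taskKind <- match.arg(taskKind)
  metric <- match.arg(metric)
  P <- as.matrix(predictions); Y <- as.matrix(labels)
  stopifnot(identical(dim(P), dim(Y)), nrow(P) > 0)
  if (taskKind == "classification") {
    aucs <- numeric(0)
    for (k in seq_len(ncol(Y))) {
      obs <- !is.na(Y[, k])
      y <- Y[obs, k]; s <- P[obs, k]
      if (!any(y == 1) || !any(y == 0)) {
        warning("task ", k, " has a single class; excluded", call. = FALSE)
        next
      }
      r <- pROC::roc(response = y, predictor = s, direction = "<",
                     levels = c(0, 1), quiet = TRUE)
      aucs <- c(aucs, as.numeric(pROC::auc(r)))
    }
    if (!length(aucs)) stop("no evaluable task", call. = FALSE)
    return(100 * mean(aucs))
  }
  obs <- !is.na(Y)
  r <- P[obs] - Y[obs]
  if (metric == "rmse") sqrt(mean(r^2)) else mean(abs(r))
}

#' Fine-tuning configuration
#'
#' @param taskKind `"classification"` or `"regression"`.
#' @param maxEpochs maximum training epochs (default 150).
#' @param patience early-stopping patience in epochs (default 20).
#' @param lr AdamW base learning rate (default 1e-3).
#' @param warmupEpochs epochs of linear learning-rate warmup.
#' @param seeds integer vector; the protocol reports mean and sd over seeds.
#' @param batchSize molecules per optimizer step.
#' @param headWidth hidden width of the 2-layer prediction head (default:
#'   the encoder width d).
#' @param weightDecay AdamW weight decay.
#' @return a `FinetuneConfig` list.
#' @export
finetuneConfig <- function(taskKind = c("classification", "regression"),
                           maxEpochs = 150L, patience = 20L, lr = 1e-3,
                           warmupEpochs = 0L, seeds = c(1L, 2L, 3L),
                           batchSize = 16L, headWidth = NULL,
                           weightDecay = 0.01) {
  taskKind <- match.arg(taskKind)
  stopifnot(patience < maxEpochs, length(seeds) >= 1L, lr > 0)
  structure(list(taskKind = taskKind, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), lr = lr,
                 warmupEpochs = as.integer(warmupEpochs),
                 seeds = as.integer(seeds), batchSize = as.integer(batchSize),
                 headWidth = headWidth, weightDecay = weightDecay),
            class = "FinetuneConfig")
}

# graph-only forward on a tape: encoder -> mean pooling -> 2-layer head
.fwd_property <- function(tp, P, mol, cfg, n_tasks) {
  g <- mol$g
  h <- .fwd_graph_encoder(tp, P, nodeFeatures(g), rep(FALSE, nAtoms(g)),
                          edgeList(g), edgeFeatures(g), cfg)
  pooled <- tp_mean_rows(tp, h)
  z <- tp_gelu(tp, tp_add_rowvec(tp, tp_matmul(tp, pooled, P("head.W1")),
                                 P("head.b1")))
  tp_add_rowvec(tp, tp_matmul(tp, z, P("head.W2")), P("head.b2"))
}

.predict_property <- function(params, cfg, mols, n_tasks) {
  out <- matrix(NA_real_, length(mols), n_tasks)
  for (i in seq_along(mols)) {
    tp <- tape_new()
    P <- param_binder(tp, params)
    out[i, ] <- tp_val(tp, .fwd_property(tp, P, mols[[i]], cfg, n_tasks))
  }
  out
}

#' Fine-tune the pre-trained graph encoder on a property dataset
#'
#' Downstream protocol: the graph encoder alone is the representation
#' network (the fusion backbone is discarded); the molecule embedding is the
#' mean over node embeddings; a 2-layer feed-forward head predicts the
#' task(s). Classification uses binary cross-entropy with missing labels
#' skipped, regression uses squared error on train-standardized targets
#' (predictions are de-standardized for metrics). Training stops early when
#' the validation metric has not improved for `patience` epochs, and the
#' test metric of the best-validation weights is reported per seed.
#'
#' @param encoder a `graphEncoder` from [exportGraphEncoder()], a checkpoint
#'   path, or a `tandemolModel`.
#' @param records labeled data.frame (column `smiles` + one column per task).
#' @param split a `SplitAssignment`.
#' @param config a [finetuneConfig()].
#' @return list with `perSeed` (named test-metric vector), `mean`, `sd`, and
#'   `metricName`.
#' @export
finetuneEncoder <- function(encoder, records, split, config) {
  stopifnot(inherits(config, "FinetuneConfig"),
            inherits(split, "SplitAssignment"))
  if (!inherits(encoder, "graphEncoder")) encoder <- exportGraphEncoder(encoder)
  cfg <- encoder$config
  label_cols <- setdiff(names(records), "smiles")
  if (!length(label_cols)) stop("no label columns", call. = FALSE)
  Y <- as.matrix(records[label_cols])
  n_tasks <- ncol(Y)
  mols <- lapply(records$smiles, function(s) list(g = featurizeGraph(s)))

  y_mu <- 0; y_sd <- 1
  if (config$taskKind == "regression") {
    tr <- Y[split$train, , drop = FALSE]
    y_mu <- colMeans(tr, na.rm = TRUE)
    y_sd <- apply(tr, 2L, stats::sd, na.rm = TRUE)
    y_sd[!is.finite(y_sd) | y_sd == 0] <- 1
  }
  Yn <- if (config$taskKind == "regression")
    sweep(sweep(Y, 2L, y_mu), 2L, y_sd, "/") else Y

  val_metric <- function(params, idx) {
    pred <- .predict_property(params, cfg, mols[idx], n_tasks)
    if (config$taskKind == "regression")
      pred <- sweep(sweep(pred, 2L, y_sd, "*"), 2L, y_mu)
    tryCatch(evaluatePredictions(pred, Y[idx, , drop = FALSE], config$taskKind),
             error = function(e) NA_real_)
  }
  better <- function(a, b) {
    if (is.na(a)) return(FALSE)
    if (is.na(b)) return(TRUE)
    if (config$taskKind == "classification") a > b else a < b
  }

  head_width <- if (is.null(config$headWidth)) cfg$d else config$headWidth
  per_seed <- numeric(length(config$seeds))
  names(per_seed) <- paste0("seed", config$seeds)

  for (si in seq_along(config$seeds)) {
    seed <- config$seeds[si]
    params <- encoder$params
    .with_seed(seed, {
      params[["head.W1"]] <- .xavier(cfg$d, head_width)
      params[["head.b1"]] <- .zeros_row(head_width)
      params[["head.W2"]] <- .xavier(head_width, n_tasks)
      params[["head.b2"]] <- .zeros_row(n_tasks)
    })
    opt <- adamw_new(lr = config$lr, weightDecay = config$weightDecay)
    best <- NA_real_; best_params <- params; since_best <- 0L
    for (epoch in seq_len(config$maxEpochs)) {
      lr_scale <- if (config$warmupEpochs > 0L && epoch <= config$warmupEpochs)
        epoch / config$warmupEpochs else 1
      opt$lr <- config$lr * lr_scale
      order_idx <- .with_seed(seed * 1009L + epoch, sample(split$train))
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batchSize))
      for (b in batches) {
        tp <- tape_new(4096L)
        P <- param_binder(tp, params)
        acc <- NULL; tot_obs <- 0L
        for (i in b) {
          yrow <- matrix(Yn[i, ], 1L)
          n_obs <- sum(!is.na(yrow))
          if (!n_obs) next
          z <- .fwd_property(tp, P, mols[[i]], cfg, n_tasks)
          li <- if (config$taskKind == "classification")
            tp_bce_masked(tp, z, yrow) else tp_mse_masked(tp, z, yrow)
          lw <- tp_mul_const(tp, li, n_obs)
          acc <- if (is.null(acc)) lw else tp_add(tp, acc, lw)
          tot_obs <- tot_obs + n_obs
        }
        if (is.null(acc)) next
        loss <- tp_mul_const(tp, acc, 1 / tot_obs)
        grads <- tp_backward(tp, loss)
        params <- adamw_step(opt, params, param_grads(P, grads))
      }
      vm <- val_metric(params, split$valid)
      if (better(vm, best)) {
        best <- vm; best_params <- params; since_best <- 0L
      } else since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
    per_seed[si] <- val_metric(best_params, split$test)
  }
  list(perSeed = per_seed, mean = mean(per_seed), sd = stats::sd(per_seed),
       metricName = if (config$taskKind == "classification") "ROC-AUC (%)"
                    else "RMSE")
}
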