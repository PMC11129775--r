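# AdamW optimizer (decoupled weight decay). Internal.

adamw_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weightDecay = 0.01) {
  env <- new.env(parent = emptyenv())
  env$lr <- lr; env$beta1 <- beta1; env$beta2 <- beta2
  env$eps <- eps; env$wd <- weightDecay
  env$m <- list(); env$v <- list(); env$t <- 0L
  env
}

# no decay on biases, norms, embeddings-with-1-row is fine to decay skip:
# decay applies to 2-d weight matrices only (both dims > 1)
.decay_applies <- function(name, val) {
  nrow(val) > 1L && ncol(val) > 1L && !grepl("(\\.b|\\.ln|emb)", name)
}

adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + opt$eps)
    p <- params[[nm]]
    if (opt$wd > 0 && .decay_applies(nm, p)) upd <- upd + opt$wd * p
    params[[nm]] <- p - opt$lr * upd
  }
  params
}

adamw_state <- function(opt) {
  list(lr = opt$lr, beta1 = opt$beta1, beta2 = opt$beta2, eps = opt$eps,
       wd = opt$wd, m = opt$m, v = opt$v, t = opt$t)
}

adamw_restore <- function(state) {
  opt <- adamw_new(state$lr, state$beta1, state$beta2, state$eps, state$wd)
  opt$m <- state$m; opt$v <- state$v; opt$t <- state$t
  opt
}
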