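# Finite-difference gradient checking utilities.
#
# `check_grads()` builds a forward pass on a fresh tape via `build(tp, ids)`
# (which must return the output node id), multiplies the output elementwise
# with a fixed random weight matrix so the effective scalar loss is
# sum(output * W), runs the analytic backward pass, and compares every
# input's gradient against central finite differences.

fd_grad <- function(eval_fn, inputs, k, eps = 1e-6) {
  x <- inputs[[k]]
  g <- x * 0
  for (j in seq_along(x)) {
    ip <- inputs; ip[[k]][j] <- x[j] + eps
    im <- inputs; im[[k]][j] <- x[j] - eps
    g[j] <- (eval_fn(ip) - eval_fn(im)) / (2 * eps)
  }
  g
}

check_grads <- function(build, inputs, tol = 1e-4, wseed = 42) {
  probe <- local({
    tp <- tandemol:::tape_new()
    ids <- lapply(inputs, function(m) tandemol:::tp_leaf(tp, m))
    tandemol:::tp_val(tp, build(tp, ids))
  })
  W <- tandemol:::.with_seed(wseed,
    matrix(stats::rnorm(length(probe)), nrow(probe)))
  eval_fn <- function(ins) {
    tp <- tandemol:::tape_new()
    ids <- lapply(ins, function(m) tandemol:::tp_leaf(tp, m))
    sum(tandemol:::tp_val(tp, build(tp, ids)) * W)
  }
  tp <- tandemol:::tape_new()
  ids <- lapply(inputs, function(m) tandemol:::tp_leaf(tp, m))
  out <- build(tp, ids)
  loss <- tandemol:::tp_mul(tp, out, tandemol:::tp_leaf(tp, W))
  grads <- tandemol:::tp_backward(tp, loss)
  for (k in seq_along(inputs)) {
    ana <- grads[[ids[[k]]]]
    if (is.null(ana)) ana <- inputs[[k]] * 0
    num <- fd_grad(eval_fn, inputs, k)
    scale <- max(1, max(abs(num)))
    expect_lt(max(abs(ana - num)) / scale, tol)
  }
  invisible(NULL)
}

rand_mat <- function(n, m, seed) {
  tandemol:::.with_seed(seed, matrix(stats::rnorm(n * m), n, m))
}
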