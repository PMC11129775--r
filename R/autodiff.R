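# Reverse-mode automatic differentiation over base-R matrices.
#
# A tape records every operation of a forward pass; tp_backward() replays it
# in reverse, accumulating gradients. Nodes are integer ids into the tape;
# values are plain numeric matrices. Each operation pushes a closure that
# maps the incoming gradient to gradients for its parents. All gradients are
# verified against central finite differences in the test suite.
#
# Internal: not exported. The public encode*/decode*/loss functions wrap
# forward passes on a fresh tape and return plain matrices.

tape_new <- function(capacity = 1024L) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", capacity)
  tp$parents <- vector("list", capacity)
  tp$backfns <- vector("list", capacity)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, parents = integer(0), backfn = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    grow <- length(tp$vals)
    tp$vals <- c(tp$vals, vector("list", grow))
    tp$parents <- c(tp$parents, vector("list", grow))
    tp$backfns <- c(tp$backfns, vector("list", grow))
  }
  tp$vals[[n]] <- val
  tp$parents[[n]] <- parents
  tp$backfns[[n]] <- backfn
  tp$n <- n
  n
}

# Read a node value. `id` is forced BEFORE tp$vals is touched: callers pass
# side-effecting expressions (nested op calls) as ids, and the environment's
# vals list must be re-read after those pushes happen.
tp_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

tp_leaf <- function(tp, val) tp_push(tp, val)

tp_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  lv <- tp_val(tp, loss_id)
  grads[[loss_id]] <- array(1, dim = dim(as.matrix(lv)))
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    bf <- tp$backfns[[i]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tp$parents[[i]]
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

# ---- elementary ops ------------------------------------------------------

tp_matmul <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A %*% B, c(a, b),
          function(g) list(g %*% t(B), t(A) %*% g))
}

# A %*% t(B)
tp_matmul_bt <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A %*% t(B), c(a, b),
          function(g) list(g %*% B, t(g) %*% A))
}

tp_add <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  stopifnot(identical(dim(A), dim(B)))
  tp_push(tp, A + B, c(a, b), function(g) list(g, g))
}

# add a 1 x d row-vector node to every row of A
tp_add_rowvec <- function(tp, a, v) {
  A <- tp_val(tp, a); V <- tp_val(tp, v)
  tp_push(tp, sweep(A, 2L, as.vector(V), "+"), c(a, v),
          function(g) list(g, matrix(colSums(g), 1L)))
}

tp_mul <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_mul_const <- function(tp, a, C) {
  A <- tp_val(tp, a)
  tp_push(tp, A * C, a, function(g) list(g * C))
}

tp_add_const <- function(tp, a, C) {
  A <- tp_val(tp, a)
  tp_push(tp, A + C, a, function(g) list(g))
}

tp_relu <- function(tp, a) {
  A <- tp_val(tp, a)
  tp_push(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

tp_gelu <- function(tp, a) {
  A <- tp_val(tp, a)
  c1 <- sqrt(2 / pi); c2 <- 0.044715
  u <- c1 * (A + c2 * A^3)
  t <- tanh(u)
  y <- 0.5 * A * (1 + t)
  tp_push(tp, y, a, function(g) {
    dy <- 0.5 * (1 + t) + 0.5 * A * (1 - t^2) * c1 * (1 + 3 * c2 * A^2)
    list(g * dy)
  })
}

# row-wise softmax; maskAdd is an optional constant additive matrix
tp_softmax_rows <- function(tp, a, maskAdd = NULL) {
  A <- tp_val(tp, a)
  if (!is.null(maskAdd)) A <- A + maskAdd
  mx <- apply(A, 1L, max)
  E <- exp(A - mx)
  Y <- E / rowSums(E)
  tp_push(tp, Y, a, function(g) {
    list(Y * (g - rowSums(g * Y)))
  })
}

# row-wise layer normalization with learnable 1 x d gain/bias nodes
tp_layernorm_rows <- function(tp, a, gamma, beta, eps = 1e-5) {
  A <- tp_val(tp, a)
  G <- as.vector(tp_val(tp, gamma)); B <- as.vector(tp_val(tp, beta))
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2L, G, "*"), 2L, B, "+")
  tp_push(tp, Y, c(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, G, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# gather rows (with repeats allowed); backward scatter-adds
tp_rows <- function(tp, a, idx) {
  A <- tp_val(tp, a)
  tp_push(tp, A[idx, , drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    list(out)
  })
}

tp_cols <- function(tp, a, idx) {
  A <- tp_val(tp, a)
  tp_push(tp, A[, idx, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[, idx] <- g
    list(out)
  })
}

tp_concat_rows <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  na <- nrow(A)
  tp_push(tp, rbind(A, B), c(a, b), function(g)
    list(g[seq_len(na), , drop = FALSE],
         g[-seq_len(na), , drop = FALSE]))
}

tp_concat_cols <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  na <- ncol(A)
  tp_push(tp, cbind(A, B), c(a, b), function(g)
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE]))
}

# sum rows of A into ngroups bins given by `groups` (empty bins allowed)
tp_rowsum_groups <- function(tp, a, groups, ngroups) {
  A <- tp_val(tp, a)
  out <- matrix(0, ngroups, ncol(A))
  if (nrow(A)) {
    agg <- rowsum(A, group = groups)
    out[as.integer(rownames(agg)), ] <- agg
  }
  tp_push(tp, out, a, function(g) list(g[groups, , drop = FALSE]))
}

# softmax over a column vector within groups
tp_group_softmax <- function(tp, s, groups) {
  S <- as.vector(tp_val(tp, s))
  y <- numeric(length(S))
  for (grp in split(seq_along(S), groups)) {
    e <- exp(S[grp] - max(S[grp]))
    y[grp] <- e / sum(e)
  }
  Y <- matrix(y, ncol = 1L)
  tp_push(tp, Y, s, function(g) {
    gv <- as.vector(g)
    dv <- numeric(length(gv))
    for (grp in split(seq_along(gv), groups)) {
      dot <- sum(gv[grp] * y[grp])
      dv[grp] <- y[grp] * (gv[grp] - dot)
    }
    list(matrix(dv, ncol = 1L))
  })
}

# scale each row of A by the scalar in the same row of w (n x 1 node)
tp_scale_rows <- function(tp, a, w) {
  A <- tp_val(tp, a); W <- as.vector(tp_val(tp, w))
  tp_push(tp, A * W, c(a, w), function(g)
    list(g * W, matrix(rowSums(g * A), ncol = 1L)))
}

# scale a matrix node by a 1 x 1 scalar node
tp_scale_scalar <- function(tp, a, s) {
  A <- tp_val(tp, a); S <- as.vector(tp_val(tp, s))
  tp_push(tp, A * S, c(a, s), function(g)
    list(g * S, matrix(sum(g * A), 1L, 1L)))
}

# row-wise dot product of two equally-shaped nodes -> n x 1
tp_rowdot <- function(tp, a, b) {
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, matrix(rowSums(A * B), ncol = 1L), c(a, b), function(g) {
    gv <- as.vector(g)
    list(A * 0 + gv * B, B * 0 + gv * A)
  })
}

tp_mean_rows <- function(tp, a) {
  A <- tp_val(tp, a)
  n <- nrow(A)
  tp_push(tp, matrix(colMeans(A), 1L), a, function(g)
    list(matrix(rep(as.vector(g) / n, each = n), nrow = n)))
}

# outer product of a constant column vector with a 1 x d parameter node
tp_outer_const <- function(tp, v, p) {
  P <- tp_val(tp, p)
  tp_push(tp, outer(v, as.vector(P)), p, function(g)
    list(matrix(as.vector(t(g) %*% v), 1L)))
}

# ---- losses --------------------------------------------------------------

# mean cross-entropy over the given rows of a logits node
tp_ce_masked <- function(tp, logits, targets, rows) {
  L <- tp_val(tp, logits)
  if (!length(rows)) return(tp_push(tp, matrix(0, 1, 1), logits,
                                    function(g) list(matrix(0, nrow(L), ncol(L)))))
  sub <- L[rows, , drop = FALSE]
  mx <- apply(sub, 1L, max)
  E <- exp(sub - mx)
  P <- E / rowSums(E)
  tgt <- targets[rows]
  nll <- -log(pmax(P[cbind(seq_along(rows), tgt)], 1e-300))
  val <- matrix(mean(nll), 1, 1)
  tp_push(tp, val, logits, function(g) {
    gl <- matrix(0, nrow(L), ncol(L))
    D <- P
    D[cbind(seq_along(rows), tgt)] <- D[cbind(seq_along(rows), tgt)] - 1
    gl[rows, ] <- as.vector(g) * D / length(rows)
    list(gl)
  })
}

# mean scaled cosine error over the given rows: (1 - cos(xhat, x))^gamma
tp_sce_masked <- function(tp, xhat, X, rows, gamma = 2, eps = 1e-8) {
  H <- tp_val(tp, xhat)
  if (!length(rows)) return(tp_push(tp, matrix(0, 1, 1), xhat,
                                    function(g) list(matrix(0, nrow(H), ncol(H)))))
  A <- H[rows, , drop = FALSE]
  B <- X[rows, , drop = FALSE]
  na <- pmax(sqrt(rowSums(A^2)), eps)
  nb <- pmax(sqrt(rowSums(B^2)), eps)
  cs <- rowSums(A * B) / (na * nb)
  val <- matrix(mean((1 - cs)^gamma), 1, 1)
  tp_push(tp, val, xhat, function(g) {
    # d cos / dA = B/(|A||B|) - cos * A/|A|^2, rows only
    dcs <- B / (na * nb) - (cs / na^2) * A
    w <- -gamma * (1 - cs)^(gamma - 1) / length(rows)
    gH <- matrix(0, nrow(H), ncol(H))
    gH[rows, ] <- as.vector(g) * w * dcs
    list(gH)
  })
}

# masked binary cross-entropy with logits; Y may contain NA (missing labels)
tp_bce_masked <- function(tp, logits, Y) {
  Z <- tp_val(tp, logits)
  obs <- which(!is.na(Y))
  n <- length(obs)
  if (!n) stop("no observed labels in batch", call. = FALSE)
  z <- Z[obs]; y <- Y[obs]
  # stable softplus(z) - y z
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  val <- matrix(mean(sp - y * z), 1, 1)
  tp_push(tp, val, logits, function(g) {
    gz <- matrix(0, nrow(Z), ncol(Z))
    gz[obs] <- as.vector(g) * (1 / (1 + exp(-z)) - y) / n
    list(gz)
  })
}

# mean squared error against constant Y (NA entries excluded)
tp_mse_masked <- function(tp, pred, Y) {
  P <- tp_val(tp, pred)
  obs <- which(!is.na(Y))
  n <- length(obs)
  if (!n) stop("no observed labels in batch", call. = FALSE)
  r <- P[obs] - Y[obs]
  val <- matrix(mean(r^2), 1, 1)
  tp_push(tp, val, pred, function(g) {
    gp <- matrix(0, nrow(P), ncol(P))
    gp[obs] <- as.vector(g) * 2 * r / n
    list(gp)
  })
}
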