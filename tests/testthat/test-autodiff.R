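# Gradient correctness of every tape operation, verified against central
# finite differences.

test_that("linear algebra ops have correct gradients", {
  A <- rand_mat(3, 4, 1); B <- rand_mat(4, 2, 2); C <- rand_mat(3, 4, 3)
  D <- rand_mat(2, 4, 4); v <- rand_mat(1, 4, 5)
  check_grads(function(tp, id) tandemol:::tp_matmul(tp, id[[1]], id[[2]]),
              list(A, B))
  check_grads(function(tp, id) tandemol:::tp_matmul_bt(tp, id[[1]], id[[2]]),
              list(A, D))
  check_grads(function(tp, id) tandemol:::tp_add(tp, id[[1]], id[[2]]),
              list(A, C))
  check_grads(function(tp, id) tandemol:::tp_add_rowvec(tp, id[[1]], id[[2]]),
              list(A, v))
  check_grads(function(tp, id) tandemol:::tp_mul(tp, id[[1]], id[[2]]),
              list(A, C))
  check_grads(function(tp, id) tandemol:::tp_mul_const(tp, id[[1]], 2.5),
              list(A))
  check_grads(function(tp, id) tandemol:::tp_add_const(tp, id[[1]], -1.3),
              list(A))
})

test_that("activations have correct gradients", {
  A <- rand_mat(3, 4, 6)
  A[abs(A) < 0.05] <- 0.2  # keep relu inputs away from the kink
  check_grads(function(tp, id) tandemol:::tp_relu(tp, id[[1]]), list(A))
  check_grads(function(tp, id) tandemol:::tp_gelu(tp, id[[1]]), list(A))
})

test_that("softmax and layer norm have correct gradients", {
  A <- rand_mat(3, 5, 7)
  maskAdd <- matrix(0, 3, 5); maskAdd[, 5] <- -1e9
  g <- rand_mat(1, 5, 8); b <- rand_mat(1, 5, 9)
  check_grads(function(tp, id) tandemol:::tp_softmax_rows(tp, id[[1]]),
              list(A))
  check_grads(function(tp, id)
    tandemol:::tp_softmax_rows(tp, id[[1]], maskAdd), list(A))
  check_grads(function(tp, id)
    tandemol:::tp_layernorm_rows(tp, id[[1]], id[[2]], id[[3]]),
    list(A, g, b), tol = 5e-4)
})

test_that("gather, scatter and concatenation ops have correct gradients", {
  A <- rand_mat(4, 3, 10); B <- rand_mat(2, 3, 11)
  check_grads(function(tp, id) tandemol:::tp_rows(tp, id[[1]], c(2L, 2L, 4L)),
              list(A))
  check_grads(function(tp, id) tandemol:::tp_cols(tp, id[[1]], c(1L, 3L)),
              list(A))
  check_grads(function(tp, id) tandemol:::tp_concat_rows(tp, id[[1]], id[[2]]),
              list(A, B))
  check_grads(function(tp, id) tandemol:::tp_concat_cols(tp, id[[1]], id[[2]]),
              list(A, rand_mat(4, 2, 12)))
})

test_that("grouped aggregation ops have correct gradients", {
  A <- rand_mat(5, 3, 13)
  groups <- c(1L, 3L, 1L, 3L, 3L)  # group 2 deliberately empty
  check_grads(function(tp, id)
    tandemol:::tp_rowsum_groups(tp, id[[1]], groups, 4L), list(A))
  s <- rand_mat(5, 1, 14)
  check_grads(function(tp, id)
    tandemol:::tp_group_softmax(tp, id[[1]], groups), list(s))
})

test_that("scaling, reduction and outer ops have correct gradients", {
  A <- rand_mat(4, 3, 15); w <- rand_mat(4, 1, 16); s <- rand_mat(1, 1, 17)
  p <- rand_mat(1, 3, 18)
  check_grads(function(tp, id) tandemol:::tp_scale_rows(tp, id[[1]], id[[2]]),
              list(A, w))
  check_grads(function(tp, id) tandemol:::tp_scale_scalar(tp, id[[1]], id[[2]]),
              list(A, s))
  check_grads(function(tp, id) tandemol:::tp_rowdot(tp, id[[1]], id[[2]]),
              list(A, rand_mat(4, 3, 19)))
  check_grads(function(tp, id) tandemol:::tp_mean_rows(tp, id[[1]]), list(A))
  check_grads(function(tp, id)
    tandemol:::tp_outer_const(tp, c(0.5, -1, 2, 0), id[[1]]), list(p))
})

test_that("loss ops have correct gradients", {
  logits <- rand_mat(5, 4, 20)
  targets <- c(1L, 3L, 2L, 4L, 1L)
  check_grads(function(tp, id)
    tandemol:::tp_ce_masked(tp, id[[1]], targets, c(1L, 3L, 5L)),
    list(logits))
  xhat <- rand_mat(5, 6, 21); X <- rand_mat(5, 6, 22)
  check_grads(function(tp, id)
    tandemol:::tp_sce_masked(tp, id[[1]], X, c(2L, 4L), gamma = 2),
    list(xhat), tol = 5e-4)
  check_grads(function(tp, id)
    tandemol:::tp_sce_masked(tp, id[[1]], X, c(1L, 3L, 5L), gamma = 1),
    list(xhat), tol = 5e-4)
  z <- rand_mat(1, 3, 23)
  Y <- matrix(c(1, NA, 0), 1)
  check_grads(function(tp, id) tandemol:::tp_bce_masked(tp, id[[1]], Y),
              list(z))
  check_grads(function(tp, id) tandemol:::tp_mse_masked(tp, id[[1]], Y),
              list(z))
})

test_that("gradients accumulate when a node is used twice", {
  A <- rand_mat(3, 3, 24)
  check_grads(function(tp, id) tandemol:::tp_add(tp, id[[1]], id[[1]]),
              list(A))
  check_grads(function(tp, id) tandemol:::tp_mul(tp, id[[1]], id[[1]]),
              list(A))
})

test_that("empty masked sets yield zero loss and zero gradient", {
  tp <- tandemol:::tape_new()
  logits <- tandemol:::tp_leaf(tp, rand_mat(3, 4, 25))
  l <- tandemol:::tp_ce_masked(tp, logits, c(1L, 2L, 3L), integer(0))
  expect_equal(as.vector(tandemol:::tp_val(tp, l)), 0)
  grads <- tandemol:::tp_backward(tp, l)
  expect_true(all(grads[[logits]] == 0))
})

test_that("AdamW steps descend and decay only multi-dimensional weights", {
  params <- list("x.W" = matrix(2, 3, 3), "x.b" = matrix(2, 1, 3),
                 "x.ln.g" = matrix(2, 1, 3), "emb" = matrix(2, 1, 3))
  opt <- tandemol:::adamw_new(lr = 0.1, weightDecay = 0.5)
  zero_grads <- lapply(params, function(p) p * 0)
  p2 <- tandemol:::adamw_step(opt, params, zero_grads)
  # zero gradient: only decayed tensors move
  expect_lt(max(p2[["x.W"]]), 2)
  expect_equal(p2[["x.b"]], params[["x.b"]])
  expect_equal(p2[["x.ln.g"]], params[["x.ln.g"]])
  expect_equal(p2[["emb"]], params[["emb"]])
  # positive gradient decreases the parameter
  opt2 <- tandemol:::adamw_new(lr = 0.1, weightDecay = 0)
  g <- lapply(params, function(p) p * 0 + 1)
  p3 <- tandemol:::adamw_step(opt2, params, g)
  expect_true(all(p3[["x.W"]] < params[["x.W"]]))
  # state save/restore continues identically
  st <- tandemol:::adamw_state(opt2)
  p4a <- tandemol:::adamw_step(opt2, p3, g)
  p4b <- tandemol:::adamw_step(tandemol:::adamw_restore(st), p3, g)
  expect_equal(p4a, p4b)
})
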