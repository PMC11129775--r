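# Network components: attention, encoders, fusion backbone, decoders.

test_that("self-attention rows are a convex combination of values", {
  set.seed(3)
  Q <- matrix(rnorm(8), 2); K <- matrix(rnorm(16), 4); V <- matrix(rnorm(12), 4)
  out <- selfAttention(Q, K, V)
  W <- attr(out, "weights")
  expect_equal(unname(rowSums(W)), c(1, 1), tolerance = 1e-6)
  expect_true(all(W >= 0))
  expect_equal(dim(out), c(2L, 3L))
})

test_that("single-position attention returns its value row exactly", {
  set.seed(4)
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(4), 1); V <- matrix(c(1, 2, 3), 1)
  out <- selfAttention(Q, K, V)
  expect_equal(unname(out[1, ]), c(1, 2, 3))
})

test_that("key masking excludes padding positions", {
  set.seed(5)
  Q <- matrix(rnorm(8), 2)
  K <- matrix(rnorm(12), 3); V <- matrix(rnorm(6), 3)
  full <- selfAttention(Q, K[1:2, , drop = FALSE], V[1:2, , drop = FALSE])
  masked <- selfAttention(Q, K, V, keyMask = c(TRUE, TRUE, FALSE))
  expect_lt(max(attr(masked, "weights")[, 3]), 1e-12)
  attr(full, "weights") <- NULL
  attr(masked, "weights") <- NULL
  expect_equal(masked, full, tolerance = 1e-9)
})

test_that("encoders and decoders produce the contracted shapes", {
  corpus <- tiny_corpus()
  v <- buildVocabulary(corpus)
  model <- small_model(vocabSize(v))
  s <- corpus[1]
  ts <- tokenizeSmiles(s, v)
  g <- featurizeGraph(s)
  d <- model$config$d
  FS <- encodeSmiles(model, tokenIds(ts))
  expect_equal(dim(FS), c(length(tokens(ts)), d))
  flags <- rep(FALSE, nAtoms(g))
  FG <- encodeGraph(model, nodeFeatures(g), flags, edgeList(g),
                    edgeFeatures(g))
  expect_equal(dim(FG), c(nAtoms(g), d))
  fused <- fuseEmbeddings(model, FS, FG)
  expect_equal(fused@split, nrow(FS))
  expect_equal(nrow(fused@embeddings), nrow(FS) + nrow(FG))
  logits <- decodeSmiles(model, fused@embeddings[seq_len(fused@split), ])
  expect_equal(dim(logits), c(nrow(FS), vocabSize(v)))
  FpG <- fused@embeddings[-seq_len(fused@split), , drop = FALSE]
  recon <- decodeGraph(model, FpG, flags, edgeList(g))
  expect_equal(dim(recon), c(nAtoms(g), nodeFeatureWidth()))
})

test_that("eval-mode forward passes are deterministic", {
  v <- buildVocabulary(tiny_corpus())
  model <- small_model(vocabSize(v))
  ts <- tokenizeSmiles("CC(=O)O", v)
  expect_identical(encodeSmiles(model, tokenIds(ts)),
                   encodeSmiles(model, tokenIds(ts)))
})

test_that("the graph encoder is permutation-equivariant", {
  v <- buildVocabulary(tiny_corpus())
  model <- small_model(vocabSize(v))
  g <- featurizeGraph("CC(=O)OCC")
  X <- nodeFeatures(g); e <- edgeList(g); ef <- edgeFeatures(g)
  n <- nAtoms(g)
  flags <- c(TRUE, rep(FALSE, n - 1L))
  out <- encodeGraph(model, X, flags, e, ef)
  p <- c(3L, 1L, 4L, 2L, 6L, 5L)  # new position i holds old node p[i]
  Xp <- X[p, , drop = FALSE]
  ep <- matrix(match(e, p), ncol = 2L)
  outp <- encodeGraph(model, Xp, flags[p], ep, ef)
  expect_equal(outp, out[p, , drop = FALSE], tolerance = 1e-10)
})

test_that("a zero-depth backbone reduces to modality embeddings", {
  v <- buildVocabulary(tiny_corpus())
  cfg <- modelConfig(d = 8L, nHeads = 2L, nLayersSmiles = 1L,
                     nLayersGraph = 1L, nLayersBackbone = 0L,
                     nLayersGraphDecoder = 1L, maxSeqLen = 32L,
                     vocabSize = vocabSize(v))
  model <- initModel(cfg, seed = 2)
  FS <- matrix(rnorm(3 * 8), 3); FG <- matrix(rnorm(2 * 8), 2)
  fused <- fuseEmbeddings(model, FS, FG)
  A_S <- model$params[["f.A_S"]]; A_G <- model$params[["f.A_G"]]
  expected <- rbind(sweep(FS, 2L, as.vector(A_S), "+"),
                    sweep(FG, 2L, as.vector(A_G), "+"))
  expect_equal(fused@embeddings, expected, tolerance = 1e-12)
})

test_that("with a backbone, information flows across modalities", {
  v <- buildVocabulary(tiny_corpus())
  model <- small_model(vocabSize(v))
  set.seed(8)
  d <- model$config$d
  FS <- matrix(rnorm(3 * d), 3)
  FG1 <- matrix(rnorm(2 * d), 2)
  # perturb a single entry (a constant whole-row shift would be invisible
  # to the blocks' layer norms)
  FG2 <- FG1; FG2[1, 1] <- FG2[1, 1] + 1
  f1 <- fuseEmbeddings(model, FS, FG1)@embeddings
  f2 <- fuseEmbeddings(model, FS, FG2)@embeddings
  # the SMILES rows must change when the graph rows change
  expect_gt(max(abs(f1[1:3, ] - f2[1:3, ])), 1e-8)
})

test_that("the graph decoder re-masks: leaked masked-row input is ignored", {
  v <- buildVocabulary(tiny_corpus())
  model <- small_model(vocabSize(v))
  g <- featurizeGraph("CCOC")
  d <- model$config$d
  set.seed(9)
  FpG <- matrix(rnorm(4 * d), 4)
  flags <- c(FALSE, TRUE, FALSE, FALSE)
  r1 <- decodeGraph(model, FpG, flags, edgeList(g))
  FpG2 <- FpG; FpG2[2, ] <- FpG2[2, ] + 100  # perturb only the masked row
  r2 <- decodeGraph(model, FpG2, flags, edgeList(g))
  expect_equal(r1, r2, tolerance = 1e-12)
  # but perturbing an unmasked row does change the reconstruction
  FpG3 <- FpG; FpG3[1, ] <- FpG3[1, ] + 1
  r3 <- decodeGraph(model, FpG3, flags, edgeList(g))
  expect_gt(max(abs(r1 - r3)), 1e-8)
})

test_that("input validation catches bad sequences", {
  v <- buildVocabulary(tiny_corpus())
  model <- small_model(vocabSize(v))
  expect_error(encodeSmiles(model, c(1L, 9999L)), "vocabulary")
  expect_error(encodeSmiles(model, rep(4L, model$config$maxSeqLen + 1L)))
  expect_error(modelConfig(d = 7L, nHeads = 2L, vocabSize = 10L))
})
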