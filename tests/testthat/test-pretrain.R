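# Pre-training loop: corpus preparation, steps, determinism, resume.

small_pretrain_cfg <- function(corpus, iterations, seed = 3L, dir = tempfile()) {
  pretrainConfig(corpus, iterations = iterations, batchSize = 4L,
                 seed = seed, checkpointDir = dir, logEvery = 1L,
                 checkpointEvery = iterations,
                 model = modelConfig(d = 16L, nHeads = 2L, nLayersSmiles = 1L,
                                     nLayersGraph = 1L, nLayersBackbone = 1L,
                                     nLayersGraphDecoder = 1L, maxSeqLen = 64L,
                                     vocabSize = 4L))
}

test_that("corpus preparation filters unusable molecules with reasons", {
  prep <- prepareCorpus(c("CCO", "C1CC", "c1ccccc1", "xx"))
  expect_length(prep$mols, 2)
  expect_identical(prep$rejected$index, c(2L, 4L))
  expect_true(all(nzchar(prep$rejected$reason)))
  expect_s4_class(prep$vocab, "Vocabulary")
  expect_error(prepareCorpus(character(0)), "empty")
  expect_error(prepareCorpus(c("C1CC", "xx")), "no usable")
})

test_that("per-molecule mask seeds are valid 32-bit seeds", {
  for (ms in c(1L, 999L, 2147483646L))
    for (step in c(1L, 500L, 90000L))
      for (i in c(0L, 1L, 256L)) {
        s <- tandemol:::.mask_seed(ms, step, i)
        expect_gte(s, 0)
        expect_lt(s, 2^31)
      }
})

test_that("a short pre-training run reduces the total loss", {
  cfg <- small_pretrain_cfg(tiny_corpus(), iterations = 30L)
  res <- runPretraining(cfg)
  h <- attr(res, "history")
  first <- h[[1]]$l_total
  last <- mean(vapply(tail(h, 5), function(e) e$l_total, 1))
  expect_lt(last, first)
  expect_true(all(vapply(h, function(e) is.finite(e$l_total), TRUE)))
  # realized mask statistics are logged and overlap stays at zero
  expect_true(all(vapply(h, function(e) e$realized_overlap == 0, TRUE)))
})

test_that("pre-training is deterministic per seed", {
  h1 <- attr(runPretraining(small_pretrain_cfg(tiny_corpus(), 8L)), "history")
  h2 <- attr(runPretraining(small_pretrain_cfg(tiny_corpus(), 8L)), "history")
  expect_equal(h1, h2, tolerance = 1e-12)
  h3 <- attr(runPretraining(small_pretrain_cfg(tiny_corpus(), 8L, seed = 4L)),
             "history")
  expect_false(isTRUE(all.equal(vapply(h1, `[[`, 1, "l_total"),
                                vapply(h3, `[[`, 1, "l_total"))))
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  dirA <- tempfile(); dirB <- tempfile()
  cfgA <- pretrainConfig(tiny_corpus(), iterations = 10L, batchSize = 4L,
                         seed = 3L, checkpointDir = dirA, logEvery = 1L,
                         checkpointEvery = 5L,
                         model = modelConfig(d = 16L, nHeads = 2L,
                                             nLayersSmiles = 1L,
                                             nLayersGraph = 1L,
                                             nLayersBackbone = 1L,
                                             nLayersGraphDecoder = 1L,
                                             maxSeqLen = 64L, vocabSize = 4L))
  resA <- runPretraining(cfgA)
  modelA <- attr(resA, "model")
  cfgB <- cfgA; cfgB$checkpointDir <- dirB
  mid <- file.path(dirA, "checkpoint_000005.rds")
  expect_true(file.exists(mid))
  resB <- runPretraining(cfgB, resumeFrom = mid)
  modelB <- attr(resB, "model")
  expect_equal(modelA$params, modelB$params, tolerance = 1e-12)
  expect_identical(modelA$step, modelB$step)
})

test_that("checkpoints round-trip model, optimizer and vocabulary", {
  cfg <- small_pretrain_cfg(tiny_corpus(), iterations = 3L)
  res <- runPretraining(cfg)
  ck <- loadCheckpoint(as.character(res))
  model <- attr(res, "model")
  expect_equal(ck$model$params, model$params, tolerance = 1e-15)
  expect_identical(ck$model$step, 3L)
  expect_s4_class(ck$vocab, "Vocabulary")
  enc <- exportGraphEncoder(as.character(res))
  expect_true(all(startsWith(names(enc$params), "g.")))
  expect_identical(enc$config$d, 16L)
})

test_that("one pre-training step reports pooled losses and mask plans", {
  prep <- prepareCorpus(tiny_corpus())
  cfg <- small_pretrain_cfg(tiny_corpus(), iterations = 1L)
  mcfg <- cfg$model; mcfg$vocabSize <- vocabSize(prep$vocab)
  model <- initModel(mcfg, seed = 1)
  opt <- tandemol:::adamw_new(lr = cfg$lr, weightDecay = cfg$weightDecay)
  before <- model$params
  rep <- pretrainStep(prep$mols[1:4], model, cfg, prep$vocab, opt)
  expect_s3_class(rep, "LossReport")
  expect_equal(rep$l_total, rep$l_en + rep$l_sce)
  plans <- attr(rep, "plans")
  expect_length(plans, 4)
  aud <- auditMasks(plans)
  expect_identical(aud$realized_overlap, 0)
  # parameters actually moved
  expect_gt(max(abs(model$params[["s.tok_emb"]] - before[["s.tok_emb"]])), 0)
})
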