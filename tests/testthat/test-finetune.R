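# Splitting, metrics and the downstream fine-tuning protocol.

chain_records <- function(n) {
  data.frame(smiles = vapply(seq_len(n), function(i)
    paste(rep("C", i), collapse = ""), ""), label = rep(c(0, 1), length.out = n))
}

test_that("random splits are sized, disjoint and deterministic", {
  rec <- chain_records(100)
  sp <- randomSplit(rec, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$valid, 10)
  expect_length(sp$test, 10)
  expect_identical(sort(c(sp$train, sp$valid, sp$test)), 1:100)
  expect_identical(randomSplit(rec, seed = 1)$train, sp$train)
  expect_false(identical(randomSplit(rec, seed = 2)$train, sp$train))
})

test_that("scaffold split of 100 distinct scaffolds is sized 8:1:1", {
  sp <- scaffoldSplit(chain_records(100))
  expect_length(sp$train, 80)
  expect_length(sp$valid, 10)
  expect_length(sp$test, 10)
  expect_identical(sort(c(sp$train, sp$valid, sp$test)), 1:100)
})

test_that("no scaffold ever spans two splits", {
  df <- generateLabeled(genSpec(50, seed = 12, sizeRange = c(6L, 18L)),
                        "classification")
  sp <- scaffoldSplit(df)
  keys <- vapply(df$smiles, scaffoldKey, "")
  k <- list(train = unique(keys[sp$train]), valid = unique(keys[sp$valid]),
            test = unique(keys[sp$test]))
  expect_length(intersect(k$train, k$valid), 0)
  expect_length(intersect(k$train, k$test), 0)
  expect_length(intersect(k$valid, k$test), 0)
})

test_that("an oversized scaffold group triggers a warning", {
  rec <- data.frame(smiles = c(rep("c1ccccc1", 12), "CCO", "CCN"),
                    label = 0)
  expect_warning(sp <- scaffoldSplit(rec), "exceeds the train target")
  expect_true(all(1:12 %in% sp$train))
})

test_that("splits require a minimum dataset size", {
  expect_error(scaffoldSplit(chain_records(5)), "at least 10")
})

test_that("classification metric is ROC-AUC in percent", {
  y <- c(0, 0, 1, 1)
  expect_equal(evaluatePredictions(c(0.1, 0.2, 0.8, 0.9), y,
                                   "classification"), 100)
  expect_equal(evaluatePredictions(c(0.9, 0.8, 0.2, 0.1), y,
                                   "classification"), 0)
  expect_equal(evaluatePredictions(c(0.1, 0.8, 0.3, 0.9), y,
                                   "classification"), 75)
  # single-class task excluded with a warning; all excluded is an error
  Y <- cbind(a = y, b = c(1, 1, 1, 1))
  expect_warning(m <- evaluatePredictions(cbind(runif(4), runif(4)), Y,
                                          "classification"), "single class")
  expect_error(suppressWarnings(
    evaluatePredictions(runif(4), rep(1, 4), "classification")))
})

test_that("regression metrics and missing-label handling", {
  p <- c(1, 2, 3, 4); y <- c(1, 2, 5, NA)
  expect_equal(evaluatePredictions(p, y, "regression"),
               sqrt(mean(c(0, 0, 4))))
  expect_equal(evaluatePredictions(p, y, "regression", metric = "mae"),
               mean(c(0, 0, 2)))
})

test_that("fine-tune configuration validates early-stopping settings", {
  expect_error(finetuneConfig("classification", maxEpochs = 10L,
                              patience = 10L))
  cfg <- finetuneConfig("regression", maxEpochs = 5L, patience = 2L)
  expect_identical(cfg$taskKind, "regression")
})

test_that("fine-tuning runs end to end, deterministically, on both tasks", {
  df <- generateLabeled(genSpec(24, seed = 13, sizeRange = c(6L, 14L)),
                        "classification")
  sp <- randomSplit(df, seed = 1)
  cfg <- modelConfig(d = 8L, nHeads = 2L, nLayersSmiles = 1L,
                     nLayersGraph = 1L, nLayersBackbone = 0L,
                     nLayersGraphDecoder = 1L, maxSeqLen = 64L,
                     vocabSize = 4L)
  enc <- exportGraphEncoder(initModel(cfg, seed = 5))
  fcfg <- finetuneConfig("classification", maxEpochs = 3L, patience = 2L,
                         seeds = c(1L, 2L), batchSize = 8L)
  res <- finetuneEncoder(enc, df, sp, fcfg)
  expect_length(res$perSeed, 2)
  expect_true(all(is.finite(res$perSeed)))
  expect_identical(res$metricName, "ROC-AUC (%)")
  expect_equal(res$mean, mean(res$perSeed))
  res2 <- finetuneEncoder(enc, df, sp, fcfg)
  expect_equal(res$perSeed, res2$perSeed, tolerance = 1e-12)

  dfr <- generateLabeled(genSpec(24, seed = 14, sizeRange = c(6L, 14L)),
                         "regression")
  spr <- randomSplit(dfr, seed = 2)
  fcfg_r <- finetuneConfig("regression", maxEpochs = 3L, patience = 2L,
                           seeds = 1L, batchSize = 8L)
  resr <- finetuneEncoder(enc, dfr, spr, fcfg_r)
  expect_identical(resr$metricName, "RMSE")
  expect_true(is.finite(resr$mean))
  expect_gt(resr$mean, 0)
})
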