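# Coordinated mask sampling.

align_for <- function(s) {
  v <- buildVocabulary(s)
  alignAtoms(tokenizeSmiles(s, v), featurizeGraph(s))
}

test_that("masked-count rounding rule", {
  expect_identical(maskedCount(0, 10), 0L)
  expect_identical(maskedCount(0.25, 0), 0L)
  expect_identical(maskedCount(0.25, 1), 1L)   # floor of one
  expect_identical(maskedCount(0.15, 4), 1L)
  expect_identical(maskedCount(0.25, 20), 5L)
  expect_identical(maskedCount(0.15, 20), 3L)
  expect_identical(maskedCount(0.25, 10), 2L)  # banker's rounding of 2.5
  expect_identical(maskedCount(1, 7), 7L)
})

test_that("default plans are disjoint across many molecules and seeds", {
  corpus <- generateCorpus(genSpec(40, seed = 21))
  aligns <- lapply(corpus, align_for)
  for (seed in 1:10) {
    for (al in aligns) {
      p <- sampleMasks(al, seed = seed * 1000L + nAtoms(al))
      expect_length(intersect(maskedGraphIdx(p), maskedSmilesIdx(p)), 0)
      expect_identical(length(maskedGraphIdx(p)),
                       maskedCount(0.25, nAtoms(al)))
      expect_identical(length(maskedSmilesIdx(p)),
                       maskedCount(0.15, nAtoms(al)))
    }
  }
})

test_that("the overlap dial is honored exactly", {
  al <- align_for("CCCCCCCCCCCCCCCCCCCC")  # 20 atoms: kG = 5, kS = 3
  for (rho in c(0, 0.25, 0.5, 0.75, 1)) {
    for (seed in 1:25) {
      p <- sampleMasks(al, overlap = rho, seed = seed)
      kS <- length(maskedSmilesIdx(p))
      expect_identical(length(intersect(maskedGraphIdx(p),
                                        maskedSmilesIdx(p))),
                       as.integer(round(rho * kS)))
    }
  }
})

test_that("plans are deterministic per seed and vary across seeds", {
  al <- align_for("CCCCCCCCCCCCCCCCCCCC")
  p1 <- sampleMasks(al, seed = 7)
  p2 <- sampleMasks(al, seed = 7)
  expect_identical(maskedGraphIdx(p1), maskedGraphIdx(p2))
  expect_identical(maskedSmilesIdx(p1), maskedSmilesIdx(p2))
  plans <- lapply(1:50, function(s) sampleMasks(al, seed = s))
  keys <- vapply(plans, function(p)
    paste(c(maskedGraphIdx(p), "|", maskedSmilesIdx(p)), collapse = ","), "")
  expect_gt(length(unique(keys)), 40)
})

test_that("mask sampling leaves the caller's RNG stream untouched", {
  al <- align_for("CCCCCCCCCC")
  set.seed(99); a <- stats::runif(3)
  set.seed(99); invisible(sampleMasks(al, seed = 1)); b <- stats::runif(3)
  expect_identical(a, b)
})

test_that("each node is masked with approximately uniform marginal", {
  al <- align_for("CCCCCCCCCCCCCCCCCCCC")  # 20 atoms, kG = 5
  counts <- integer(20)
  for (seed in 1:400) {
    p <- sampleMasks(al, seed = seed)
    counts[maskedGraphIdx(p)] <- counts[maskedGraphIdx(p)] + 1L
  }
  # each node expected 100 times (binomial sd ~ 8.7)
  expect_true(all(counts > 55 & counts < 145))
})

test_that("applyMasks corrupts exactly the planned positions", {
  s <- "Cc1ccccc1O"
  v <- buildVocabulary(s)
  ts <- tokenizeSmiles(s, v)
  g <- featurizeGraph(s)
  plan <- sampleMasks(alignAtoms(ts, g), seed = 3)
  out <- applyMasks(ts, g, plan, maskId(v))
  pos <- maskedTokenPositions(plan)
  expect_true(all(out$maskedTokenIds[pos] == maskId(v)))
  expect_identical(out$maskedTokenIds[-pos], tokenIds(ts)[-pos])
  flags <- maskedNodeFlags(plan)
  expect_identical(which(flags), maskedGraphIdx(plan))
  expect_true(all(out$maskedNodeFeatures[flags, ] == 0))
  expect_identical(out$maskedNodeFeatures[!flags, ],
                   nodeFeatures(g)[!flags, ])
})

test_that("applyMasks rejects a plan from another molecule", {
  v <- buildVocabulary(c("CCO", "CCCCCC"))
  ts <- tokenizeSmiles("CCO", v)
  g <- featurizeGraph("CCO")
  plan6 <- sampleMasks(align_for("CCCCCC"), seed = 1)
  expect_error(applyMasks(ts, g, plan6, maskId(v)), "does not match")
})

test_that("infeasible mask plans are rejected", {
  al <- align_for("CCOC")
  expect_error(sampleMasks(al, rG = 1, rS = 0.15, overlap = 0, seed = 1),
               "infeasible")
  al10 <- align_for("CCCCCCCCCC")
  expect_error(sampleMasks(al10, rG = 0.1, rS = 1, overlap = 1, seed = 1),
               "infeasible")
})

test_that("auditMasks reports pooled realized statistics", {
  al <- align_for("CCCCCCCCCCCCCCCCCCCC")  # n = 20
  plans <- lapply(1:30, function(s) sampleMasks(al, seed = s))
  aud <- auditMasks(plans)
  expect_equal(aud$mean_graph_ratio, 5 / 20)
  expect_equal(aud$mean_smiles_ratio, 3 / 20)
  expect_equal(aud$realized_overlap, 0)
  expect_error(auditMasks(list()), "empty")
})
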