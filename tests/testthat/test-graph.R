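# Molecular graph construction and featurization.

test_that("feature widths match the schema", {
  expect_identical(nodeFeatureWidth(), 28L)
  expect_identical(edgeFeatureWidth(), 10L)
  g <- featurizeGraph("CC(=O)O")
  expect_identical(ncol(nodeFeatures(g)), 28L)
  expect_identical(ncol(edgeFeatures(g)), 10L)
})

test_that("acetic acid graph has the expected topology and hydrogens", {
  g <- featurizeGraph("CC(=O)O")
  expect_identical(nAtoms(g), 4L)
  e <- edgeList(g)
  expect_identical(nrow(e), 6L)  # 3 bonds, both directions
  # every directed edge has its reverse
  expect_true(all(paste(e[, 2], e[, 1]) %in% paste(e[, 1], e[, 2])))
  at <- atomTable(g)
  expect_identical(at$element, c("C", "C", "O", "O"))
  expect_identical(at$hcount, c(3L, 0L, 0L, 1L))
  expect_identical(at$degree, c(1L, 3L, 1L, 1L))
  expect_false(any(at$inRing))
})

test_that("aromatic rings are perceived with correct flags and hydrogens", {
  g <- featurizeGraph("c1ccccc1")
  at <- atomTable(g)
  expect_identical(nAtoms(g), 6L)
  expect_true(all(at$aromatic))
  expect_true(all(at$inRing))
  expect_identical(at$hcount, rep(1L, 6))
  expect_identical(nrow(edgeList(g)), 12L)
  # aromatic bond type one-hot (column 4 of the edge schema)
  expect_true(all(edgeFeatures(g)[, 4] == 1))
})

test_that("ring membership separates ring atoms from substituents", {
  g <- featurizeGraph("C1CCCCC1O")
  at <- atomTable(g)
  expect_identical(at$inRing, c(rep(TRUE, 6), FALSE))
  g2 <- featurizeGraph("c1ccc2ccccc2c1")  # fused bicyclic
  expect_true(all(atomTable(g2)$inRing))
})

test_that("charges, explicit hydrogens and chirality are captured", {
  g <- featurizeGraph("C[NH3+].[Cl-]")
  at <- atomTable(g)
  expect_identical(at$charge, c(0L, 1L, -1L))
  expect_identical(at$hcount[2], 3L)
  g2 <- featurizeGraph("C[C@@H](N)C(=O)O")
  expect_identical(atomTable(g2)$chirality[2], "@@")
})

test_that("element one-hot block has exactly one active entry per atom", {
  for (s in panel_smiles()) {
    X <- nodeFeatures(featurizeGraph(s))
    expect_true(all(rowSums(X[, 1:12, drop = FALSE]) == 1))
  }
})

test_that("multiple bonds reduce implicit hydrogen counts", {
  at <- atomTable(featurizeGraph("CC#N"))
  expect_identical(at$hcount, c(3L, 0L, 0L))
  at2 <- atomTable(featurizeGraph("C=CC"))
  expect_identical(at2$hcount, c(2L, 1L, 3L))
})

test_that("graph construction agrees with the OpenBabel oracle", {
  # independent route: ChemmineR/ChemmineOB parse the same strings; compare
  # heavy-atom counts, element sequences and bond counts
  library(ChemmineR)
  cases <- c("CC(=O)O", "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "C(Cl)(Cl)Cl",
             "CCBr", "CC#N", "C=CC", "C1CCCCC1", "c1ccsc1", "OS(=O)(=O)O",
             "c1ccc2ccccc2c1")
  for (s in cases) {
    sdf <- suppressWarnings(smiles2sdf(s))[[1]]
    ab <- atomblock(sdf)
    oracle_elems <- gsub("_\\d+$", "", rownames(ab))
    keep <- oracle_elems != "H"
    g <- featurizeGraph(s)
    expect_identical(nAtoms(g), sum(keep))
    expect_identical(atomTable(g)$element, oracle_elems[keep])
    bb <- bondblock(sdf)
    heavy <- which(keep)
    heavy_bonds <- sum(bb[, 1] %in% heavy & bb[, 2] %in% heavy)
    expect_identical(nrow(edgeList(g)), 2L * heavy_bonds)
  }
})

test_that("ring perception agrees with the OpenBabel oracle", {
  library(ChemmineR)
  cases <- c("C1CCCCC1O", "Cc1ccccc1", "CC(=O)O", "c1ccc2ccccc2c1")
  for (s in cases) {
    sdf <- suppressWarnings(smiles2sdf(s))[[1]]
    ring_atoms <- unique(unlist(ringinfo <- rings(sdf, type = "all",
                                                  arom = FALSE)))
    idx <- sort(as.integer(gsub("^.*_", "", ring_atoms)))
    g <- featurizeGraph(s)
    expect_identical(which(atomTable(g)$inRing), idx)
  }
})

test_that("unparseable SMILES raise errors in featurization", {
  expect_error(featurizeGraph("C1CC"))
  expect_error(featurizeGraph("junk"))
  expect_error(featurizeGraph(""))
})
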