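ielFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixtureBlocks()
      sp <- lncEnsemble:::.stratifiedSplit(transcriptLabels(fx$blocks),
                                           0.2, seed = 77)
      sel <- fitSelections(fx$blocks,
                           control = selectionControl(poolSize = 40,
                                                      sizes = c(5, 10),
                                                      numTrees = 50),
                           seed = 77)
      cache <<- list(train = lncEnsemble:::.subsetBlocks(fx$blocks, sp$train),
                     val = lncEnsemble:::.subsetBlocks(fx$blocks, sp$val),
                     sel = sel)
    }
    cache
  }
})

test_that("base predictors emit calibrated probabilities deterministically", {
  fx <- ielFixture()
  blk <- getBlock(fx$train, "transcript_specified")
  y <- transcriptLabels(fx$train)
  base <- fitBase(blk, y, fx$sel$transcript_specified, seed = 3,
                  numTrees = 100)
  p1 <- predictBase(base, getBlock(fx$val, "transcript_specified"))
  expect_true(all(p1 >= 0 & p1 <= 1))
  base2 <- fitBase(blk, y, fx$sel$transcript_specified, seed = 3,
                   numTrees = 100)
  expect_identical(p1, predictBase(base2,
                                   getBlock(fx$val, "transcript_specified")))
  # a separable toy block trains to AUC 1
  toyY <- rep(c(0L, 1L), each = 10)
  toy <- FeatureBlock("transcript_specified",
                      matrix(as.numeric(toyY), 20, 1,
                             dimnames = list(NULL, "x")))
  toySel <- methods::new("SelectionResult", blockTag = "transcript_specified",
                         rankedIdx = 1L, mrmrIdx = 1L, chosenSize = 1L,
                         chosenIdx = 1L,
                         trace = data.frame(size = 1L, auc = 1))
  tb <- fitBase(toy, toyY, toySel, seed = 1)
  expect_equal(aucScore(toyY, predictBase(tb, toy)), 1)
  expect_error(fitBase(toy, rep(1L, 20), toySel, seed = 1), "both classes")
  expect_error(predictBase(tb, getBlock(fx$val, "spectrum")), "mismatch")
})

test_that("the stacked chain grows one score column per round", {
  fx <- ielFixture()
  m <- ielFit(fx$train, fx$val, selections = fx$sel,
              control = ielControl(maxRounds = 4, numTrees = 50), seed = 5)
  expect_s4_class(m, "IELModel")
  expect_equal(m@trace$dim[1], 6L)                 # round 1 input is 6-dim
  expect_equal(m@trace$dim, 6L + (m@trace$round - 1L))
  expect_lte(m@roundsRun, 4L)
  m1 <- ielFit(fx$train, fx$val, selections = fx$sel,
               control = ielControl(maxRounds = 1, numTrees = 50), seed = 5)
  expect_equal(length(m1@chain), 1L)
})

test_that("prediction is per-row, in [0,1], and order-invariant", {
  fx <- ielFixture()
  m <- ielFit(fx$train, fx$val, selections = fx$sel,
              control = ielControl(maxRounds = 2, numTrees = 50), seed = 5)
  p <- predictProb(m, fx$val)
  expect_true(all(p >= 0 & p <= 1))
  idx <- rev(seq_along(p))
  pRev <- predictProb(m, lncEnsemble:::.subsetBlocks(fx$val, idx))
  expect_equal(pRev, p[idx])
  # same seed + same data -> identical fit and predictions
  m2 <- ielFit(fx$train, fx$val, selections = fx$sel,
               control = ielControl(maxRounds = 2, numTrees = 50), seed = 5)
  expect_identical(predictProb(m2, fx$val), p)
  # missing block -> schema error
  broken <- FeatureBlockSet(fx$val@blocks[1:5], label = fx$val@label)
  expect_error(predictProb(m, broken), "missing feature block")
})

test_that("stacking does not materially hurt the best base predictor", {
  fx <- ielFixture()
  m <- ielFit(fx$train, fx$val, selections = fx$sel,
              control = ielControl(maxRounds = 5, numTrees = 100), seed = 7)
  yVal <- transcriptLabels(fx$val)
  baseAuc <- vapply(m@tags, function(tag)
    aucScore(yVal, predictBase(m@bases[[tag]], getBlock(fx$val, tag))),
    numeric(1))
  finalAuc <- aucScore(yVal, predictProb(m, fx$val))
  expect_gte(finalAuc, max(baseAuc) - 0.02)
  # validation trace never drops sharply between consecutive rounds
  if (nrow(m@trace) > 1)
    expect_true(all(diff(m@trace$auc) > -0.02))
})
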