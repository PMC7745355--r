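test_that("confusion metrics reproduce the defining formulas", {
  expect_equal(confusionMetrics(c(TP = 5, TN = 5, FP = 0, FN = 0)),
               c(SN = 1, SP = 1, ACC = 1))
  expect_equal(
    suppressWarnings(confusionMetrics(c(TP = 3, TN = 0, FP = 0, FN = 1)))[["SN"]],
    0.75)
  expect_equal(confusionMetrics(c(TP = 2, TN = 6, FP = 2, FN = 2))[["ACC"]],
               8 / 12)
  expect_warning(
    out <- confusionMetrics(c(TP = 0, TN = 3, FP = 1, FN = 0)), "SN")
  expect_equal(out[["SN"]], 0)
  # SN depends only on the positive row, SP only on the negative row
  expect_equal(confusionMetrics(c(TP = 3, TN = 9, FP = 1, FN = 1))[["SN"]],
               confusionMetrics(c(TP = 3, TN = 2, FP = 5, FN = 1))[["SN"]])
  cc <- confusionCounts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(cc, c(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
})

test_that("rank AUC equals exhaustive concordant-pair counting", {
  pairAuc <- function(y, s) {
    pos <- which(y == 1L); neg <- which(y == 0L)
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    tot / (length(pos) * length(neg))
  }
  expect_equal(aucScore(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # every label arrangement x every score arrangement over {1,2,3}, n <= 4
  for (n in 2:4) {
    labGrid <- as.matrix(expand.grid(rep(list(0:1), n)))
    labGrid <- labGrid[rowSums(labGrid) %in% seq_len(n - 1), , drop = FALSE]
    scoreGrid <- as.matrix(expand.grid(rep(list(1:3), n)))
    got <- want <- numeric(0)
    for (li in seq_len(nrow(labGrid))) {
      y <- unname(labGrid[li, ])
      for (si in seq_len(nrow(scoreGrid))) {
        s <- unname(scoreGrid[si, ])
        got <- c(got, aucScore(y, s))
        want <- c(want, unname(pairAuc(y, s)))
      }
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
  # n = 5, 6 with real-valued random scores including ties
  set.seed(71)
  got <- want <- numeric(0)
  for (rep in 1:200) {
    y <- sample(c(0L, 1L), sample(5:6, 1), replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(c(0.2, 0.5, 0.9, rnorm(3)), length(y), replace = TRUE)
    got <- c(got, aucScore(y, s))
    want <- c(want, unname(pairAuc(y, s)))
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(aucScore(rep(1L, 4), rnorm(4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(73)
  y <- sample(c(0L, 1L), 30, replace = TRUE)
  y[1:2] <- c(0L, 1L)
  s <- rnorm(30)
  expect_equal(aucScore(y, s), aucScore(y, exp(s)), tolerance = 1e-12)
  expect_equal(aucScore(y, s), aucScore(y, 3 * s - 7), tolerance = 1e-12)
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  fx <- fixtureBlocks()
  report <- suppressWarnings(
    crossValidate(fx$ts, "IEL", config = smallRunConfig(), seed = 5))
  expect_s4_class(report, "CVReport")
  fold <- report@foldAssignment
  expect_setequal(names(fold), transcriptIds(fx$ts))
  expect_equal(sort(unique(fold)), 1:5)
  lab <- transcriptLabels(fx$ts)
  for (cls in 0:1) {
    sizes <- table(fold[lab == cls])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_equal(nrow(cvPerFold(report)), 5L)
  expect_identical(cvSummary(report)$metric, c("SN", "SP", "ACC", "AUC"))
  # every sample is tested exactly once (fold assignment is a partition)
  expect_equal(length(fold), length(lab))
  expect_error(crossValidate(fx$ts[c(1:8, 31:33)], "IEL"), "at least")
  expect_error(crossValidate(fx$ts[1:8], "IEL"), "both classes")
})

test_that("the same seed reproduces an identical report end-to-end", {
  fx <- fixtureBlocks()
  cfg <- smallRunConfig()
  r1 <- suppressWarnings(crossValidate(fx$ts, "IEL", cfg, seed = 42))
  r2 <- suppressWarnings(crossValidate(fx$ts, "IEL", cfg, seed = 42))
  expect_identical(cvPerFold(r1), cvPerFold(r2))
  expect_identical(r1@foldAssignment, r2@foldAssignment)
})
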