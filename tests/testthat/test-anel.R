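test_that("attention weights are uniform under symmetry", {
  f <- matrix(rnorm(3 * 4), 3, 4)
  params <- list(Ww = diag(4), bw = rep(0, 4), hw = rnorm(4))
  out <- attentionForward(rep(list(f), 6), params$Ww, params$bw, params$hw)
  expect_equal(out$alpha, matrix(1 / 6, 3, 6))
  expect_equal(out$Fatt, f)
  # hw = 0 -> uniform weights regardless of inputs
  fs <- lapply(1:6, function(i) matrix(rnorm(8), 2, 4))
  out0 <- attentionForward(fs, matrix(rnorm(16), 4, 4), rnorm(4), rep(0, 4))
  expect_equal(out0$alpha, matrix(1 / 6, 2, 6))
})

test_that("attention reproduces a hand-computed 2-d example", {
  # six single-sample embeddings in d = 2 with integer parameters
  fs <- list(c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 0), c(1, 2))
  Ww <- rbind(c(1, -1), c(0, 1))
  bw <- c(0, -1)
  hw <- c(1, 2)
  # by hand: h_i = max(Ww f_i + bw, 0), logit_i = h_i . hw
  hList <- lapply(fs, function(f) pmax(c(f[1] - f[2], f[2] - 1), 0))
  logits <- vapply(hList, function(h) sum(h * hw), numeric(1))
  aOracle <- exp(logits - max(logits)) / sum(exp(logits - max(logits)))
  fOracle <- Reduce(`+`, Map(function(a, f) a * f, aOracle, fs))
  out <- attentionForward(fs, Ww, bw, hw)
  expect_equal(unname(out$alpha[1, ]), unname(aOracle), tolerance = 1e-12)
  expect_equal(unname(out$Fatt[1, ]), unname(fOracle), tolerance = 1e-12)
  expect_error(attentionForward(list(c(1, 2), c(1, 2, 3)), Ww, bw, hw),
               "same dimension")
})

test_that("softmax rows sum to one and Fatt stays in the embedding hull", {
  set.seed(61)
  fs <- lapply(1:6, function(i) matrix(rnorm(40), 10, 4))
  out <- attentionForward(fs, matrix(rnorm(16), 4, 4), rnorm(4), rnorm(4))
  expect_equal(rowSums(out$alpha), rep(1, 10), tolerance = 1e-12)
  expect_true(all(out$alpha >= 0))
  lo <- Reduce(pmin, fs); hi <- Reduce(pmax, fs)
  expect_true(all(out$Fatt >= lo - 1e-12 & out$Fatt <= hi + 1e-12))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(63)
  dims <- c(5, 3, 4)
  B <- 4
  Xlist <- lapply(dims, function(p) matrix(rnorm(B * p), B, p))
  y <- c(0L, 1L, 1L, 0L)
  params <- lncEnsemble:::.anelInit(dims, anelControl(d = 3, hidden = 3),
                                    seed = 2)
  g <- lncEnsemble:::.anelGrad(params, Xlist, y)$grad
  eps <- 1e-6
  numGrad <- function(get, set) {
    v <- get(params)
    out <- v
    for (i in seq_along(v)) {
      up <- params; vv <- get(up); vv[i] <- vv[i] + eps; up <- set(up, vv)
      dn <- params; vv <- get(dn); vv[i] <- vv[i] - eps; dn <- set(dn, vv)
      out[i] <- (lncEnsemble:::.anelGrad(up, Xlist, y)$loss -
                 lncEnsemble:::.anelGrad(dn, Xlist, y)$loss) / (2 * eps)
    }
    out
  }
  relErr <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)
  expect_lt(relErr(g$Ww, numGrad(function(p) p$Ww,
                                 function(p, v) { p$Ww <- v; p })), 1e-4)
  expect_lt(relErr(g$hw, numGrad(function(p) p$hw,
                                 function(p, v) { p$hw <- v; p })), 1e-4)
  expect_lt(relErr(g$bw, numGrad(function(p) p$bw,
                                 function(p, v) { p$bw <- v; p })), 1e-4)
  expect_lt(relErr(g$We[[2]], numGrad(function(p) p$We[[2]],
                                      function(p, v) { p$We[[2]] <- v; p })),
            1e-4)
})

test_that("training is finite, seeded, and a null update changes nothing", {
  fbs <- makeSignalBlocks(n = 60, seed = 5)
  ctl <- anelControl(d = 16L, hidden = 8L, epochs = 4L)
  m <- anelFit(fbs, control = ctl, seed = 21)
  expect_true(all(is.finite(m@trace$loss)))
  m2 <- anelFit(fbs, control = ctl, seed = 21)
  expect_equal(m@params, m2@params)
  # lr = 0 and dropout = 0: parameters equal the initialization
  sp <- lncEnsemble:::.stratifiedSplit(transcriptLabels(fbs), 0.2, seed = 21)
  ctl0 <- anelControl(d = 16L, hidden = 8L, epochs = 2L, lr = 0, dropout = 0)
  m0 <- anelFit(fbs, control = ctl0, seed = 21)
  trainB <- lncEnsemble:::.subsetBlocks(fbs, sp$train)
  X <- lncEnsemble:::.anelInputs(trainB, blockTags(trainB), NULL)
  init <- lncEnsemble:::.anelInit(vapply(X, ncol, integer(1)), ctl0, seed = 21)
  expect_equal(m0@params, init, tolerance = 1e-12)
})

test_that("a separable six-block dataset is learned to high AUC", {
  fbs <- makeSignalBlocks(n = 200, shift = 3, seed = 7)
  m <- anelFit(fbs, control = anelControl(d = 32L, hidden = 16L,
                                          epochs = 15L), seed = 17)
  expect_gte(max(m@trace$valAUC), 0.95)
})

test_that("prediction is deterministic and block-order invariant", {
  fbs <- makeSignalBlocks(n = 80, seed = 9)
  m <- anelFit(fbs, control = anelControl(d = 16L, hidden = 8L, epochs = 3L),
               seed = 33)
  p1 <- predictProb(m, fbs)
  expect_identical(p1, predictProb(m, fbs))
  shuffled <- FeatureBlockSet(fbs@blocks[c(4, 1, 6, 2, 5, 3)],
                              label = fbs@label)
  expect_equal(predictProb(m, shuffled), p1)
  a <- attentionWeights(m, fbs)
  expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # schema mismatch is caught
  bad <- FeatureBlockSet(lapply(fbs@blocks, function(b)
    FeatureBlock(b@tag, b@values[, -1, drop = FALSE])), label = fbs@label)
  expect_error(predictProb(m, bad), "expects")
})
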