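# Shared fixtures, generated in code and cached for the test run.

.fixtureEnv <- new.env(parent = emptyenv())

# A small labeled synthetic dataset with the default class contrast, plus
# its six feature blocks (full default feature configuration).
fixtureBlocks <- function() {
  if (is.null(.fixtureEnv$blocks)) {
    ts <- generateDataset(synthConfig(nPos = 30L, nNeg = 30L,
                                      lenRange = c(200L, 500L), seed = 424L))
    .fixtureEnv$ts <- ts
    .fixtureEnv$blocks <- extractFeatures(ts)
  }
  list(ts = .fixtureEnv$ts, blocks = .fixtureEnv$blocks)
}

# Reduced configuration for fast end-to-end smoke runs (not the study
# conditions; those live in the acceptance tests).
smallRunConfig <- function(seed = 1L) {
  runConfig(
    selection = selectionControl(poolSize = 50L, sizes = c(5L, 10L, 25L),
                                 numTrees = 50L),
    iel = ielControl(maxRounds = 3L, numTrees = 100L),
    anel = anelControl(d = 32L, hidden = 16L, epochs = 8L),
    seed = seed)
}

# Six aligned gaussian blocks where only `informative` carries label
# signal (a mean shift on its first columns).
makeSignalBlocks <- function(n = 120L, dims = c(20L, 15L, 25L, 10L, 30L, 12L),
                             informative = 3L, shift = 2, seed = 1L) {
  set.seed(seed)
  tags <- c("transcript_specified", "spectrum", "revc_kmer",
            "mismatch", "pse_nc", "acc")
  y <- rep(c(1L, 0L), length.out = n)
  ids <- sprintf("s%03d", seq_len(n))
  blocks <- lapply(seq_along(tags), function(i) {
    m <- matrix(stats::rnorm(n * dims[i]), n, dims[i],
                dimnames = list(ids, paste0(tags[i], ".", seq_len(dims[i]))))
    if (i == informative)
      m[, 1:3] <- m[, 1:3] + shift * y
    FeatureBlock(tags[i], m)
  })
  FeatureBlockSet(blocks, label = y)
}

expectNoLabels <- function(x) suppressMessages(x)
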