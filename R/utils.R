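# Internal helpers shared across modules.

# Stratified train/validation split: valFrac of each class goes to 'val'.
.stratifiedSplit <- function(y, valFrac, seed) {
  y <- as.integer(y)
  val <- integer(0)
  set.seed(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    nVal <- max(1L, round(valFrac * length(idx)))
    val <- c(val, sample(idx, nVal))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

# Stratified k-fold assignment (fold sizes differ by at most 1 per class).
.stratifiedFolds <- function(y, k, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Probability random forest behind the module surfaces (ranger, seeded,
# single-threaded for reproducibility).
.rfFit <- function(x, y, numTrees = 500L, seed = 1L) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(df)))
  df$.y <- factor(y, levels = c(0L, 1L))
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 num.trees = numTrees, probability = TRUE,
                 seed = seed, num.threads = 1L,
                 respect.unordered.factors = TRUE, verbose = FALSE)
}

.rfPredict <- function(fit, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(df)))
  stats::predict(fit, data = df, num.threads = 1L,
                 verbose = FALSE)$predictions[, "1"]
}

# AUC that tolerates a single-class slice (returns NA instead of failing);
# used only for internal model-selection scoring.
.aucSafe <- function(y, scores) {
  if (length(unique(y)) < 2L) return(NA_real_)
  aucScore(y, scores)
}

# Out-of-fold class-1 probabilities on (x, y) via internal stratified
# k-fold refitting; no row is ever scored by a forest that saw it.
.oofScores <- function(x, y, k = 5L, numTrees = 500L, seed = 1L) {
  fold <- .stratifiedFolds(y, k, seed = seed)
  out <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- .rfFit(x[tr, , drop = FALSE], y[tr], numTrees = numTrees,
                  seed = seed + f)
    out[!tr] <- .rfPredict(fit, x[!tr, , drop = FALSE])
  }
  out
}

# Derive a stream of sub-seeds from one integer seed (kept below 2^31).
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}
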