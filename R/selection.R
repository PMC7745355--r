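#' ANOVA (one-way F) feature ranking
#'
#' Per-column one-way F statistic (between-class over within-class
#' variance) for a binary label, with descending order and ties broken by
#' column index. Constant columns get F = 0; columns that separate the
#' classes perfectly (zero within-class variance, positive between-class
#' variance) get F = Inf and rank first.
#'
#' @param x numeric matrix (samples x features)
#' @param y binary labels (0/1), both classes with at least 2 samples
#' @return list with \code{order} (column indices, most important first)
#'   and \code{F} (per-column statistics, original order)
#' @export
anovaRank <- function(x, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  n <- nrow(x)
  g0 <- y == 0L; g1 <- y == 1L
  n0 <- sum(g0); n1 <- sum(g1)
  m0 <- colMeans(x[g0, , drop = FALSE])
  m1 <- colMeans(x[g1, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ssw <- colSums((x[g0, , drop = FALSE] - rep(m0, each = n0))^2) +
         colSums((x[g1, , drop = FALSE] - rep(m1, each = n1))^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2L)
  f <- ifelse(msw == 0, ifelse(msb == 0, 0, Inf), msb / msw)
  list(order = order(-f, seq_along(f)), F = f)
}

# Equal-frequency discretization into up to `bins` levels (1-based integer
# codes). Constant columns collapse to a single level.
.discretize <- function(v, bins = 10L) {
  qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = qs, include.lowest = TRUE))
}

# Plug-in mutual information (nats) between two integer codes.
.miDiscrete <- function(a, b, na, nb) {
  joint <- tabulate((a - 1L) * nb + b, nbins = na * nb)
  n <- length(a)
  p <- joint / n
  pa <- rowSums(matrix(p, na, nb, byrow = TRUE))  # p over levels of a
  pb <- colSums(matrix(p, na, nb, byrow = TRUE))
  pm <- matrix(p, na, nb, byrow = TRUE)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (pa[row(pm)[nz]] * pb[col(pm)[nz]])))
}

#' Two-step ANOVA + mRMR feature selection for one block
#'
#' First ranks all columns by one-way ANOVA F and keeps the top
#' \code{poolSize} as candidates; then orders the candidates by greedy
#' incremental mRMR (MID criterion: maximize the mutual information with
#' the label minus the mean mutual information with the already selected
#' columns, after equal-frequency discretization into 10 bins). Each size
#' in \code{sizes} is scored by a small internal random-forest validation
#' classifier and the size with the highest validation AUC is chosen (ties
#' go to the smaller size). The first mRMR pick is always the
#' maximum-relevance column.
#'
#' @param x numeric matrix (samples x features)
#' @param y binary labels (0/1)
#' @param blockTag family tag recorded in the result
#' @param poolSize ANOVA candidate pool size (clipped to ncol(x))
#' @param sizes size grid (clipped to the pool size)
#' @param trainIdx,valIdx row indices used to fit and score the internal
#'   validation classifier; when NULL a stratified 80/20 split is drawn
#'   from the seed
#' @param bins discretization bins for the mutual information estimates
#' @param numTrees trees of the internal validation forest
#' @param seed integer seed controlling the internal split and forests
#' @return a \linkS4class{SelectionResult}
#' @export
mrmrSelect <- function(x, y, blockTag = "block", poolSize = 500L,
                       sizes = c(10L, 20L, 50L, 100L, 200L, 500L),
                       trainIdx = NULL, valIdx = NULL, bins = 10L,
                       numTrees = 100L, seed = 1L) {
  y <- as.integer(y)
  rk <- anovaRank(x, y)
  pool <- rk$order[seq_len(min(poolSize, ncol(x)))]
  sizes <- sort(unique(pmin(as.integer(sizes), length(pool))))
  if (!length(sizes)) stop("empty size grid")
  disc <- lapply(pool, function(j) .discretize(x[, j], bins))
  nlev <- vapply(disc, max, integer(1))
  ylev <- y + 1L
  rel <- vapply(seq_along(pool), function(i)
    .miDiscrete(disc[[i]], ylev, nlev[i], 2L), numeric(1))
  K <- length(pool)
  maxSize <- max(sizes)
  selected <- integer(0)
  redSum <- numeric(K)
  remaining <- seq_len(K)
  for (step in seq_len(maxSize)) {
    scores <- if (!length(selected)) rel[remaining]
              else rel[remaining] - redSum[remaining] / length(selected)
    pick <- remaining[order(-scores, remaining)[1L]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      mi <- vapply(remaining, function(i)
        .miDiscrete(disc[[i]], disc[[pick]],
                    nlev[i], nlev[pick]), numeric(1))
      redSum[remaining] <- redSum[remaining] + mi
    }
  }
  mrmrIdx <- pool[selected]
  if (is.null(trainIdx) || is.null(valIdx)) {
    sp <- .stratifiedSplit(y, 0.2, seed = seed)
    trainIdx <- sp$train; valIdx <- sp$val
  }
  auc <- vapply(seq_along(sizes), function(si) {
    cols <- mrmrIdx[seq_len(sizes[si])]
    fit <- .rfFit(x[trainIdx, cols, drop = FALSE], y[trainIdx],
                  numTrees = numTrees, seed = seed + si)
    .aucSafe(y[valIdx], .rfPredict(fit, x[valIdx, cols, drop = FALSE]))
  }, numeric(1))
  best <- sizes[order(-auc, sizes)[1L]]
  methods::new("SelectionResult", blockTag = blockTag,
               rankedIdx = as.integer(rk$order), mrmrIdx = as.integer(mrmrIdx),
               chosenSize = as.integer(best),
               chosenIdx = as.integer(mrmrIdx[seq_len(best)]),
               trace = data.frame(size = sizes, auc = auc))
}

#' Serialize a SelectionResult to JSON
#'
#' @param sel a \linkS4class{SelectionResult}
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeSelection <- function(sel, path) {
  jsonlite::write_json(list(
    block_tag = sel@blockTag, ranked_indices = sel@rankedIdx,
    mrmr_indices = sel@mrmrIdx, chosen_size = sel@chosenSize,
    chosen_indices = sel@chosenIdx,
    criterion_trace = sel@trace), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Selection protocol configuration
#'
#' @param poolSize ANOVA candidate pool per block
#' @param sizes subset-size grid evaluated on validation AUC
#' @param bins discretization bins for the mutual information estimates
#' @param numTrees trees of the internal validation forest
#' @return a list of class \code{selectionControl}
#' @export
selectionControl <- function(poolSize = 500L,
                             sizes = c(10L, 20L, 50L, 100L, 200L, 500L),
                             bins = 10L, numTrees = 100L) {
  structure(list(poolSize = as.integer(poolSize), sizes = as.integer(sizes),
                 bins = as.integer(bins), numTrees = as.integer(numTrees)),
            class = "selectionControl")
}

#' Fit the two-step selection for every block of a set
#'
#' @param fbs a labeled \linkS4class{FeatureBlockSet} (train + validation
#'   rows of the current fold)
#' @param trainIdx,valIdx row indices of the training and validation parts
#' @param control a \code{\link{selectionControl}}
#' @param seed integer seed
#' @return named list of \linkS4class{SelectionResult}, keyed by block tag
#' @export
fitSelections <- function(fbs, trainIdx = NULL, valIdx = NULL,
                          control = selectionControl(), seed = 1L) {
  y <- transcriptLabels(fbs)
  seeds <- .subSeeds(seed, length(blockTags(fbs)))
  out <- lapply(seq_along(blockTags(fbs)), function(i) {
    tag <- blockTags(fbs)[i]
    mrmrSelect(featureValues(getBlock(fbs, tag)), y, blockTag = tag,
               poolSize = control$poolSize, sizes = control$sizes,
               trainIdx = trainIdx, valIdx = valIdx, bins = control$bins,
               numTrees = control$numTrees, seed = seeds[i])
  })
  names(out) <- blockTags(fbs)
  out
}
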