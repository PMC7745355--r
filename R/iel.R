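#' Iterative ensemble control parameters
#'
#' @param maxRounds maximum stacking rounds (default 18)
#' @param tol minimum validation-AUC improvement counted as progress
#' @param patience stop after this many consecutive rounds below \code{tol}
#' @param numTrees trees per random forest
#' @param oofFolds internal folds for out-of-fold stacking scores
#' @return a list of class \code{ielControl}
#' @export
ielControl <- function(maxRounds = 18L, tol = 1e-3, patience = 2L,
                       numTrees = 500L, oofFolds = 5L) {
  structure(list(maxRounds = as.integer(maxRounds), tol = tol,
                 patience = as.integer(patience),
                 numTrees = as.integer(numTrees),
                 oofFolds = as.integer(oofFolds)), class = "ielControl")
}

#' Fit one per-block base predictor
#'
#' A probability random forest trained on the block's selected columns.
#'
#' @param block a \linkS4class{FeatureBlock}
#' @param y binary labels (0/1)
#' @param selection the block's \linkS4class{SelectionResult}
#' @param seed integer seed
#' @param numTrees number of trees
#' @return a list (class \code{basePredictor}) with the fitted forest, the
#'   selection, the block tag and the seed
#' @export
fitBase <- function(block, y, selection, seed = 1L, numTrees = 500L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  cols <- selection@chosenIdx
  fit <- .rfFit(featureValues(block)[, cols, drop = FALSE], y,
                numTrees = numTrees, seed = seed)
  structure(list(tag = blockTag(block), selection = selection, model = fit,
                 seed = as.integer(seed)), class = "basePredictor")
}

#' Class-1 probability of a base predictor on a block
#' @param base a \code{basePredictor} from \code{\link{fitBase}}
#' @param block the matching \linkS4class{FeatureBlock}
#' @return numeric probabilities
#' @export
predictBase <- function(base, block) {
  if (blockTag(block) != base$tag)
    stop(sprintf("block tag mismatch: model '%s' vs data '%s'",
                 base$tag, blockTag(block)))
  .rfPredict(base$model, featureValues(block)[, base$selection@chosenIdx,
                                              drop = FALSE])
}

#' Fit the iterative stacked ensemble
#'
#' Trains one random-forest base predictor per feature block on its
#' selected columns, then grows a chain of stacked ensembles: at round t a
#' stacking forest is trained on the out-of-fold probability scores of all
#' current predictors (the 6 bases plus the t - 1 previous ensembles, so
#' its input dimension is exactly 6 + (t - 1)) and is then added to the
#' predictor set itself. Stacking inputs on the training partition are
#' always out-of-fold (internal stratified refits), so no chain member ever
#' sees its own training row's in-fold prediction. Iteration stops at
#' \code{maxRounds} or once the validation AUC has improved by less than
#' \code{tol} for \code{patience} consecutive rounds.
#'
#' @param trainBlocks labeled \linkS4class{FeatureBlockSet} (training part)
#' @param valBlocks labeled \linkS4class{FeatureBlockSet} for early
#'   stopping; when NULL a stratified 80/20 split of \code{trainBlocks} is
#'   used
#' @param selections named list of per-block \linkS4class{SelectionResult};
#'   when NULL, \code{\link{fitSelections}} is run on the training part
#' @param control an \code{\link{ielControl}}
#' @param seed integer seed
#' @return an \linkS4class{IELModel}
#' @export
ielFit <- function(trainBlocks, valBlocks = NULL, selections = NULL,
                   control = ielControl(), seed = 1L) {
  if (is.null(valBlocks)) {
    sp <- .stratifiedSplit(transcriptLabels(trainBlocks), 0.2, seed = seed)
    valBlocks <- .subsetBlocks(trainBlocks, sp$val)
    trainBlocks <- .subsetBlocks(trainBlocks, sp$train)
  }
  y <- transcriptLabels(trainBlocks)
  yVal <- transcriptLabels(valBlocks)
  tags <- blockTags(trainBlocks)
  if (is.null(selections))
    selections <- fitSelections(trainBlocks, control = selectionControl(),
                                seed = seed)
  seeds <- .subSeeds(seed, length(tags) + control$maxRounds)
  bases <- vector("list", length(tags)); names(bases) <- tags
  scoreTrain <- matrix(0, length(y), 0L)
  scoreVal <- matrix(0, length(yVal), 0L)
  for (i in seq_along(tags)) {
    tag <- tags[i]
    sel <- selections[[tag]]
    blk <- getBlock(trainBlocks, tag)
    bases[[tag]] <- fitBase(blk, y, sel, seed = seeds[i],
                            numTrees = control$numTrees)
    cols <- sel@chosenIdx
    oof <- .oofScores(featureValues(blk)[, cols, drop = FALSE], y,
                      k = control$oofFolds, numTrees = control$numTrees,
                      seed = seeds[i])
    scoreTrain <- cbind(scoreTrain, oof)
    scoreVal <- cbind(scoreVal, predictBase(bases[[tag]],
                                            getBlock(valBlocks, tag)))
  }
  nBases <- length(tags)
  chain <- list()
  trace <- data.frame(round = integer(), dim = integer(), auc = numeric())
  bestAuc <- -Inf; stall <- 0L
  for (t in seq_len(control$maxRounds)) {
    stopifnot(ncol(scoreTrain) == nBases + (t - 1L))
    rs <- seeds[nBases + t]
    stack <- .rfFit(scoreTrain, y, numTrees = control$numTrees, seed = rs)
    valScore <- .rfPredict(stack, scoreVal)
    aucVal <- aucScore(yVal, valScore)
    chain[[t]] <- stack
    trace <- rbind(trace, data.frame(round = t, dim = ncol(scoreTrain),
                                     auc = aucVal))
    if (aucVal > bestAuc + control$tol) {
      bestAuc <- max(bestAuc, aucVal); stall <- 0L
    } else {
      bestAuc <- max(bestAuc, aucVal); stall <- stall + 1L
      if (stall >= control$patience) break
    }
    if (t < control$maxRounds) {
      oof <- .oofScores(scoreTrain, y, k = control$oofFolds,
                        numTrees = control$numTrees, seed = rs)
      scoreTrain <- cbind(scoreTrain, oof)
      scoreVal <- cbind(scoreVal, valScore)
    }
  }
  methods::new("IELModel", bases = bases, chain = chain, tags = tags,
               roundsRun = length(chain), trace = trace,
               seed = as.integer(seed))
}

#' @describeIn ielFit predict class-1 probabilities: the six bases score
#'   each row, then every chain member is applied in order, each feeding
#'   its score back into the accumulated score matrix; the last chain
#'   member's output is returned.
#' @param object a fitted \linkS4class{IELModel}
#' @param blocks a \linkS4class{FeatureBlockSet} with the training-time tags
#' @export
setMethod("predictProb", "IELModel", function(object, blocks) {
  missing <- setdiff(object@tags, blockTags(blocks))
  if (length(missing))
    stop(sprintf("missing feature block(s): %s",
                 paste(missing, collapse = ", ")))
  scores <- vapply(object@tags, function(tag)
    predictBase(object@bases[[tag]], getBlock(blocks, tag)),
    numeric(nrow(featureValues(getBlock(blocks, object@tags[1L])))))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  p <- NULL
  for (stack in object@chain) {
    p <- .rfPredict(stack, scores)
    scores <- cbind(scores, p)
  }
  unname(p)
})
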