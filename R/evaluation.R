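#' Confusion counts from labels and predictions
#'
#' @param labels true binary labels (0/1)
#' @param predicted predicted binary labels (0/1)
#' @return named integer vector \code{c(TP, TN, FP, FN)}
#' @export
confusionCounts <- function(labels, predicted) {
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  stopifnot(length(labels) == length(predicted),
            all(labels %in% 0:1), all(predicted %in% 0:1))
  c(TP = sum(labels == 1L & predicted == 1L),
    TN = sum(labels == 0L & predicted == 0L),
    FP = sum(labels == 0L & predicted == 1L),
    FN = sum(labels == 1L & predicted == 0L))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/(TP+TN+FP+FN). A metric
#' whose denominator is zero is reported as 0 with a warning.
#'
#' @param counts named vector with TP, TN, FP, FN (as from
#'   \code{\link{confusionCounts}})
#' @return named numeric vector \code{c(SN, SP, ACC)}
#' @export
confusionMetrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  safe <- function(num, den, what) {
    if (den == 0) { warning(sprintf("%s undefined (zero denominator)", what)); 0 }
    else num / den
  }
  c(SN = safe(tp, tp + fn, "SN"),
    SP = safe(tn, tn + fp, "SP"),
    ACC = safe(tp + tn, tp + tn + fp + fn, "ACC"))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted 0.5, equal to the
#' trapezoidal area under the (1-SP, SN) curve over all thresholds, and
#' invariant under strictly monotone transforms of the scores.
#'
#' @param labels binary labels (0/1), both classes present
#' @param scores numeric scores, larger = more positive
#' @return the AUC in [0, 1]
#' @export
aucScore <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Stratified 5-fold cross-validation of the full pipeline
#'
#' Splits the labeled dataset into 5 stratified folds; in each fold the
#' remaining four fifths are split 80/20 (stratified) into training and
#' validation. Per fold, strictly inside the training partition: the
#' hexamer reference table is rebuilt, per-block ANOVA + mRMR selection is
#' fit (scored on the validation part), and the chosen model (IEL or ANEL)
#' is trained with its early-stopping / checkpoint decisions made on the
#' validation part. Metrics (SN, SP, ACC at threshold 0.5, and AUC) are
#' computed on the held-out test fold and aggregated as mean and sd.
#'
#' @param ts a labeled \linkS4class{TranscriptSet} (both classes, at least
#'   5 per class)
#' @param method \code{"IEL"} or \code{"ANEL"}
#' @param config a \code{\link{runConfig}}
#' @param seed integer seed driving fold assignment and all model fits
#' @param nFolds number of folds (default 5)
#' @return a \linkS4class{CVReport}
#' @export
crossValidate <- function(ts, method = c("IEL", "ANEL"),
                          config = runConfig(), seed = 1L, nFolds = 5L) {
  method <- match.arg(method)
  lab <- transcriptLabels(ts)
  if (anyNA(lab)) stop("all transcripts must be labeled")
  if (!all(c(0L, 1L) %in% lab)) stop("dataset must contain both classes")
  if (min(table(lab)) < nFolds)
    stop(sprintf("each class needs at least %d members", nFolds))
  seeds <- .subSeeds(seed, nFolds + 1L)
  fold <- .stratifiedFolds(lab, nFolds, seed = seeds[nFolds + 1L])
  seqs <- transcriptSeqs(ts)
  # Label-free blocks are pure per-sequence functions: compute once; only
  # the hexamer column depends on the fold-specific reference table.
  general <- extractFeaturesGeneral(ts, config$feature)
  tsStatic <- .transcriptFeatureMatrix(seqs)
  perFold <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    foldSeed <- seeds[f]
    testIdx <- which(fold == f)
    restIdx <- which(fold != f)
    sp <- .stratifiedSplit(lab[restIdx], 0.2, seed = foldSeed)
    trainIdx <- restIdx[sp$train]; valIdx <- restIdx[sp$val]
    hex <- buildHexamerTable(seqs[trainIdx][lab[trainIdx] == 0L],
                             seqs[trainIdx][lab[trainIdx] == 1L],
                             pseudocount = config$feature$hexamerPseudocount)
    tsMat <- tsStatic
    tsMat[, "hexamer"] <- .hexamerColumn(seqs, hex)
    blocks <- FeatureBlockSet(
      c(list(FeatureBlock("transcript_specified", tsMat)), general@blocks),
      label = lab)
    fitIdx <- c(trainIdx, valIdx)   # selection sees train+val of this fold
    selections <- fitSelections(.subsetBlocks(blocks, fitIdx),
                                trainIdx = seq_along(trainIdx),
                                valIdx = seq_along(valIdx) + length(trainIdx),
                                control = config$selection,
                                seed = foldSeed)
    trainBlocks <- .subsetBlocks(blocks, trainIdx)
    valBlocks <- .subsetBlocks(blocks, valIdx)
    model <- if (method == "IEL")
      ielFit(trainBlocks, valBlocks, selections = selections,
             control = config$iel, seed = foldSeed)
    else
      anelFit(trainBlocks, valBlocks, selections = selections,
              control = config$anel, seed = foldSeed)
    testBlocks <- .subsetBlocks(blocks, testIdx)
    p <- predictProb(model, testBlocks)
    cm <- confusionMetrics(confusionCounts(lab[testIdx],
                                           as.integer(p >= 0.5)))
    perFold[[f]] <- data.frame(fold = f, SN = cm[["SN"]], SP = cm[["SP"]],
                               ACC = cm[["ACC"]],
                               AUC = aucScore(lab[testIdx], p))
  }
  perFold <- do.call(rbind, perFold)
  metrics <- c("SN", "SP", "ACC", "AUC")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m) mean(perFold[[m]]),
                                      numeric(1)),
                        sd = vapply(metrics, function(m) stats::sd(perFold[[m]]),
                                    numeric(1)))
  methods::new("CVReport", perFold = perFold, summary = summary,
               foldAssignment = stats::setNames(fold, transcriptIds(ts)),
               method = method, seed = as.integer(seed))
}

#' Write a CVReport as JSON and TSV
#'
#' @param report a \linkS4class{CVReport}
#' @param jsonPath,tsvPath output paths (NULL = skip)
#' @return invisibly, the report
#' @export
writeCVReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath))
    jsonlite::write_json(list(method = report@method, seed = report@seed,
                              per_fold = report@perFold,
                              summary = report@summary,
                              fold_assignment = as.list(report@foldAssignment)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsvPath))
    utils::write.table(report@perFold, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(report)
}
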