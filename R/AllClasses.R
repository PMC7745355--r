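#' @include AllGenerics.R
NULL

#' TranscriptSet: labeled transcript sequences
#'
#' A set of transcript sequences held as a \link[Biostrings]{DNAStringSet}
#' (internal alphabet is DNA: U is mapped to T on input) together with an
#' optional binary label per transcript (1 = lncRNA, 0 = protein-coding
#' transcript, NA = unlabeled). Identifiers must be unique and every
#' sequence must contain only A/C/G/T; construct instances through
#' \code{\link{TranscriptSet}} or \code{\link{readTranscripts}} so that
#' normalization and validation are applied.
#'
#' @slot seqs a \link[Biostrings]{DNAStringSet} with unique names
#' @slot label integer vector parallel to \code{seqs} with values 0, 1 or NA
#'
#' @seealso \code{\link{readTranscripts}}, \code{\link{extractFeatures}}
#' @export
setClass("TranscriptSet",
  representation(seqs = "ANY", label = "integer"),
  validity = function(object) {
    msg <- character()
    if (!methods::is(object@seqs, "DNAStringSet"))
      msg <- c(msg, "'seqs' must be a DNAStringSet")
    else {
      ids <- names(object@seqs)
      if (is.null(ids) || anyNA(ids) || any(ids == ""))
        msg <- c(msg, "all transcripts must be named")
      else if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate transcript id: '%s'",
                              ids[duplicated(ids)][1L]))
      if (length(object@seqs) && any(Biostrings::width(object@seqs) < 1L))
        msg <- c(msg, "zero-length sequence")
      alph <- Biostrings::alphabetFrequency(object@seqs, baseOnly = TRUE)
      if (length(object@seqs) && any(alph[, "other"] > 0))
        msg <- c(msg, "sequences must contain only A/C/G/T after normalization")
    }
    if (length(object@label) != length(object@seqs))
      msg <- c(msg, "'label' length must match number of sequences")
    if (!all(object@label %in% c(0L, 1L, NA_integer_)))
      msg <- c(msg, "labels must be 0, 1 or NA")
    if (length(msg)) msg else TRUE
  })

#' Construct a TranscriptSet
#'
#' Sequences are normalized with \code{\link{normalizeSequence}} (uppercase,
#' U to T, ambiguity codes rejected) before the object is built.
#'
#' @param seqs named character vector, or a DNAStringSet/RNAStringSet with
#'   unique names
#' @param label optional vector of 0/1 labels (recycled if length 1);
#'   NA marks unlabeled transcripts
#' @param ids optional ids overriding \code{names(seqs)}
#' @return a \linkS4class{TranscriptSet}
#' @examples
#' ts <- TranscriptSet(c(t1 = "acgu", t2 = "ATGAAATAG"), label = c(1, 0))
#' transcriptLengths(ts)
#' @export
TranscriptSet <- function(seqs, label = NULL, ids = NULL) {
  if (methods::is(seqs, "XStringSet")) {
    ids0 <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- ids0
  }
  if (!is.character(seqs)) stop("'seqs' must be character or an XStringSet")
  if (!is.null(ids)) names(seqs) <- ids
  if (is.null(names(seqs))) stop("transcripts must be named")
  norm <- vapply(seqs, normalizeSequence, character(1), USE.NAMES = FALSE)
  if (is.null(label)) label <- rep(NA_integer_, length(norm))
  label <- as.integer(rep_len(label, length(norm)))
  methods::new("TranscriptSet",
    seqs = Biostrings::DNAStringSet(stats::setNames(norm, names(seqs))),
    label = label)
}

#' FeatureBlock: one feature family for a set of transcripts
#'
#' A numeric matrix (transcripts in rows, features in columns, both named)
#' carrying the tag of the feature family it encodes. The six family tags
#' used by the pipeline are \code{transcript_specified}, \code{spectrum},
#' \code{revc_kmer}, \code{mismatch}, \code{pse_nc} and \code{acc}.
#'
#' @slot tag character(1) family tag
#' @slot values numeric matrix with row and column names
#' @export
setClass("FeatureBlock",
  representation(tag = "character", values = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@tag) != 1L || is.na(object@tag) || object@tag == "")
      msg <- c(msg, "'tag' must be a single non-empty string")
    if (!is.numeric(object@values))
      msg <- c(msg, "'values' must be numeric")
    if (is.null(colnames(object@values)))
      msg <- c(msg, "'values' must have column names")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "feature values must be finite")
    if (length(msg)) msg else TRUE
  })

#' @rdname FeatureBlock-class
#' @param tag family tag
#' @param values numeric matrix
#' @export
FeatureBlock <- function(tag, values) {
  methods::new("FeatureBlock", tag = tag, values = values)
}

#' FeatureBlockSet: the six aligned feature blocks of a dataset
#'
#' Holds one \linkS4class{FeatureBlock} per feature family, all with
#' identical row order, plus the label vector of the underlying transcripts.
#'
#' @slot blocks named list of \linkS4class{FeatureBlock}, keyed by tag
#' @slot label integer labels parallel to the block rows (NA = unlabeled)
#' @export
setClass("FeatureBlockSet",
  representation(blocks = "list", label = "integer"),
  validity = function(object) {
    msg <- character()
    if (!length(object@blocks)) msg <- c(msg, "no blocks")
    ok <- vapply(object@blocks, function(b) methods::is(b, "FeatureBlock"),
                 logical(1))
    if (!all(ok)) msg <- c(msg, "all elements must be FeatureBlock")
    else {
      tags <- vapply(object@blocks, blockTag, character(1))
      if (!identical(unname(tags), names(object@blocks)))
        msg <- c(msg, "list names must equal block tags")
      nr <- vapply(object@blocks, function(b) nrow(b@values), integer(1))
      if (length(unique(nr)) > 1L)
        msg <- c(msg, "blocks must have the same number of rows")
      rn <- lapply(object@blocks, function(b) rownames(b@values))
      if (length(rn) > 1L &&
          !all(vapply(rn[-1], identical, logical(1), rn[[1]])))
        msg <- c(msg, "blocks must share identical row order")
      if (length(object@label) != nr[1L])
        msg <- c(msg, "'label' length must match block rows")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname FeatureBlockSet-class
#' @param blocks list of \linkS4class{FeatureBlock}
#' @param label optional 0/1 labels parallel to the block rows
#' @export
FeatureBlockSet <- function(blocks, label = NULL) {
  names(blocks) <- vapply(blocks, blockTag, character(1))
  n <- nrow(blocks[[1]]@values)
  if (is.null(label)) label <- rep(NA_integer_, n)
  methods::new("FeatureBlockSet", blocks = blocks, label = as.integer(label))
}

#' HexamerTable: in-frame hexamer usage of coding and non-coding transcripts
#'
#' Pseudocounted in-frame hexamer frequencies, used by
#' \code{\link{hexamerScore}} as the log-ratio reference. Coding frequencies
#' are counted in-frame (step 3) over each coding transcript's longest ORF;
#' non-coding frequencies over whole sequences from position 1 with step 3.
#'
#' @slot coding named numeric of length 4096, sums to 1
#' @slot noncoding named numeric of length 4096, sums to 1
#' @slot pseudocount positive real added to every cell before normalization
#' @seealso \code{\link{buildHexamerTable}}
#' @export
setClass("HexamerTable",
  representation(coding = "numeric", noncoding = "numeric",
                 pseudocount = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in c("coding", "noncoding")) {
      v <- methods::slot(object, nm)
      if (length(v) != 4096L) msg <- c(msg, sprintf("'%s' must cover all 4096 hexamers", nm))
      else {
        if (any(v <= 0)) msg <- c(msg, sprintf("'%s' frequencies must be positive", nm))
        if (abs(sum(v) - 1) > 1e-9) msg <- c(msg, sprintf("'%s' must sum to 1", nm))
      }
    }
    if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
      msg <- c(msg, "'pseudocount' must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' SelectionResult: per-block two-step feature selection outcome
#'
#' Produced by \code{\link{mrmrSelect}}: the ANOVA importance ranking, the
#' greedy mRMR ordering of the candidate pool, the validation-chosen subset
#' size and the score trace over the evaluated size grid.
#'
#' @slot blockTag feature family tag
#' @slot rankedIdx ANOVA-ranked column indices (descending F)
#' @slot mrmrIdx greedy mRMR ordering of the candidate pool
#' @slot chosenSize selected subset size
#' @slot chosenIdx prefix of \code{mrmrIdx} of length \code{chosenSize}
#' @slot trace data.frame with columns \code{size} and \code{auc}
#' @export
setClass("SelectionResult",
  representation(blockTag = "character", rankedIdx = "integer",
                 mrmrIdx = "integer", chosenSize = "integer",
                 chosenIdx = "integer", trace = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@chosenSize < 1L) msg <- c(msg, "'chosenSize' must be >= 1")
    if (!identical(object@chosenIdx, object@mrmrIdx[seq_len(object@chosenSize)]))
      msg <- c(msg, "'chosenIdx' must be the prefix of the mRMR ordering")
    if (!all(object@mrmrIdx %in% object@rankedIdx))
      msg <- c(msg, "mRMR candidates must come from the ranked pool")
    if (length(msg)) msg else TRUE
  })

#' IELModel: iterative stacked ensemble over six feature families
#'
#' Six per-family random-forest base predictors plus the chain of stacked
#' ensemble classifiers grown iteratively: at round t the stack is trained
#' on the 6 + (t - 1) probability scores of all current predictors and is
#' then added to the predictor set itself.
#'
#' @slot bases named list (by tag) of base predictors, each a list with the
#'   fitted forest, its \linkS4class{SelectionResult} and seed
#' @slot chain list of stacked classifiers, in training order
#' @slot tags block tag order used for the score matrix
#' @slot roundsRun number of stacking rounds actually run
#' @slot trace data.frame with per-round validation AUC
#' @slot seed integer seed the fit was derived from
#' @export
setClass("IELModel",
  representation(bases = "list", chain = "list", tags = "character",
                 roundsRun = "integer", trace = "data.frame", seed = "integer"))

#' ANELModel: attention-network feature fusion classifier
#'
#' Per-family affine embedders into a shared dimension d, a shared attention
#' scorer (Ww, bw, hw) producing softmax weights over the six families, and
#' an MLP head on the attention-weighted embedding sum. Standardization
#' statistics and the per-family selected columns are stored so prediction
#' reproduces the training-time input pipeline.
#'
#' @slot params list of network parameters (We/be per tag, Ww, bw, hw,
#'   W1/b1, W2/b2)
#' @slot tags block tag order
#' @slot selections named list of \linkS4class{SelectionResult} or NULL
#' @slot scaling per-tag list of column means and sds used to standardize
#' @slot hyper list of hyperparameters (d, lr, batch, epochs, dropout, hidden)
#' @slot trace data.frame (epoch, loss, valAUC)
#' @slot seed integer seed
#' @export
setClass("ANELModel",
  representation(params = "list", tags = "character", selections = "list",
                 scaling = "list", hyper = "list", trace = "data.frame",
                 seed = "integer"))

#' CVReport: stratified 5-fold cross-validation report
#'
#' @slot perFold data.frame with one row per fold (SN, SP, ACC, AUC)
#' @slot summary data.frame with mean and sd per metric
#' @slot foldAssignment integer fold id per sample, named by transcript id
#' @slot method "IEL" or "ANEL"
#' @slot seed integer seed
#' @export
setClass("CVReport",
  representation(perFold = "data.frame", summary = "data.frame",
                 foldAssignment = "integer", method = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    k <- nrow(object@perFold)
    if (length(object@foldAssignment) &&
        !setequal(unique(object@foldAssignment), seq_len(k)))
      msg <- c(msg, "every fold must test at least one sample")
    if (length(msg)) msg else TRUE
  })

## ---- accessors and show methods ----

#' @rdname transcript-accessors
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@seqs))

#' @rdname transcript-accessors
setMethod("transcriptSeqs", "TranscriptSet",
          function(x) stats::setNames(as.character(x@seqs), names(x@seqs)))

#' @rdname transcript-accessors
setMethod("transcriptLengths", "TranscriptSet",
          function(x) stats::setNames(Biostrings::width(x@seqs), names(x@seqs)))

#' @rdname transcript-accessors
setMethod("transcriptLabels", "TranscriptSet",
          function(x) stats::setNames(x@label, names(x@seqs)))

#' @describeIn TranscriptSet number of transcripts
#' @param x a TranscriptSet
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@seqs))

#' @describeIn TranscriptSet subset by index, id or logical mask
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  methods::new("TranscriptSet", seqs = x@seqs[i], label = x@label[i])
})

setMethod("show", "TranscriptSet", function(object) {
  lab <- object@label
  cat(sprintf("TranscriptSet with %d transcripts (%d lncRNA, %d PCT, %d unlabeled)\n",
              length(object@seqs), sum(lab == 1L, na.rm = TRUE),
              sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
  if (length(object@seqs)) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf("  length range: %d-%d nt\n", min(w), max(w)))
  }
})

#' @rdname featureblock-accessors
setMethod("blockTag", "FeatureBlock", function(x) x@tag)

#' @rdname featureblock-accessors
setMethod("featureValues", "FeatureBlock", function(x) x@values)

#' @rdname featureblock-accessors
setMethod("blockTags", "FeatureBlockSet", function(x) names(x@blocks))

#' @rdname featureblock-accessors
setMethod("getBlock", "FeatureBlockSet", function(x, tag) {
  if (!tag %in% names(x@blocks))
    stop(sprintf("no block tagged '%s'", tag))
  x@blocks[[tag]]
})

#' @describeIn FeatureBlockSet labels of the underlying transcripts
#' @param x a FeatureBlockSet
#' @export
setMethod("transcriptLabels", "FeatureBlockSet", function(x) x@label)

setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock '%s': %d transcripts x %d features\n",
              object@tag, nrow(object@values), ncol(object@values)))
})

setMethod("show", "FeatureBlockSet", function(object) {
  cat(sprintf("FeatureBlockSet: %d transcripts, %d blocks\n",
              nrow(object@blocks[[1]]@values), length(object@blocks)))
  for (b in object@blocks)
    cat(sprintf("  %-21s %5d features\n", b@tag, ncol(b@values)))
})

setMethod("show", "HexamerTable", function(object) {
  cat(sprintf("HexamerTable: 4096 in-frame hexamer frequencies (pseudocount %g)\n",
              object@pseudocount))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult '%s': %d of %d candidates chosen (grid best AUC %.4f)\n",
              object@blockTag, object@chosenSize, length(object@mrmrIdx),
              max(object@trace$auc)))
})

setMethod("show", "IELModel", function(object) {
  cat(sprintf("IELModel: 6 base predictors + chain of %d stacked ensembles\n",
              length(object@chain)))
  cat(sprintf("  final validation AUC: %.4f\n", utils::tail(object@trace$auc, 1)))
})

setMethod("show", "ANELModel", function(object) {
  cat(sprintf("ANELModel: d = %d attention fusion over %d blocks, %d epochs trained\n",
              object@hyper$d, length(object@tags), nrow(object@trace)))
  cat(sprintf("  best validation AUC: %.4f\n", max(object@trace$valAUC)))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport (%s, %d-fold, seed %d)\n", object@method,
              nrow(object@perFold), object@seed))
  s <- object@summary
  for (m in s$metric)
    cat(sprintf("  %-4s %.4f +/- %.4f\n", m,
                s$mean[s$metric == m], s$sd[s$metric == m]))
})

#' Per-fold and summary metrics of a CVReport
#' @param report a \linkS4class{CVReport}
#' @return \code{cvPerFold}: data.frame of per-fold SN/SP/ACC/AUC;
#'   \code{cvSummary}: data.frame with mean and sd per metric.
#' @export
cvPerFold <- function(report) report@perFold

#' @rdname cvPerFold
#' @export
cvSummary <- function(report) report@summary
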