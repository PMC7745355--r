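#' Transcript accessors
#'
#' Accessors for \linkS4class{TranscriptSet}: identifiers, sequences (as
#' plain character), lengths and binary labels (1 = lncRNA, 0 =
#' protein-coding transcript, NA = unlabeled).
#'
#' @param x a \linkS4class{TranscriptSet}
#' @return a vector parallel to the transcripts
#' @name transcript-accessors
#' @aliases transcriptIds transcriptSeqs transcriptLengths transcriptLabels
NULL

#' @rdname transcript-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname transcript-accessors
#' @export
setGeneric("transcriptSeqs", function(x) standardGeneric("transcriptSeqs"))

#' @rdname transcript-accessors
#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @rdname transcript-accessors
#' @export
setGeneric("transcriptLabels", function(x) standardGeneric("transcriptLabels"))

#' Feature block accessors
#'
#' @param x a \linkS4class{FeatureBlock} or \linkS4class{FeatureBlockSet}
#' @param tag character, the family tag of the block to extract
#' @return \code{blockTag} the family tag; \code{featureValues} the numeric
#'   matrix (transcripts in rows); \code{blockTags} the tags of all blocks in
#'   a set; \code{getBlock} one \linkS4class{FeatureBlock} from a set.
#' @name featureblock-accessors
NULL

#' @rdname featureblock-accessors
#' @export
setGeneric("blockTag", function(x) standardGeneric("blockTag"))

#' @rdname featureblock-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureblock-accessors
#' @export
setGeneric("blockTags", function(x) standardGeneric("blockTags"))

#' @rdname featureblock-accessors
#' @export
setGeneric("getBlock", function(x, tag) standardGeneric("getBlock"))

#' Predict class-1 (lncRNA) probabilities from a fitted ensemble model
#'
#' Dispatches on the model type: for an \linkS4class{IELModel} the six base
#' random forests score each transcript and the stacked chain is applied in
#' order; for an \linkS4class{ANELModel} the attention network is evaluated
#' in eval mode (dropout off).
#'
#' @param object a fitted \linkS4class{IELModel} or \linkS4class{ANELModel}
#' @param blocks a \linkS4class{FeatureBlockSet} produced with the same
#'   feature configuration as at training time
#' @return numeric vector of probabilities in [0, 1], one per transcript
#' @export
setGeneric("predictProb", function(object, blocks) standardGeneric("predictProb"))
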