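#' Feature extraction configuration
#'
#' Bundles the tunable parameters of the six feature families. Defaults are
#' the settings the pipeline was designed around: k = 1..5 for the spectrum
#' and reverse-complement profiles, mismatch pairs (3,1), (4,1), (5,1),
#' per-variant (lambda, w) = (7, 0.5), (7, 0.7), (6, 0.7), (7, 0.1),
#' (6, 0.1) for the pseudo compositions, and lag = 7 for the auto-cross
#' covariance.
#'
#' @param ks k values for spectrum and reverse-complement profiles
#' @param mismatchPairs list of c(k, m) pairs
#' @param pseNcSpecs named list of per-variant list(lambda =, w =)
#'   overrides (NULL = variant defaults)
#' @param lagMax auto-cross covariance maximum lag
#' @param hexamerPseudocount pseudocount of the hexamer table
#' @return a list of class \code{featureConfig}
#' @export
featureConfig <- function(ks = 1:5,
                          mismatchPairs = list(c(3L, 1L), c(4L, 1L), c(5L, 1L)),
                          pseNcSpecs = NULL,
                          lagMax = 7L,
                          hexamerPseudocount = 1) {
  structure(list(ks = as.integer(ks), mismatchPairs = mismatchPairs,
                 pseNcSpecs = pseNcSpecs, lagMax = as.integer(lagMax),
                 hexamerPseudocount = hexamerPseudocount),
            class = "featureConfig")
}

#' Extract the six feature blocks of a dataset
#'
#' Computes all six feature families with identical row order:
#' \code{transcript_specified} (38), \code{spectrum} (1364),
#' \code{revc_kmer} (708), \code{mismatch} (1344), \code{pse_nc} (310, the
#' five variants concatenated) and \code{acc} (280, DACC + TACC).
#'
#' @param x a \linkS4class{TranscriptSet}
#' @param config a \code{\link{featureConfig}}
#' @param hexTable optional \linkS4class{HexamerTable}; see
#'   \code{\link{transcriptFeatures}} for the leakage caveat
#' @return a \linkS4class{FeatureBlockSet} carrying the labels of \code{x}
#' @export
extractFeatures <- function(x, config = featureConfig(), hexTable = NULL) {
  stopifnot(methods::is(x, "TranscriptSet"))
  blocks <- list(
    transcriptFeatures(x, hexTable = hexTable),
    FeatureBlock("spectrum", spectrumProfile(x, config$ks)),
    FeatureBlock("revc_kmer", revcKmerProfile(x, config$ks)),
    FeatureBlock("mismatch", mismatchProfile(x, config$mismatchPairs)),
    FeatureBlock("pse_nc", pseNcBlock(x, config$pseNcSpecs)),
    FeatureBlock("acc", accBlock(x, config$lagMax)))
  FeatureBlockSet(blocks, label = transcriptLabels(x))
}

# Subset a FeatureBlockSet by row index.
.subsetBlocks <- function(fbs, idx) {
  blocks <- lapply(fbs@blocks, function(b)
    FeatureBlock(b@tag, b@values[idx, , drop = FALSE]))
  FeatureBlockSet(blocks, label = fbs@label[idx])
}

#' Write feature blocks as TSV
#'
#' One TSV per block (header, id column first), the shared dialect of all
#' feature outputs.
#'
#' @param fbs a \linkS4class{FeatureBlockSet}
#' @param dir output directory (created if missing)
#' @return the written paths, invisibly
#' @export
writeFeatureTSV <- function(fbs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(fbs@blocks, function(b) {
    p <- file.path(dir, paste0(b@tag, ".tsv"))
    df <- data.frame(id = rownames(b@values), b@values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Extract only the five label-free general feature blocks
#'
#' The spectrum, reverse-complement, mismatch, pseudo-composition and
#' auto-cross covariance blocks are pure per-sequence functions, so they
#' can be computed once per dataset; only the transcript-specified block
#' depends on a (fold-specific) hexamer table.
#'
#' @inheritParams extractFeatures
#' @return a \linkS4class{FeatureBlockSet} with five blocks
#' @export
extractFeaturesGeneral <- function(x, config = featureConfig()) {
  stopifnot(methods::is(x, "TranscriptSet"))
  blocks <- list(
    FeatureBlock("spectrum", spectrumProfile(x, config$ks)),
    FeatureBlock("revc_kmer", revcKmerProfile(x, config$ks)),
    FeatureBlock("mismatch", mismatchProfile(x, config$mismatchPairs)),
    FeatureBlock("pse_nc", pseNcBlock(x, config$pseNcSpecs)),
    FeatureBlock("acc", accBlock(x, config$lagMax)))
  FeatureBlockSet(blocks, label = transcriptLabels(x))
}
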