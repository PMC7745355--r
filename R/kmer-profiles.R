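.asDSS <- function(x) {
  if (methods::is(x, "TranscriptSet")) return(x@seqs)
  if (methods::is(x, "DNAStringSet")) return(x)
  s <- .asSeq(x)
  if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  Biostrings::DNAStringSet(s)
}

#' All k-mers in lexicographic order (A < C < G < T)
#' @param k word length
#' @return character vector of length 4^k
#' @export
allKmers <- function(k) {
  g <- expand.grid(rep(list(.BASES), k), stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}

# Exact k-mer window counts, rows = sequences, columns = 4^k k-mers in
# lexicographic order.
.kmerCounts <- function(dss, k) {
  m <- Biostrings::oligonucleotideFrequency(dss, width = k)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(m)))
  rownames(m) <- names(dss)
  m
}

.windowNorm <- function(counts, widths, k) {
  denom <- pmax(widths - k + 1L, 1L)
  counts / denom
}

#' Spectrum (k-mer) profile
#'
#' For each k the 4^k-dimensional vector of k-mer occurrence frequencies,
#' each count normalized by the number of windows (L - k + 1); blocks for
#' the requested k values are concatenated in ascending k. When L < k the
#' block is all zeros.
#'
#' @param x sequences (TranscriptSet, XStringSet or character vector)
#' @param ks strictly increasing k values (default 1:5, total dimension
#'   4 + 16 + 64 + 256 + 1024 = 1364)
#' @return numeric matrix, one row per sequence
#' @export
spectrumProfile <- function(x, ks = 1:5) {
  stopifnot(all(ks >= 1L), !is.unsorted(ks, strictly = TRUE))
  dss <- .asDSS(x)
  w <- Biostrings::width(dss)
  do.call(cbind, lapply(ks, function(k) {
    m <- .windowNorm(.kmerCounts(dss, k), w, k)
    colnames(m) <- paste0("spec.", colnames(m))
    m
  }))
}

#' Canonical reverse-complement k-mer representatives
#'
#' Each k-mer is folded onto the lexicographically smaller of itself and
#' its reverse complement; the sorted unique representatives define the
#' profile's columns (2, 10, 32, 136, 528 for k = 1..5).
#'
#' @param k word length
#' @return character vector of canonical k-mers, sorted
#' @export
canonicalKmers <- function(k) {
  km <- allKmers(k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  sort(unique(pmin(km, rc)))
}

#' Reverse-complement k-mer profile
#'
#' k-mer counts folded onto canonical representatives (a k-mer and its
#' reverse complement share one cell), normalized by the number of windows
#' L - k + 1; per-k blocks concatenated in ascending k.
#'
#' @inheritParams spectrumProfile
#' @return numeric matrix, one row per sequence
#' @export
revcKmerProfile <- function(x, ks = 1:5) {
  stopifnot(all(ks >= 1L), !is.unsorted(ks, strictly = TRUE))
  dss <- .asDSS(x)
  w <- Biostrings::width(dss)
  do.call(cbind, lapply(ks, function(k) {
    counts <- .kmerCounts(dss, k)
    km <- colnames(counts)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    canon <- pmin(km, rc)
    reps <- sort(unique(canon))
    folded <- vapply(reps, function(r)
      rowSums(counts[, canon == r, drop = FALSE]), numeric(nrow(counts)))
    if (nrow(counts) == 1L)
      folded <- matrix(folded, nrow = 1L, dimnames = list(rownames(counts), reps))
    m <- .windowNorm(folded, w, k)
    colnames(m) <- paste0("revc.", reps)
    m
  }))
}

# Indices (1-based, lexicographic) of all k-mers within Hamming distance
# <= m of each k-mer; returned as a 0/1 aggregation matrix A with
# A[p, q] = 1 iff d(p, q) <= m. Symmetric. Cached per (k, m).
.mismatchCache <- new.env(parent = emptyenv())

.mismatchMatrix <- function(k, m) {
  key <- paste(k, m, sep = "_")
  if (!is.null(.mismatchCache[[key]])) return(.mismatchCache[[key]])
  n <- 4L^k
  # digits[i, ] = base-4 expansion of k-mer i (most significant first)
  digits <- matrix(0L, n, k)
  idx <- 0:(n - 1L)
  for (j in k:1) { digits[, j] <- idx %% 4L; idx <- idx %/% 4L }
  A <- matrix(0, n, n)
  for (p in seq_len(n)) {
    d <- colSums(t(digits) != digits[p, ])
    A[p, d <= m] <- 1
  }
  .mismatchCache[[key]] <- A
  A
}

#' Mismatch profile
#'
#' For each (k, m) pair and each of the 4^k patterns in lexicographic
#' order, the number of length-k windows of the sequence whose Hamming
#' distance to the pattern is at most m, normalized by the number of
#' windows L - k + 1. Windows are shared among patterns by construction,
#' so rows are not probability-normalized across patterns; with m = 0 the
#' profile reduces exactly to the spectrum profile.
#'
#' @param x sequences (TranscriptSet, XStringSet or character vector)
#' @param pairs list of c(k, m) pairs with m < k (default
#'   (3,1), (4,1), (5,1), total dimension 64 + 256 + 1024 = 1344)
#' @return numeric matrix, one row per sequence
#' @export
mismatchProfile <- function(x, pairs = list(c(3L, 1L), c(4L, 1L), c(5L, 1L))) {
  dss <- .asDSS(x)
  w <- Biostrings::width(dss)
  do.call(cbind, lapply(pairs, function(km) {
    k <- km[1L]; m <- km[2L]
    if (m >= k || m < 0L) stop("mismatch tolerance must satisfy 0 <= m < k")
    counts <- .kmerCounts(dss, k)
    mm <- counts %*% .mismatchMatrix(k, m)
    res <- .windowNorm(mm, w, k)
    colnames(res) <- paste0("mis", k, m, ".", colnames(counts))
    rownames(res) <- rownames(counts)
    res
  }))
}
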