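.asSeq <- function(x) {
  if (methods::is(x, "TranscriptSet")) transcriptSeqs(x)
  else if (methods::is(x, "XStringSet")) stats::setNames(as.character(x), names(x))
  else if (is.character(x)) x
  else stop("expected a TranscriptSet, XStringSet or character vector")
}

.seq1 <- function(x) {
  s <- .asSeq(x)
  if (length(s) != 1L) stop("expected a single sequence")
  unname(s)
}

#' Find open reading frames on the forward strand
#'
#' Scans all three frames of the forward strand (inputs are transcripts,
#' already stranded) for ATG-initiated spans. For each ATG the span runs to
#' the first in-frame stop codon (TAA/TAG/TGA), stop included
#' (\code{hasStop = TRUE}); an ATG with no downstream in-frame stop yields
#' an incomplete span truncated at the last full codon
#' (\code{hasStop = FALSE}).
#'
#' @param x a single sequence (character), or a one-element
#'   TranscriptSet/XStringSet
#' @return a data.frame with 1-based columns \code{start}, \code{end}
#'   (inclusive), \code{frame} (0..2), \code{hasStart}, \code{hasStop} and
#'   \code{ntLength}, sorted by start; zero rows when no ATG exists
#' @examples
#' findOrfs("ATGAAATAG")
#' @export
findOrfs <- function(x) {
  s <- .seq1(x)
  L <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(), frame = integer(),
                      hasStart = logical(), hasStop = logical(),
                      ntLength = integer())
  if (L < 3L) return(empty)
  codStart <- seq_len(L - 2L)
  cods <- substring(s, codStart, codStart + 2L)
  atg <- codStart[cods == "ATG"]
  if (!length(atg)) return(empty)
  stops <- codStart[cods %in% .STOP_CODONS]
  out <- lapply(atg, function(a) {
    fr <- (a - 1L) %% 3L
    st <- stops[stops > a & (stops - a) %% 3L == 0L]
    if (length(st)) {
      e <- st[1L] + 2L
      data.frame(start = a, end = e, frame = fr, hasStart = TRUE,
                 hasStop = TRUE, ntLength = e - a + 1L)
    } else {
      len <- ((L - a + 1L) %/% 3L) * 3L
      data.frame(start = a, end = a + len - 1L, frame = fr, hasStart = TRUE,
                 hasStop = FALSE, ntLength = len)
    }
  })
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# Longest ORF (incomplete spans count), ties broken by smaller start;
# NULL when no ORF.
.longestOrf <- function(orfs) {
  if (!nrow(orfs)) return(NULL)
  orfs[order(-orfs$ntLength, orfs$start), , drop = FALSE][1L, , drop = FALSE]
}

#' ORF-derived scalar features
#'
#' \code{orfLength} is the nucleotide length of the first (5'-most)
#' complete ORF; \code{orfCoverage} is the longest ORF's length (complete
#' or incomplete) divided by the transcript length; \code{orfIntegrity} is
#' 1 iff the longest ORF has both a start and a stop codon. All three are 0
#' when the transcript has no ORF.
#'
#' @param x a single sequence
#' @return named numeric vector \code{c(orfLength, orfCoverage, orfIntegrity)}
#' @examples
#' orfFeatures("ATGAAATAG")  # 9, 1, 1
#' @export
orfFeatures <- function(x) {
  s <- .seq1(x)
  orfs <- findOrfs(s)
  if (!nrow(orfs))
    return(c(orfLength = 0, orfCoverage = 0, orfIntegrity = 0))
  complete <- orfs[orfs$hasStop, , drop = FALSE]
  firstLen <- if (nrow(complete)) complete$ntLength[1L] else 0
  longest <- .longestOrf(orfs)
  c(orfLength = as.numeric(firstLen),
    orfCoverage = longest$ntLength / nchar(s),
    orfIntegrity = as.numeric(longest$hasStart && longest$hasStop))
}
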