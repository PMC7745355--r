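#' Normalize a raw transcript sequence
#'
#' Uppercases the sequence and maps U to T so that all downstream k-mer,
#' codon and property tables live in a single DNA alphabet. Characters
#' outside A/C/G/T/U (any case) are rejected with the position of the first
#' offending character; sequences containing the ambiguity code N are
#' rejected rather than silently skipped, because k-mer counting over
#' ambiguous bases is not defined here.
#'
#' The function is idempotent: applying it twice gives the same result.
#'
#' @param raw a single non-empty character string
#' @return the normalized sequence (uppercase, DNA alphabet)
#' @examples
#' normalizeSequence("acguACGU")  # "ACGTACGT"
#' @export
normalizeSequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("sequence must be a single non-empty string")
  up <- chartr("u", "T", toupper(raw))
  up <- chartr("U", "T", up)
  bad <- regexpr("[^ACGT]", up)
  if (bad > 0L) {
    ch <- substr(up, bad, bad)
    if (ch == "N")
      stop(sprintf("ambiguity code 'N' at position %d is not allowed", bad))
    stop(sprintf("disallowed character '%s' at position %d", ch, bad))
  }
  up
}

.parseFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty FASTA input: %s", path))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop(sprintf("malformed FASTA (no leading '>'): %s", path))
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste0, character(1),
                 collapse = "")
  if (length(seqs) != length(ids)) {
    empty <- setdiff(as.character(seq_along(ids)), names(seqs))
    stop(sprintf("malformed FASTA: record '%s' has no sequence",
                 ids[as.integer(empty[1L])]))
  }
  stats::setNames(unname(seqs), ids)
}

#' Read transcripts from FASTA
#'
#' Reads a (multi-line) FASTA file, normalizes every sequence with
#' \code{\link{normalizeSequence}} and attaches an optional common label.
#' Duplicate record ids are an error. Records shorter than 200 nt are kept
#' (lncRNAs are defined as > 200 nt but reference datasets contain shorter
#' records) with a message reporting how many there are. With
#' \code{dropAmbiguous = TRUE}, records containing ambiguity codes are
#' skipped with a message instead of raising an error.
#'
#' @param path FASTA file path
#' @param label optional label (1 = lncRNA, 0 = PCT) applied to all records
#' @param dropAmbiguous skip records with ambiguity codes instead of failing
#' @return a \linkS4class{TranscriptSet}
#' @seealso \code{\link{readTranscriptPair}}, \code{\link{writeTranscripts}}
#' @export
readTranscripts <- function(path, label = NULL, dropAmbiguous = FALSE) {
  seqs <- .parseFasta(path)
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate transcript id in %s: '%s'", path,
                 names(seqs)[duplicated(names(seqs))][1L]))
  if (dropAmbiguous) {
    ok <- vapply(seqs, function(s) !is.null(tryCatch(normalizeSequence(s),
                 error = function(e) NULL)), logical(1))
    if (any(!ok))
      message(sprintf("dropped %d record(s) with ambiguous characters", sum(!ok)))
    seqs <- seqs[ok]
    if (!length(seqs)) stop("no records left after dropping ambiguous ones")
  }
  ts <- tryCatch(TranscriptSet(seqs, label = label), error = function(e)
    stop(sprintf("while reading %s: %s", path, conditionMessage(e))))
  short <- sum(transcriptLengths(ts) < 200L)
  if (short > 0L)
    message(sprintf("%d transcript(s) shorter than 200 nt", short))
  ts
}

#' Read a labeled dataset from a positive/negative FASTA pair
#'
#' The canonical two-file input: one FASTA of lncRNAs (label 1) and one of
#' protein-coding transcripts (label 0). Ids must be unique across both.
#'
#' @param posPath FASTA of positive (lncRNA) transcripts
#' @param negPath FASTA of negative (PCT) transcripts
#' @param dropAmbiguous passed to \code{\link{readTranscripts}}
#' @return a labeled \linkS4class{TranscriptSet}
#' @export
readTranscriptPair <- function(posPath, negPath, dropAmbiguous = FALSE) {
  pos <- readTranscripts(posPath, label = 1L, dropAmbiguous = dropAmbiguous)
  neg <- readTranscripts(negPath, label = 0L, dropAmbiguous = dropAmbiguous)
  ids <- c(transcriptIds(pos), transcriptIds(neg))
  if (anyDuplicated(ids))
    stop(sprintf("transcript id '%s' appears in both files",
                 ids[duplicated(ids)][1L]))
  TranscriptSet(c(transcriptSeqs(pos), transcriptSeqs(neg)),
                label = c(transcriptLabels(pos), transcriptLabels(neg)))
}

#' Attach labels from a TSV table
#'
#' Reads a two-column table with header \code{id<TAB>label} and assigns the
#' labels to the matching transcripts; every transcript must be covered.
#'
#' @param ts a \linkS4class{TranscriptSet}
#' @param path TSV path with columns \code{id} and \code{label}
#' @return the relabeled TranscriptSet
#' @export
readLabels <- function(ts, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab)))
    stop("label table must have columns 'id' and 'label'")
  idx <- match(transcriptIds(ts), tab$id)
  if (anyNA(idx))
    stop(sprintf("no label for transcript '%s'",
                 transcriptIds(ts)[which(is.na(idx))[1L]]))
  TranscriptSet(transcriptSeqs(ts), label = as.integer(tab$label[idx]))
}

#' Write a TranscriptSet to FASTA
#'
#' @param ts a \linkS4class{TranscriptSet}
#' @param path output file path
#' @param width line width for sequence wrapping
#' @return \code{path}, invisibly
#' @export
writeTranscripts <- function(ts, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- transcriptSeqs(ts)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
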