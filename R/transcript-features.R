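#' Fickett TESTCODE score
#'
#' The classic TESTCODE statistic: for each base, the position parameter is
#' the maximum of its three codon-phase counts divided by the minimum plus
#' one, and the content parameter is its overall frequency; each of the
#' eight values is mapped to a probability through the published lookup
#' tables and the probabilities are combined with the published weights.
#' Sequences shorter than 3 nt score 0 by convention.
#'
#' @param x a single sequence
#' @return the Fickett score (higher = more coding-like)
#' @export
fickettScore <- function(x) {
  s <- .seq1(x)
  L <- nchar(s)
  if (L < 3L) return(0)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  phase <- rep_len(1:3, L)
  tb <- .FICKETT
  score <- 0
  for (b in .BASES) {
    phaseCounts <- vapply(1:3, function(p) sum(chars == b & phase == p),
                          numeric(1))
    posVal <- max(phaseCounts) / (min(phaseCounts) + 1)
    contVal <- sum(phaseCounts) / L
    posIdx <- which(posVal >= tb$posPara)[1L]
    contIdx <- which(contVal >= tb$contPara)[1L]
    score <- score + tb$posProb[[b, posIdx]] * tb$posWeight[[b]] +
      tb$contProb[[b, contIdx]] * tb$contWeight[[b]]
  }
  score
}

# In-frame (step 3) hexamer windows of a sequence region; character(0)
# when fewer than one full hexamer fits.
.inframeHexamers <- function(s, from = 1L, to = nchar(s)) {
  if (to - from + 1L < 6L) return(character())
  starts <- seq.int(from, to - 5L, by = 3L)
  substring(s, starts, starts + 5L)
}

.allHexamers <- function() {
  k4 <- expand.grid(rep(list(.BASES), 6L), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(do.call(paste0, k4))
}

#' Build an in-frame hexamer frequency table
#'
#' Coding frequencies are counted in steps of 3 over each coding
#' transcript's longest ORF; non-coding frequencies over each full
#' non-coding sequence from position 1 in steps of 3. A pseudocount is
#' added to every one of the 4096 cells before normalization so that both
#' maps are strictly positive and sum to 1.
#'
#' @param coding transcripts of the coding class (TranscriptSet or
#'   character vector)
#' @param noncoding transcripts of the non-coding class
#' @param pseudocount positive real added to every cell
#' @return a \linkS4class{HexamerTable}
#' @seealso \code{\link{hexamerScore}}
#' @export
buildHexamerTable <- function(coding, noncoding, pseudocount = 1) {
  cod <- .asSeq(coding); nc <- .asSeq(noncoding)
  if (!length(cod) || !length(nc))
    stop("both transcript lists must be non-empty")
  hexes <- .allHexamers()
  countSet <- function(windows) {
    cnt <- stats::setNames(numeric(4096L), hexes)
    if (length(windows)) {
      tb <- table(windows)
      cnt[names(tb)] <- as.numeric(tb)
    }
    cnt
  }
  codWin <- unlist(lapply(cod, function(s) {
    lo <- .longestOrf(findOrfs(s))
    if (is.null(lo)) character() else .inframeHexamers(s, lo$start, lo$end)
  }), use.names = FALSE)
  ncWin <- unlist(lapply(nc, function(s) .inframeHexamers(s)),
                  use.names = FALSE)
  codFreq <- countSet(codWin) + pseudocount
  ncFreq <- countSet(ncWin) + pseudocount
  methods::new("HexamerTable", coding = codFreq / sum(codFreq),
               noncoding = ncFreq / sum(ncFreq), pseudocount = pseudocount)
}

#' Hexamer usage score
#'
#' Mean log-ratio \eqn{\log(f_{coding}(h)/f_{noncoding}(h))} over the
#' in-frame hexamers of the longest ORF (the whole sequence when no ORF
#' exists). Positive scores indicate coding-like hexamer usage. Returns 0
#' when fewer than one hexamer window exists.
#'
#' @param x a single sequence
#' @param table a \linkS4class{HexamerTable}
#' @return the hexamer score
#' @export
hexamerScore <- function(x, table) {
  stopifnot(methods::is(table, "HexamerTable"))
  s <- .seq1(x)
  lo <- .longestOrf(findOrfs(s))
  win <- if (is.null(lo)) .inframeHexamers(s)
         else .inframeHexamers(s, lo$start, lo$end)
  if (!length(win)) return(0)
  mean(log(table@coding[win] / table@noncoding[win]))
}

.translateOrf <- function(s) {
  lo <- .longestOrf(findOrfs(s))
  if (is.null(lo)) return("")
  to <- if (lo$hasStop) lo$end - 3L else lo$end   # stop codon excluded
  if (to < lo$start + 2L) return("")
  starts <- seq.int(lo$start, to - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  paste0(Biostrings::GENETIC_CODE[codons], collapse = "")
}

.netCharge <- function(pep, pH) {
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  pos <- .PKA_POSITIVE["Nterm"]
  neg <- .PKA_NEGATIVE["Cterm"]
  for (r in c("K", "R", "H"))
    pos <- c(pos, rep(.PKA_POSITIVE[[r]], sum(aa == r)))
  for (r in c("D", "E", "C", "Y"))
    neg <- c(neg, rep(.PKA_NEGATIVE[[r]], sum(aa == r)))
  sum(1 / (1 + 10^(pH - pos))) - sum(1 / (1 + 10^(neg - pH)))
}

#' Peptide features of the longest ORF
#'
#' Translates the longest ORF with the standard genetic code (initial Met
#' kept, terminal stop excluded) and computes the theoretical isoelectric
#' point (bisection on the Henderson-Hasselbalch net charge with the
#' Bjellqvist/Expasy pKa set, to |charge| < 1e-4 on pH in [0, 14]), the
#' GRAVY hydropathy mean (Kyte-Doolittle) and the Guruprasad instability
#' index \eqn{(10/len)\sum DIWV(x_i, x_{i+1})}. A transcript with no ORF
#' (or an empty peptide) yields (0, 0, 0).
#'
#' @param x a single sequence
#' @return named numeric vector \code{c(pI, gravy, instability)}
#' @export
peptideFeatures <- function(x) {
  s <- .seq1(x)
  pep <- .translateOrf(s)
  if (pep == "" || grepl("*", pep, fixed = TRUE))
    return(c(pI = 0, gravy = 0, instability = 0))
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    ch <- .netCharge(pep, mid)
    if (abs(ch) < 1e-4) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  pI <- (lo + hi) / 2
  gravy <- mean(.KYTE_DOOLITTLE[aa])
  inst <- if (length(aa) < 2L) 0 else
    (10 / length(aa)) * sum(.DIWV[cbind(aa[-length(aa)], aa[-1L])])
  c(pI = pI, gravy = gravy, instability = inst)
}

#' Composition-transition-distribution (CTD) descriptor
#'
#' A 30-dimensional global descriptor: 4 composition values (fraction of
#' each base), 6 transition values (fraction of adjacent unordered
#' heteropairs AC, AG, AT, CG, CT, GT among the L-1 adjacent pairs) and 20
#' distribution values (for each base, the fractional sequence position of
#' its first occurrence and of the occurrences at 25, 50, 75 and 100
#' percent of that base's count; the ceil(q * count)-th occurrence, divided
#' by L). A base absent from the sequence contributes 0 to its five
#' distribution cells.
#'
#' @param x a single sequence of length >= 2
#' @return named numeric vector of length 30
#' @export
ctdFeatures <- function(x) {
  s <- .seq1(x)
  L <- nchar(s)
  if (L < 2L) stop("CTD requires a sequence of length >= 2")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  comp <- vapply(.BASES, function(b) sum(chars == b) / L, numeric(1))
  names(comp) <- paste0("comp.", .BASES)
  pairsU <- paste0(pmin(chars[-L], chars[-1L]), pmax(chars[-L], chars[-1L]))
  hetero <- c("AC", "AG", "AT", "CG", "CT", "GT")
  trans <- vapply(hetero, function(p) sum(pairsU == p) / (L - 1L), numeric(1))
  names(trans) <- paste0("trans.", hetero)
  dist <- numeric(0)
  for (b in .BASES) {
    pos <- which(chars == b)
    cells <- if (!length(pos)) rep(0, 5L) else {
      cnt <- length(pos)
      idx <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * cnt))
      pos[idx] / L
    }
    names(cells) <- paste0("dist.", b, ".", c(0, 25, 50, 75, 100))
    dist <- c(dist, cells)
  }
  c(comp, trans, dist)
}

#' Transcript-specified feature block (38 dimensions)
#'
#' Computes, per transcript: ORF length, ORF coverage, ORF integrity,
#' Fickett score, hexamer score, pI, GRAVY, instability index, and the
#' 30-dimensional CTD descriptor, in that order.
#'
#' @param x a TranscriptSet (or character vector of sequences)
#' @param hexTable a \linkS4class{HexamerTable} for the hexamer score.
#'   When NULL and \code{x} carries both labels, a table is built from
#'   \code{x} itself (coding = label 0, non-coding = label 1); supply a
#'   training-fold table explicitly to avoid information leakage in
#'   evaluation settings.
#' @return a \linkS4class{FeatureBlock} tagged \code{transcript_specified}
#' @export
transcriptFeatures <- function(x, hexTable = NULL) {
  seqs <- .asSeq(x)
  if (is.null(hexTable)) {
    if (methods::is(x, "TranscriptSet") &&
        all(c(0L, 1L) %in% transcriptLabels(x))) {
      lab <- transcriptLabels(x)
      hexTable <- buildHexamerTable(seqs[lab == 0L], seqs[lab == 1L])
    } else stop("supply 'hexTable' (or a fully labeled TranscriptSet)")
  }
  rows <- .transcriptFeatureMatrix(seqs)
  rows[, "hexamer"] <- .hexamerColumn(seqs, hexTable)
  FeatureBlock("transcript_specified", rows)
}

# The 37 table-free columns (hexamer left at 0), reusable across CV folds.
.transcriptFeatureMatrix <- function(seqs) {
  rows <- t(vapply(seqs, function(s) {
    c(orfFeatures(s), fickett = fickettScore(s), hexamer = 0,
      peptideFeatures(s), ctdFeatures(s))
  }, numeric(38L)))
  rownames(rows) <- names(seqs)
  rows
}

.hexamerColumn <- function(seqs, hexTable) {
  vapply(seqs, hexamerScore, numeric(1), table = hexTable)
}
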