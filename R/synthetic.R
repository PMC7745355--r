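#' Synthetic dataset configuration
#'
#' Defines the study conditions of the built-in benchmark: negatives are
#' protein-coding-like transcripts carrying a long in-frame ORF with biased
#' codon usage; positives are lncRNA-like transcripts with matched base
#' composition but no such ORF structure.
#'
#' @param nPos,nNeg class sizes (defaults 300/300)
#' @param lenRange transcript length range in nt (min >= 60)
#' @param orfFracNeg fraction of a negative's length occupied by its ORF
#' @param codonBiasStrength in [0, 1]: mixes the packaged biased codon
#'   table with the uniform 61-codon distribution
#' @param gcShift added to the background GC content of 0.5
#' @param seed integer seed
#' @return a list of class \code{synthConfig}
#' @export
synthConfig <- function(nPos = 300L, nNeg = 300L, lenRange = c(200L, 1000L),
                        orfFracNeg = 0.7, codonBiasStrength = 0.8,
                        gcShift = 0, seed = 1L) {
  stopifnot(nPos >= 1L, nNeg >= 1L, length(lenRange) == 2L,
            lenRange[1L] >= 60L, lenRange[1L] <= lenRange[2L],
            orfFracNeg >= 0, orfFracNeg <= 1,
            codonBiasStrength >= 0, codonBiasStrength <= 1)
  structure(list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
                 lenRange = as.integer(lenRange), orfFracNeg = orfFracNeg,
                 codonBiasStrength = codonBiasStrength, gcShift = gcShift,
                 seed = as.integer(seed)), class = "synthConfig")
}

# Altschul-Erickson dinucleotide-preserving shuffle: permutes a sequence
# so that every dinucleotide count (and hence base composition) is exactly
# preserved while higher-order structure (codons, ORFs) is destroyed.
.dinucShuffle <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 3L) return(s)
  last <- chars[n]
  edges <- split(chars[-1L], factor(chars[-n], levels = .BASES), drop = TRUE)
  verts <- names(edges)
  for (try in 1:1000) {
    lastEdge <- vapply(verts, function(v)
      if (v == last && !length(edges[[v]])) NA_character_
      else edges[[v]][sample.int(length(edges[[v]]), 1L)], character(1))
    # every vertex with out-edges must reach `last` through the lastEdge map
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; seen <- character()
      while (!is.na(cur) && cur != last && !(cur %in% seen) &&
             cur %in% verts) {
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(s)   # pathological composition; keep as is
  pool <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last && !length(e)) return(character())
    drop <- match(lastEdge[[v]], e)
    rest <- e[-drop]
    c(if (length(rest)) sample(rest) else character(), lastEdge[[v]])
  })
  names(pool) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:n) {
    nxt <- pool[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste0(out, collapse = "")
}

.sampleBackground <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# One PCT-like sequence: UTR + ATG + biased codons + stop + UTR.
.samplePctLike <- function(len, orfFrac, biasStrength, gc) {
  if (orfFrac == 0) return(.sampleBackground(len, gc))
  orfLen <- max(9L, (floor(orfFrac * len) %/% 3L) * 3L)
  orfLen <- min(orfLen, (len %/% 3L) * 3L)
  nCodons <- orfLen %/% 3L - 2L   # minus start and stop
  codons <- setdiff(names(.CODON_USAGE), .STOP_CODONS)
  biased <- .CODON_USAGE[codons] / sum(.CODON_USAGE[codons])
  p <- biasStrength * biased + (1 - biasStrength) / length(codons)
  body <- if (nCodons > 0L)
    paste0(sample(codons, nCodons, replace = TRUE, prob = p), collapse = "")
  else ""
  orf <- paste0("ATG", body, sample(.STOP_CODONS, 1L))
  utrLen <- len - nchar(orf)
  utr5 <- sample.int(utrLen + 1L, 1L) - 1L
  paste0(if (utr5 > 0L) .sampleBackground(utr5, gc) else "",
         orf,
         if (utrLen - utr5 > 0L) .sampleBackground(utrLen - utr5, gc) else "")
}

#' Generate a labeled synthetic transcript dataset
#'
#' Negatives (PCT-like) are drawn as random UTRs flanking an ATG-initiated
#' ORF whose codons come from the biased codon table mixed with the
#' uniform distribution by \code{codonBiasStrength} and whose length
#' covers \code{orfFracNeg} of the transcript. Positives (lncRNA-like) are
#' drawn from the same construction and then dinucleotide-shuffled, so
#' base and dinucleotide composition match between classes and only
#' ORF/codon structure separates them. With \code{codonBiasStrength = 0}
#' and \code{orfFracNeg = 0} the two classes are exchangeable (the null
#' configuration). All draws derive from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @return a labeled \linkS4class{TranscriptSet} (positives first)
#' @export
generateDataset <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "synthConfig"))
  set.seed(cfg$seed)
  gc <- 0.5 + cfg$gcShift
  if (gc <= 0 || gc >= 1) stop("infeasible gcShift")
  lens <- function(n) sample(seq.int(cfg$lenRange[1L], cfg$lenRange[2L]),
                             n, replace = TRUE)
  negSeqs <- vapply(lens(cfg$nNeg), function(L)
    .samplePctLike(L, cfg$orfFracNeg, cfg$codonBiasStrength, gc), character(1))
  posSeqs <- vapply(lens(cfg$nPos), function(L)
    .dinucShuffle(.samplePctLike(L, cfg$orfFracNeg, cfg$codonBiasStrength, gc)),
    character(1))
  names(posSeqs) <- sprintf("pos_%04d", seq_len(cfg$nPos))
  names(negSeqs) <- sprintf("neg_%04d", seq_len(cfg$nNeg))
  TranscriptSet(c(posSeqs, negSeqs),
                label = c(rep(1L, cfg$nPos), rep(0L, cfg$nNeg)))
}
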