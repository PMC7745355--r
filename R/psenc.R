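# Overlapping oligomers (step 1) of a sequence as a character vector.
.oligomers <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character())
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

#' Pseudo nucleotide composition variants
#'
#' Chou-type pseudo composition: the first 16 (dinucleotide) or 64
#' (trinucleotide) entries are the normalized oligomer frequencies
#' \eqn{f_u / (1 + w \sum_j \theta_j)} and the remaining entries are
#' \eqn{w \theta_j / (1 + w \sum_j \theta_j)}, so the full vector is
#' non-negative and sums to 1.
#'
#' Parallel-correlation variants (\code{PseDNC}, \code{PC-PseDNC-General},
#' \code{PC-PseTNC-General}) use one \eqn{\theta} per tier j = 1..lambda:
#' the mean over sequence positions of the mean squared difference of the
#' standardized property values between oligomers j apart (lambda extra
#' entries). Series-correlation variants (\code{SC-PseDNC-General},
#' \code{SC-PseTNC-General}) use one \eqn{\theta} per (property, tier)
#' pair, the mean product of the standardized property values (6 lambda
#' extra entries for the 6 dinucleotide properties, 12 lambda for the 12
#' trinucleotide tracks). Default (lambda, w) pairs follow the per-variant
#' grid-search optima: (7, 0.5), (7, 0.7), (6, 0.7), (7, 0.1), (6, 0.1)
#' for PseDNC, PC-PseDNC-General, PC-PseTNC-General, SC-PseDNC-General and
#' SC-PseTNC-General respectively.
#'
#' @param x sequences (TranscriptSet, XStringSet or character vector)
#' @param variant one of \code{"PseDNC"}, \code{"PC-PseDNC-General"},
#'   \code{"PC-PseTNC-General"}, \code{"SC-PseDNC-General"},
#'   \code{"SC-PseTNC-General"}
#' @param lambda highest correlation tier (NULL = the variant's default);
#'   every sequence must satisfy L >= lambda + 2 (dinucleotide variants)
#'   or L >= lambda + 3 (trinucleotide variants)
#' @param w sequence-order weight in [0.1, 0.9] (NULL = variant default)
#' @return numeric matrix, one row per sequence (dimension 16 + lambda,
#'   16 + lambda, 64 + lambda, 16 + 6 lambda, 64 + 12 lambda respectively)
#' @export
pseNc <- function(x, variant = "PseDNC", lambda = NULL, w = NULL) {
  defaults <- list(
    "PseDNC"            = c(lambda = 7, w = 0.5),
    "PC-PseDNC-General" = c(lambda = 7, w = 0.7),
    "PC-PseTNC-General" = c(lambda = 6, w = 0.7),
    "SC-PseDNC-General" = c(lambda = 7, w = 0.1),
    "SC-PseTNC-General" = c(lambda = 6, w = 0.1))
  variant <- match.arg(variant, names(defaults))
  if (is.null(lambda)) lambda <- defaults[[variant]][["lambda"]]
  if (is.null(w)) w <- defaults[[variant]][["w"]]
  lambda <- as.integer(lambda)
  stopifnot(lambda >= 1L, w >= 0, w <= 1)
  k <- if (grepl("TNC", variant)) 3L else 2L
  series <- startsWith(variant, "SC")
  props <- if (k == 2L) .DINUC_PROPS_STD else .TRINUC_PROPS_STD
  seqs <- .asSeq(x)
  short <- which(nchar(seqs) < lambda + k)
  if (length(short))
    stop(sprintf("sequence '%s' too short for lambda = %d (%s)",
                 if (is.null(names(seqs))) as.character(short[1L])
                 else names(seqs)[short[1L]], lambda, variant))
  oligos <- allKmers(k)
  nP <- nrow(props)
  rows <- t(vapply(seqs, function(s) {
    og <- .oligomers(s, k)
    n <- length(og)
    f <- stats::setNames(numeric(4L^k), oligos)
    tb <- table(og)
    f[names(tb)] <- as.numeric(tb)
    f <- f / n
    sv <- props[, og, drop = FALSE]            # properties x positions
    if (series) {
      theta <- numeric(nP * lambda)
      for (j in seq_len(lambda))
        theta[((j - 1L) * nP + 1L):(j * nP)] <-
          rowMeans(sv[, 1:(n - j), drop = FALSE] *
                   sv[, (1 + j):n, drop = FALSE])
      names(theta) <- paste0("tau.", rep(seq_len(lambda), each = nP), ".",
                             rep(rownames(props), lambda))
    } else {
      theta <- vapply(seq_len(lambda), function(j)
        mean(colMeans((sv[, 1:(n - j), drop = FALSE] -
                       sv[, (1 + j):n, drop = FALSE])^2)), numeric(1))
      names(theta) <- paste0("theta.", seq_len(lambda))
    }
    denom <- 1 + w * sum(theta)
    c(f / denom, w * theta / denom)
  }, numeric(4L^k + lambda * (if (series) nP else 1L))))
  rownames(rows) <- names(seqs)
  colnames(rows) <- paste0(gsub("-General", "", variant), ".", colnames(rows))
  rows
}

#' Full pseudo nucleotide composition block
#'
#' Concatenates the five variants at their default (lambda, w) settings
#' (total dimension 23 + 23 + 70 + 58 + 136 = 310).
#'
#' @param x sequences
#' @param specs optional named list overriding per-variant
#'   \code{list(lambda =, w =)}
#' @return numeric matrix, one row per sequence
#' @export
pseNcBlock <- function(x, specs = NULL) {
  variants <- c("PseDNC", "PC-PseDNC-General", "PC-PseTNC-General",
                "SC-PseDNC-General", "SC-PseTNC-General")
  do.call(cbind, lapply(variants, function(v) {
    sp <- specs[[v]]
    pseNc(x, v, lambda = sp$lambda, w = sp$w)
  }))
}
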