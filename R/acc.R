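#' Auto-cross covariance of physicochemical property tracks
#'
#' The sequence is expanded into its overlapping dinucleotides
#' (\code{kind = "DACC"}, 6 standardized base-step properties) or
#' trinucleotides (\code{kind = "TACC"}, 2 composite flexibility tracks).
#' With property track \eqn{S_{i,j}} (property i at oligomer position j, n
#' positions) and track mean \eqn{\bar S_i}, the auto covariance for each
#' property and lag is
#' \deqn{AC(i, lag) = \sum_{j=1}^{n-lag} (S_{i,j} - \bar S_i)(S_{i,j+lag} - \bar S_i) / (n - lag)}
#' and the cross covariance for each ordered property pair i1 != i2 is
#' \deqn{CC(i1, i2, lag) = \sum_{j=1}^{n-lag} (S_{i1,j} - \bar S_{i1})(S_{i2,j+lag} - \bar S_{i2}) / (n - lag).}
#' Output order is all AC blocks (property-major, lag within) followed by
#' all CC blocks (ordered pair-major, lag within); the dimension is
#' P*LAG + P*(P-1)*LAG, i.e. 36 x LAG for DACC and 4 x LAG for TACC.
#'
#' @param x sequences (TranscriptSet, XStringSet or character vector)
#' @param kind \code{"DACC"} or \code{"TACC"}
#' @param lagMax maximum lag (default 7); every sequence must have more
#'   oligomer positions than \code{lagMax}
#' @return numeric matrix, one row per sequence
#' @export
accProfile <- function(x, kind = c("DACC", "TACC"), lagMax = 7L) {
  kind <- match.arg(kind)
  lagMax <- as.integer(lagMax)
  stopifnot(lagMax >= 1L)
  k <- if (kind == "DACC") 2L else 3L
  props <- if (kind == "DACC") .DINUC_PROPS_STD
           else .TRINUC_PROPS_STD[.TACC_PROPS, , drop = FALSE]
  P <- nrow(props)
  pnames <- rownames(props)
  seqs <- .asSeq(x)
  short <- which(nchar(seqs) - k + 1L <= lagMax)
  if (length(short))
    stop(sprintf("sequence '%s' too short for lag = %d (%s)",
                 if (is.null(names(seqs))) as.character(short[1L])
                 else names(seqs)[short[1L]], lagMax, kind))
  pairs <- expand.grid(i2 = seq_len(P), i1 = seq_len(P))[, 2:1]
  pairs <- pairs[pairs$i1 != pairs$i2, , drop = FALSE]
  dim <- P * lagMax + nrow(pairs) * lagMax
  rows <- t(vapply(seqs, function(s) {
    og <- .oligomers(s, k)
    n <- length(og)
    sv <- props[, og, drop = FALSE]
    centered <- sv - rowMeans(sv)
    ac <- numeric(P * lagMax)
    for (i in seq_len(P)) for (lg in seq_len(lagMax))
      ac[(i - 1L) * lagMax + lg] <-
        sum(centered[i, 1:(n - lg)] * centered[i, (1 + lg):n]) / (n - lg)
    cc <- numeric(nrow(pairs) * lagMax)
    for (r in seq_len(nrow(pairs))) {
      i1 <- pairs$i1[r]; i2 <- pairs$i2[r]
      for (lg in seq_len(lagMax))
        cc[(r - 1L) * lagMax + lg] <-
          sum(centered[i1, 1:(n - lg)] * centered[i2, (1 + lg):n]) / (n - lg)
    }
    c(ac, cc)
  }, numeric(dim)))
  rownames(rows) <- names(seqs)
  colnames(rows) <- c(
    paste0(kind, ".ac.", rep(pnames, each = lagMax), ".", seq_len(lagMax)),
    paste0(kind, ".cc.", rep(paste0(pnames[pairs$i1], ".", pnames[pairs$i2]),
                             each = lagMax), ".", seq_len(lagMax)))
  rows
}

#' Auto-cross covariance block (DACC + TACC)
#'
#' @param x sequences
#' @param lagMax maximum lag shared by both components (default 7, so
#'   36 x 7 + 4 x 7 = 280 dimensions)
#' @return numeric matrix, one row per sequence
#' @export
accBlock <- function(x, lagMax = 7L) {
  cbind(accProfile(x, "DACC", lagMax), accProfile(x, "TACC", lagMax))
}
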