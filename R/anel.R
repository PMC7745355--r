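#' Attention network control parameters
#'
#' Defaults: embedding dimension d = 128, MLP head 128 -> 64 -> 2 with
#' ReLU, Adam with learning rate 5e-3, batch size 32, 23 epochs, dropout
#' 0.5 after the embedding layer. The best-validation-AUC parameters seen
#' during training are restored at the end; optional early stopping on
#' validation loss is available via \code{patience}.
#'
#' @param d shared embedding dimension
#' @param hidden MLP hidden width
#' @param lr Adam learning rate
#' @param batch mini-batch size
#' @param epochs training epochs
#' @param dropout drop probability after the embedding layer
#' @param patience epochs without validation-loss improvement before
#'   stopping early (Inf = train all epochs)
#' @return a list of class \code{anelControl}
#' @export
anelControl <- function(d = 128L, hidden = 64L, lr = 5e-3, batch = 32L,
                        epochs = 23L, dropout = 0.5, patience = Inf) {
  structure(list(d = as.integer(d), hidden = as.integer(hidden), lr = lr,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 dropout = dropout, patience = patience),
            class = "anelControl")
}

#' Attention layer forward pass
#'
#' Exactly the three attention equations: \eqn{h_i = ReLU(W_w f_i + b_w)},
#' \eqn{\alpha_i = \exp(h_i^T h_w) / \sum_i \exp(h_i^T h_w)} (softmax over
#' the six blocks, numerically stabilized by subtracting the max logit per
#' sample) and \eqn{F_{att} = \sum_i \alpha_i f_i}.
#'
#' @param fList list of embedding matrices (samples x d), one per block;
#'   plain vectors are treated as single-sample rows
#' @param Ww d x d attention weight matrix
#' @param bw length-d bias
#' @param hw length-d context vector
#' @return list with \code{alpha} (samples x blocks, rows sum to 1),
#'   \code{Fatt} (samples x d) and \code{h} (list of hidden matrices)
#' @export
attentionForward <- function(fList, Ww, bw, hw) {
  fList <- lapply(fList, function(f)
    if (is.null(dim(f))) matrix(f, nrow = 1L) else f)
  d <- ncol(fList[[1L]])
  if (!all(vapply(fList, ncol, integer(1)) == d))
    stop("all embeddings must share the same dimension")
  stopifnot(nrow(Ww) == d, ncol(Ww) == d, length(bw) == d, length(hw) == d)
  B <- nrow(fList[[1L]])
  h <- lapply(fList, function(f) {
    z <- f %*% t(Ww) + matrix(bw, B, d, byrow = TRUE)
    z * (z > 0)
  })
  logits <- vapply(h, function(hi) as.numeric(hi %*% hw), numeric(B))
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = B)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  alpha <- ex / rowSums(ex)
  Fatt <- matrix(0, B, d)
  for (i in seq_along(fList))
    Fatt <- Fatt + alpha[, i] * fList[[i]]
  list(alpha = alpha, Fatt = Fatt, h = h)
}

# Full forward pass. Xlist: per-block standardized input matrices.
# masks: optional dropout masks (same shapes as the embeddings).
.anelForward <- function(params, Xlist, masks = NULL) {
  B <- nrow(Xlist[[1L]])
  d <- length(params$bw)
  f <- vector("list", length(Xlist))
  for (i in seq_along(Xlist)) {
    f[[i]] <- Xlist[[i]] %*% t(params$We[[i]]) +
      matrix(params$be[[i]], B, d, byrow = TRUE)
    if (!is.null(masks)) f[[i]] <- f[[i]] * masks[[i]]
  }
  att <- attentionForward(f, params$Ww, params$bw, params$hw)
  z1pre <- att$Fatt %*% t(params$W1) +
    matrix(params$b1, B, length(params$b1), byrow = TRUE)
  z1 <- z1pre * (z1pre > 0)
  logits <- z1 %*% t(params$W2) +
    matrix(params$b2, B, length(params$b2), byrow = TRUE)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  prob <- ex / rowSums(ex)
  list(f = f, att = att, z1pre = z1pre, z1 = z1, prob = prob)
}

.anelLoss <- function(prob, y) {
  -mean(log(pmax(prob[cbind(seq_along(y), y + 1L)], 1e-12)))
}

# Analytic gradients of the mean cross-entropy loss w.r.t. all parameters.
.anelGrad <- function(params, Xlist, y, masks = NULL) {
  fw <- .anelForward(params, Xlist, masks)
  B <- length(y)
  d <- length(params$bw)
  nb <- length(Xlist)
  onehot <- matrix(0, B, 2L); onehot[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (fw$prob - onehot) / B
  g <- list()
  g$W2 <- t(dlogits) %*% fw$z1
  g$b2 <- colSums(dlogits)
  dz1 <- (dlogits %*% params$W2) * (fw$z1pre > 0)
  g$W1 <- t(dz1) %*% fw$att$Fatt
  g$b1 <- colSums(dz1)
  dFatt <- dz1 %*% params$W1
  alpha <- fw$att$alpha
  dalpha <- vapply(seq_len(nb), function(i)
    rowSums(dFatt * fw$f[[i]]), numeric(B))
  if (is.null(dim(dalpha))) dalpha <- matrix(dalpha, nrow = B)
  inner <- rowSums(alpha * dalpha)
  dlogitAtt <- alpha * (dalpha - inner)        # B x nb, softmax jacobian
  g$Ww <- matrix(0, d, d); g$bw <- numeric(d); g$hw <- numeric(d)
  g$We <- vector("list", nb); g$be <- vector("list", nb)
  for (i in seq_len(nb)) {
    hi <- fw$att$h[[i]]
    g$hw <- g$hw + colSums(hi * dlogitAtt[, i])
    dh <- outer(dlogitAtt[, i], params$hw)      # B x d
    dh <- dh * (hi > 0)
    g$Ww <- g$Ww + t(dh) %*% fw$f[[i]]
    g$bw <- g$bw + colSums(dh)
    df <- alpha[, i] * dFatt + dh %*% params$Ww
    if (!is.null(masks)) df <- df * masks[[i]]
    g$We[[i]] <- t(df) %*% Xlist[[i]]
    g$be[[i]] <- colSums(df)
  }
  list(grad = g, loss = .anelLoss(fw$prob, y))
}

.anelInit <- function(dims, control, seed) {
  set.seed(seed)
  d <- control$d; hid <- control$hidden
  kaiming <- function(nout, nin) {
    s <- sqrt(6 / nin)
    matrix(stats::runif(nout * nin, -s, s), nout, nin)
  }
  list(
    We = lapply(dims, function(p) kaiming(d, p)),
    be = lapply(dims, function(p) numeric(d)),
    Ww = kaiming(d, d), bw = numeric(d),
    hw = stats::runif(d, -1 / sqrt(d), 1 / sqrt(d)),
    W1 = kaiming(hid, d), b1 = numeric(hid),
    W2 = kaiming(2L, hid), b2 = numeric(2L))
}

# Flatten/unflatten parameter lists for Adam state bookkeeping.
.paramWalk <- function(params, fn) {
  out <- params
  out$Ww <- fn("Ww", params$Ww); out$bw <- fn("bw", params$bw)
  out$hw <- fn("hw", params$hw)
  out$W1 <- fn("W1", params$W1); out$b1 <- fn("b1", params$b1)
  out$W2 <- fn("W2", params$W2); out$b2 <- fn("b2", params$b2)
  for (i in seq_along(params$We)) {
    out$We[[i]] <- fn(paste0("We", i), params$We[[i]])
    out$be[[i]] <- fn(paste0("be", i), params$be[[i]])
  }
  out
}

.anelInputs <- function(blocks, tags, selections, scaling = NULL) {
  Xlist <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    m <- featureValues(getBlock(blocks, tags[i]))
    if (!is.null(selections) && !is.null(selections[[tags[i]]]))
      m <- m[, selections[[tags[i]]]@chosenIdx, drop = FALSE]
    if (!is.null(scaling)) {
      sc <- scaling[[tags[i]]]
      if (ncol(m) != length(sc$mean))
        stop(sprintf("block '%s': %d columns but model expects %d",
                     tags[i], ncol(m), length(sc$mean)))
      m <- sweep(sweep(m, 2L, sc$mean), 2L, sc$sd, "/")
    }
    Xlist[[i]] <- unname(m)
  }
  Xlist
}

#' Fit the attention network ensemble
#'
#' Each feature block (its mRMR-selected columns when selections are
#' given, the raw block otherwise) is standardized with training-set
#' column means and sds, embedded by a per-block affine layer into a
#' shared dimension d, passed through dropout, fused by the shared
#' softmax-attention layer, and classified by an MLP head with a 2-class
#' softmax. Training minimizes cross-entropy with Adam (mini-batches drawn
#' from the seed); after every epoch the validation AUC is recorded and
#' the best-scoring parameters are restored at the end.
#'
#' @param trainBlocks labeled \linkS4class{FeatureBlockSet}
#' @param valBlocks labeled validation set; when NULL a stratified 80/20
#'   split of \code{trainBlocks} is used
#' @param selections optional named list of \linkS4class{SelectionResult}
#' @param control an \code{\link{anelControl}}
#' @param seed integer seed for initialization, batching and dropout
#' @return an \linkS4class{ANELModel}
#' @export
anelFit <- function(trainBlocks, valBlocks = NULL, selections = NULL,
                    control = anelControl(), seed = 1L) {
  if (is.null(valBlocks)) {
    sp <- .stratifiedSplit(transcriptLabels(trainBlocks), 0.2, seed = seed)
    valBlocks <- .subsetBlocks(trainBlocks, sp$val)
    trainBlocks <- .subsetBlocks(trainBlocks, sp$train)
  }
  tags <- blockTags(trainBlocks)
  y <- transcriptLabels(trainBlocks)
  yVal <- transcriptLabels(valBlocks)
  Xraw <- .anelInputs(trainBlocks, tags, selections)
  scaling <- lapply(Xraw, function(m) {
    mu <- colMeans(m); s <- apply(m, 2L, stats::sd); s[s == 0] <- 1
    list(mean = mu, sd = s)
  })
  names(scaling) <- tags
  X <- .anelInputs(trainBlocks, tags, selections, scaling)
  Xval <- .anelInputs(valBlocks, tags, selections, scaling)
  dims <- vapply(X, ncol, integer(1))
  params <- .anelInit(dims, control, seed)
  mState <- .paramWalk(params, function(nm, v) v * 0)
  vState <- .paramWalk(params, function(nm, v) v * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(y)
  trace <- data.frame(epoch = integer(), loss = numeric(), valAUC = numeric())
  best <- list(auc = -Inf, params = params)
  bestValLoss <- Inf; stall <- 0L
  set.seed(seed + 1L)
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nBatch <- 0L
    for (start in seq(1L, n, by = control$batch)) {
      idx <- ord[start:min(start + control$batch - 1L, n)]
      Xb <- lapply(X, function(m) m[idx, , drop = FALSE])
      masks <- if (control$dropout > 0)
        lapply(seq_along(Xb), function(i)
          matrix(stats::rbinom(length(idx) * control$d, 1L,
                               1 - control$dropout) / (1 - control$dropout),
                 length(idx), control$d))
      else NULL
      gl <- .anelGrad(params, Xb, y[idx], masks)
      if (!is.finite(gl$loss))
        stop(sprintf("non-finite training loss at epoch %d", ep))
      epochLoss <- epochLoss + gl$loss; nBatch <- nBatch + 1L
      step <- step + 1L
      g <- gl$grad
      getG <- function(nm, i = NULL) if (is.null(i)) g[[nm]] else g[[nm]][[i]]
      mState <- .paramWalk(mState, function(nm, v) {
        gg <- if (startsWith(nm, "We")) g$We[[as.integer(sub("We", "", nm))]]
              else if (startsWith(nm, "be")) g$be[[as.integer(sub("be", "", nm))]]
              else g[[nm]]
        b1 * v + (1 - b1) * gg
      })
      vState <- .paramWalk(vState, function(nm, v) {
        gg <- if (startsWith(nm, "We")) g$We[[as.integer(sub("We", "", nm))]]
              else if (startsWith(nm, "be")) g$be[[as.integer(sub("be", "", nm))]]
              else g[[nm]]
        b2 * v + (1 - b2) * gg^2
      })
      lrT <- control$lr * sqrt(1 - b2^step) / (1 - b1^step)
      params <- local({
        mm <- mState; vv <- vState
        .paramWalk(params, function(nm, v) {
          mi <- if (startsWith(nm, "We")) mm$We[[as.integer(sub("We", "", nm))]]
                else if (startsWith(nm, "be")) mm$be[[as.integer(sub("be", "", nm))]]
                else mm[[nm]]
          vi <- if (startsWith(nm, "We")) vv$We[[as.integer(sub("We", "", nm))]]
                else if (startsWith(nm, "be")) vv$be[[as.integer(sub("be", "", nm))]]
                else vv[[nm]]
          v - lrT * mi / (sqrt(vi) + eps)
        })
      })
    }
    fwVal <- .anelForward(params, Xval)
    valLoss <- .anelLoss(fwVal$prob, yVal)
    valAuc <- .aucSafe(yVal, fwVal$prob[, 2L])
    trace <- rbind(trace, data.frame(epoch = ep, loss = epochLoss / nBatch,
                                     valAUC = valAuc))
    if (!is.na(valAuc) && valAuc > best$auc)
      best <- list(auc = valAuc, params = params)
    if (valLoss < bestValLoss - 1e-6) { bestValLoss <- valLoss; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= control$patience) break
  }
  methods::new("ANELModel", params = best$params, tags = tags,
               selections = if (is.null(selections)) list() else selections,
               scaling = scaling, hyper = unclass(control), trace = trace,
               seed = as.integer(seed))
}

#' @describeIn anelFit eval-mode probabilities (dropout off)
#' @param object a fitted \linkS4class{ANELModel}
#' @param blocks a \linkS4class{FeatureBlockSet}
#' @export
setMethod("predictProb", "ANELModel", function(object, blocks) {
  sel <- if (length(object@selections)) object@selections else NULL
  X <- .anelInputs(blocks, object@tags, sel, object@scaling)
  fw <- .anelForward(object@params, X)
  unname(fw$prob[, 2L])
})

#' Per-sample attention weights of a fitted model
#'
#' Exposes the softmax attention weights over the six feature families in
#' eval mode, for interpretability; each row sums to 1.
#'
#' @param model a fitted \linkS4class{ANELModel}
#' @param blocks a \linkS4class{FeatureBlockSet}
#' @return numeric matrix (samples x blocks), columns named by tag
#' @export
attentionWeights <- function(model, blocks) {
  sel <- if (length(model@selections)) model@selections else NULL
  X <- .anelInputs(blocks, model@tags, sel, model@scaling)
  fw <- .anelForward(model@params, X)
  a <- fw$att$alpha
  colnames(a) <- model@tags
  rownames(a) <- rownames(featureValues(getBlock(blocks, model@tags[1L])))
  a
}
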