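# Internal LSTM machinery for the typing-pattern backbone.
#
# Weights per layer: W (inputDim x 4H input kernel), U (H x 4H recurrent
# kernel), b (4H bias). Gate blocks in column order i, f, g, o. The forget
# bias is initialised at 1 (standard LSTM practice). Padded timesteps
# (t > validLength) carry h and c through unchanged, so the embedding
# depends only on valid rows and gradients never flow through padding.

lstmInitWeights <- function(config) {
  H <- config$unitsPerLayer
  inDims <- c(config$inputShape[2L],
              rep(H, config$nRecurrentLayers - 1L))
  lapply(inDims, function(D) {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget gate bias
    list(W = glorot(D, 4L * H), U = glorot(H, 4L * H), b = b)
  })
}

gateIdx <- function(H) list(i = 1:H, f = (H + 1L):(2L * H),
                            g = (2L * H + 1L):(3L * H),
                            o = (3L * H + 1L):(4L * H))

# X: N x T x D array; lens: valid lengths. Dropout masks (inverted dropout,
# constant across timesteps per sequence) are drawn from the current RNG
# stream when training. Returns final-step top-layer h as the embedding.
lstmForward <- function(weights, X, lens, training = FALSE,
                        recurrentDropout = 0, interLayerDropout = 0,
                        cache = FALSE) {
  N <- dim(X)[1L]
  Tmax <- min(dim(X)[2L], max(lens))
  nLayers <- length(weights)
  H <- nrow(weights[[1L]]$U)
  gi <- gateIdx(H)
  inpList <- lapply(seq_len(Tmax), function(t)
    matrix(X[, t, ], N, dim(X)[3L]))
  caches <- vector("list", nLayers)
  h <- NULL
  for (l in seq_len(nLayers)) {
    W <- weights[[l]]$W; U <- weights[[l]]$U
    bRow <- matrix(weights[[l]]$b, N, 4L * H, byrow = TRUE)
    recMask <- NULL
    if (training && recurrentDropout > 0)
      recMask <- matrix((stats::runif(N * H) >= recurrentDropout) /
                          (1 - recurrentDropout), N, H)
    h <- matrix(0, N, H); cc <- matrix(0, N, H)
    outList <- vector("list", Tmax)
    steps <- if (cache) vector("list", Tmax)
    for (t in seq_len(Tmax)) {
      m <- as.numeric(t <= lens)
      xt <- inpList[[t]]
      hUse <- if (is.null(recMask)) h else h * recMask
      z <- xt %*% W + hUse %*% U + bRow
      ig <- sigmoid(z[, gi$i]); fg <- sigmoid(z[, gi$f])
      gg <- tanh(z[, gi$g]);    og <- sigmoid(z[, gi$o])
      cNew <- fg * cc + ig * gg
      tc <- tanh(cNew)
      hNew <- og * tc
      if (cache)
        steps[[t]] <- list(xt = xt, hPrevUse = hUse, i = ig, f = fg,
                           g = gg, o = og, cPrev = cc, tc = tc, m = m)
      if (all(m == 1)) { h <- hNew; cc <- cNew }
      else { h <- m * hNew + (1 - m) * h; cc <- m * cNew + (1 - m) * cc }
      outList[[t]] <- h
    }
    interMask <- NULL
    if (l < nLayers) {
      if (training && interLayerDropout > 0) {
        interMask <- matrix((stats::runif(N * H) >= interLayerDropout) /
                              (1 - interLayerDropout), N, H)
        inpList <- lapply(outList, function(o) o * interMask)
      } else inpList <- outList
    }
    if (cache)
      caches[[l]] <- list(steps = steps, recMask = recMask,
                          interMask = interMask)
  }
  list(emb = h, caches = if (cache) caches, Tmax = Tmax, N = N)
}

# Backpropagation through time given the gradient of the loss with respect
# to the final embedding (dEmb: N x H). Returns per-layer W/U/b gradients.
lstmBackward <- function(weights, fw, dEmb) {
  nLayers <- length(weights)
  N <- fw$N; Tmax <- fw$Tmax
  H <- nrow(weights[[1L]]$U)
  grads <- vector("list", nLayers)
  dOutAbove <- NULL  # list over t: gradient wrt this layer's (dropped) output
  for (l in rev(seq_len(nLayers))) {
    cc <- fw$caches[[l]]
    W <- weights[[l]]$W; U <- weights[[l]]$U
    dW <- W * 0; dU <- U * 0; db <- numeric(length(weights[[l]]$b))
    dh <- if (l == nLayers) dEmb else matrix(0, N, H)
    dc <- matrix(0, N, H)
    dInp <- if (l > 1L) vector("list", Tmax)
    for (t in rev(seq_len(Tmax))) {
      s <- cc$steps[[t]]
      if (l < nLayers) {
        dUp <- dOutAbove[[t]]
        if (!is.null(cc$interMask)) dUp <- dUp * cc$interMask
        dh <- dh + dUp
      }
      m <- s$m
      dhNew <- dh * m
      dcT <- dc + dhNew * s$o * (1 - s$tc^2)
      dcEff <- dcT * m
      do <- dhNew * s$tc
      di <- dcEff * s$g
      dg <- dcEff * s$i
      df <- dcEff * s$cPrev
      dz <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do * s$o * (1 - s$o))
      dW <- dW + crossprod(s$xt, dz)
      dU <- dU + crossprod(s$hPrevUse, dz)
      db <- db + colSums(dz)
      dhPrev <- tcrossprod(dz, U)
      if (!is.null(cc$recMask)) dhPrev <- dhPrev * cc$recMask
      dh <- dhPrev + dh * (1 - m)
      dc <- dcT * (1 - m) + dcEff * s$f
      if (l > 1L) dInp[[t]] <- tcrossprod(dz, W)
    }
    grads[[l]] <- list(W = dW, U = dU, b = db)
    dOutAbove <- dInp
  }
  grads
}

# Gradient of the mean hinge triplet loss with respect to stacked embeddings
# [anchors; positives; negatives] (each B rows).
tripletEmbGrad <- function(E, B, margin, eps = 1e-8) {
  Ea <- E[seq_len(B), , drop = FALSE]
  Ep <- E[B + seq_len(B), , drop = FALSE]
  En <- E[2L * B + seq_len(B), , drop = FALSE]
  dAP <- rowDistance(Ea, Ep)
  dAN <- rowDistance(Ea, En)
  loss <- pmax(0, dAP - dAN + margin)
  act <- as.numeric(loss > 0)
  ua <- (Ea - Ep) / pmax(dAP, eps)
  va <- (Ea - En) / pmax(dAN, eps)
  dA <- act * (ua - va) / B
  dP <- act * (-ua) / B
  dN <- act * va / B
  list(dEmb = rbind(dA, dP, dN), loss = mean(loss),
       activeFrac = mean(act))
}
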