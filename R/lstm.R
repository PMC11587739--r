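#' Masked LSTM regression head
#'
#' Maps a (possibly zero-padded) sequence of 64-dimensional latent day codes
#' to a days-until-labor estimate at every step: masking excludes padded
#' steps (state and loss are untouched wherever the mask is 0, so padding of
#' any length, before or after the content, cannot change the outputs of
#' valid steps), then an LSTM with 128 tanh units, layer normalization, a
#' 128-unit linear dense layer and a scalar output head. Because the
#' recurrence is causal, the estimate emitted after consuming days
#' 1..(k-1) depends only on those days.
#'
#' @name lstm
NULL

#' LSTM configuration defaults
#'
#' @param latentDim input code length per day.
#' @param lstmUnits LSTM hidden units.
#' @param denseUnits units of the linear dense layer before the output.
#' @param lr,epochs Adam learning rate and training epochs.
#' @return config list.
#' @export
lstmConfig <- function(latentDim = 64L, lstmUnits = 128L, denseUnits = 128L,
                       lr = 3e-3, epochs = 150L) {
  list(latentDim = as.integer(latentDim), lstmUnits = as.integer(lstmUnits),
       denseUnits = as.integer(denseUnits), lr = lr,
       epochs = as.integer(epochs))
}

#' Build an untrained masked LSTM
#'
#' @param config an [lstmConfig()].
#' @param seed RNG seed.
#' @return list with `params` and `config`.
#' @export
buildLstm <- function(config = lstmConfig(), seed = 1L) {
  set.seed(seed)
  D <- config$latentDim; H <- config$lstmUnits; M <- config$denseUnits
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1          # forget-gate bias
  p <- list(
    Wx = glorot(c(D, 4L * H), D, H), Wh = glorot(c(H, 4L * H), H, H),
    b = b,
    lnG = rep(1, H), lnB = numeric(H),
    W1 = glorot(c(H, M), H, M), b1 = numeric(M),
    W2 = glorot(c(M, 1L), M, 1L), b2 = numeric(1L))
  list(params = p, config = config)
}

#' Total trainable parameter count of the LSTM stage
#' @param lstm a [buildLstm()] result.
#' @export
lstmParameterCount <- function(lstm) {
  sum(vapply(lstm$params, length, integer(1)))
}

#' @noRd
lstmForward <- function(params, X, mask, keepCache = FALSE) {
  d <- dim(X); N <- d[1]; Tt <- d[2]; D <- d[3]
  H <- length(params$lnG)
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  Hs <- array(0, c(N, Tt, H))
  steps <- if (keepCache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    Xt <- matrix(X[, t, ], N, D)
    Z <- Xt %*% params$Wx + h %*% params$Wh + rep(params$b, each = N)
    i <- sigm(Z[, 1:H, drop = FALSE])
    f <- sigm(Z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigm(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    cNew <- f * cc + i * g
    tanhC <- tanh(cNew)
    hNew <- o * tanhC
    m <- mask[, t]
    if (keepCache)
      steps[[t]] <- list(Xt = Xt, hPrev = h, cPrev = cc, i = i, f = f,
                         o = o, g = g, tanhC = tanhC, m = m)
    cc <- m * cNew + (1 - m) * cc
    h <- m * hNew + (1 - m) * h
    Hs[, t, ] <- h
  }
  Hmat <- matrix(Hs, N * Tt, H)
  ln <- layernormForward(Hmat, params$lnG, params$lnB)
  A1 <- ln$out %*% params$W1 + rep(params$b1, each = N * Tt)
  Yh <- A1 %*% params$W2 + rep(params$b2, each = N * Tt)
  Yhat <- matrix(Yh, N, Tt)
  list(Yhat = Yhat, Hs = Hs,
       cache = if (keepCache) list(steps = steps, ln = ln, Hmat = Hmat,
                                   A1 = A1, N = N, Tt = Tt, H = H) else NULL)
}

#' @noRd
lstmBackward <- function(params, fw, X, dYhat) {
  ca <- fw$cache
  N <- ca$N; Tt <- ca$Tt; H <- ca$H
  D <- dim(X)[3]
  dYm <- matrix(dYhat, N * Tt, 1L)
  g <- list()
  g$W2 <- crossprod(ca$A1, dYm); g$b2 <- colSums(dYm)
  dA1 <- dYm %*% t(params$W2)
  g$W1 <- crossprod(ca$ln$out, dA1); g$b1 <- colSums(dA1)
  dLn <- dA1 %*% t(params$W1)
  lb <- layernormBackward(dLn, ca$ln, params$lnG)
  g$lnG <- lb$dg; g$lnB <- lb$db
  dHs <- array(lb$dX, c(N, Tt, H))
  g$Wx <- params$Wx * 0; g$Wh <- params$Wh * 0; g$b <- params$b * 0
  dh <- matrix(0, N, H); dc <- matrix(0, N, H)
  dX <- array(0, dim(X))
  for (t in rev(seq_len(Tt))) {
    s <- ca$steps[[t]]
    dhTot <- dh + matrix(dHs[, t, ], N, H)
    m <- s$m
    dhNew <- dhTot * m
    dhPrev <- dhTot * (1 - m)
    dcNew <- dc * m
    dcPrev <- dc * (1 - m)
    do <- dhNew * s$tanhC
    dC <- dcNew + dhNew * s$o * (1 - s$tanhC^2)
    df <- dC * s$cPrev
    di <- dC * s$g
    dg <- dC * s$i
    dcPrev <- dcPrev + dC * s$f
    dZ <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                do * s$o * (1 - s$o), dg * (1 - s$g^2))
    g$Wx <- g$Wx + crossprod(s$Xt, dZ)
    g$Wh <- g$Wh + crossprod(s$hPrev, dZ)
    g$b <- g$b + colSums(dZ)
    dX[, t, ] <- dZ %*% t(params$Wx)
    dh <- dhPrev + dZ %*% t(params$Wh)
    dc <- dcPrev
  }
  g$dX <- dX
  g
}

#' Train the LSTM stage on latent day sequences
#'
#' Sequence-to-sequence training: the output head is applied to the hidden
#' state after every consumed day, giving the prediction for the following
#' day, and the mean absolute error over all valid steps is minimized. This
#' is equivalent to predicting once per prefix (the recurrence is causal)
#' at a fraction of the cost.
#'
#' @param X array (participants, maxDays, latentDim), zero-padded.
#' @param Y matrix (participants, maxDays) of true days-until-labor targets.
#' @param mask matrix (participants, maxDays), 1 = valid step.
#' @param config an [lstmConfig()].
#' @param seed RNG seed.
#' @param verbose print per-epoch loss.
#' @return list with `params`, `config`, `history`.
#' @export
trainLstm <- function(X, Y, mask, config = lstmConfig(), seed = 1L,
                      verbose = FALSE) {
  net <- buildLstm(config, seed = mixSeed(seed, 3L))
  params <- net$params
  st <- adamInit(params)
  nValid <- sum(mask)
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fw <- lstmForward(params, X, mask, keepCache = TRUE)
    res <- (fw$Yhat - Y) * mask
    if (any(!is.finite(res)))
      stop("LSTM training diverged (non-finite loss at epoch ", ep, ")")
    loss <- sum(abs(res)) / nValid
    hist[ep] <- loss
    dY <- sign(res) * mask / nValid
    gr <- lstmBackward(params, fw, X, dY)
    gr$dX <- NULL
    up <- adamUpdate(params, gr, st, lr = config$lr)
    params <- up$params; st <- up$state
    if (verbose && ep %% 10 == 0)
      message(sprintf("LSTM epoch %d MAE %.3f", ep, loss))
  }
  list(params = params, config = config, history = hist)
}

#' Predict with a trained LSTM on padded latent sequences
#'
#' @param lstm trained LSTM list.
#' @param X array (N, maxDays, latentDim).
#' @param mask matrix (N, maxDays).
#' @return matrix (N, maxDays) of predictions (only valid steps meaningful).
#' @export
lstmPredict <- function(lstm, X, mask) {
  lstmForward(lstm$params, X, mask)$Yhat
}
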