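#' Convolutional autoencoder for daily temperature vectors
#'
#' The encoder passes a 288-slot day vector through three blocks of 1-D
#' convolution (kernel width 5, ReLU) plus stride-2 max pooling
#' (288 -> 144 -> 72 -> 36), flattens, and projects to a 64-dimensional
#' latent code. The decoder mirrors the encoder with x2 up-sampling in place
#' of pooling and reconstructs the 288 slots; training minimizes the mean
#' absolute reconstruction error in deg C.
#'
#' @name autoencoder
NULL

#' Autoencoder configuration defaults
#'
#' @param inputLen day vector length (288 five-minute slots).
#' @param kernel convolution kernel width (odd).
#' @param filters channel counts of the three encoder blocks.
#' @param latentDim latent code length.
#' @param lr,epochs,batchSize,valFraction,patience Adam learning rate,
#'   training epochs, minibatch size, held-out fraction used for the
#'   reconstruction-error report and early stopping patience.
#' @return config list.
#' @export
aeConfig <- function(inputLen = 288L, kernel = 5L, filters = c(64L, 32L, 16L),
                     latentDim = 64L, lr = 1e-3, epochs = 30L,
                     batchSize = 64L, valFraction = 0.1, patience = 10L) {
  cfg <- list(inputLen = as.integer(inputLen), kernel = as.integer(kernel),
              filters = as.integer(filters), latentDim = as.integer(latentDim),
              lr = lr, epochs = as.integer(epochs),
              batchSize = as.integer(batchSize), valFraction = valFraction,
              patience = as.integer(patience))
  if (cfg$inputLen %% 8L != 0L)
    stop("input length must be divisible by 8 so the decoder reconstructs ",
         "the original length exactly")
  if (cfg$kernel %% 2L != 1L) stop("kernel width must be odd")
  if (length(cfg$filters) != 3L) stop("exactly three convolutional blocks")
  cfg
}

#' Build an untrained autoencoder
#'
#' @param config an [aeConfig()].
#' @param seed RNG seed for the weight initialization.
#' @return list with `params` (flat named list of weight arrays) and
#'   `config`.
#' @export
buildAutoencoder <- function(config = aeConfig(), seed = 1L) {
  set.seed(seed)
  K <- config$kernel; f <- config$filters
  L3 <- config$inputLen %/% 8L
  flat <- L3 * f[3]
  p <- list(
    Wc1 = glorot(c(K, 1L, f[1]), K, f[1]), bc1 = numeric(f[1]),
    Wc2 = glorot(c(K, f[1], f[2]), K * f[1], f[2]), bc2 = numeric(f[2]),
    Wc3 = glorot(c(K, f[2], f[3]), K * f[2], f[3]), bc3 = numeric(f[3]),
    Wz = glorot(c(flat, config$latentDim), flat, config$latentDim),
    bz = numeric(config$latentDim),
    Wg = glorot(c(config$latentDim, flat), config$latentDim, flat),
    bg = numeric(flat),
    Wd1 = glorot(c(K, f[3], f[2]), K * f[3], f[2]), bd1 = numeric(f[2]),
    Wd2 = glorot(c(K, f[2], f[1]), K * f[2], f[1]), bd2 = numeric(f[1]),
    Wd3 = glorot(c(K, f[1], 1L), K * f[1], 1L), bd3 = numeric(1L))
  list(params = p, config = config)
}

#' Total trainable parameter count of an autoencoder
#' @param ae a [buildAutoencoder()] result.
#' @export
aeParameterCount <- function(ae) {
  sum(vapply(ae$params, length, integer(1)))
}

#' @noRd
aeForwardFull <- function(params, X, config) {
  N <- nrow(X); L <- ncol(X)
  A0 <- array(X, c(N, L, 1L))
  c1 <- convForward(A0, params$Wc1, params$bc1); r1 <- relu(c1$out)
  p1 <- poolForward(r1)
  c2 <- convForward(p1$out, params$Wc2, params$bc2); r2 <- relu(c2$out)
  p2 <- poolForward(r2)
  c3 <- convForward(p2$out, params$Wc3, params$bc3); r3 <- relu(c3$out)
  p3 <- poolForward(r3)
  dflat <- dim(p3$out)
  Fm <- matrix(p3$out, N, dflat[2] * dflat[3])
  Z <- Fm %*% params$Wz + rep(params$bz, each = N)
  G <- Z %*% params$Wg + rep(params$bg, each = N)
  A <- array(G, c(N, dflat[2], dflat[3]))
  u1 <- upsampleForward(A)
  d1 <- convForward(u1, params$Wd1, params$bd1); rd1 <- relu(d1$out)
  u2 <- upsampleForward(rd1)
  d2 <- convForward(u2, params$Wd2, params$bd2); rd2 <- relu(d2$out)
  u3 <- upsampleForward(rd2)
  d3 <- convForward(u3, params$Wd3, params$bd3)
  Y <- matrix(d3$out, N, L)
  list(Y = Y, Z = Z,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, p3 = p3, Fm = Fm, Z = Z, A = A,
                    u1 = u1, d1 = d1, rd1 = rd1, u2 = u2, d2 = d2,
                    rd2 = rd2, u3 = u3, d3 = d3, dflat = dflat))
}

#' Encode day vectors to latent codes
#'
#' @param ae trained (or untrained) autoencoder list.
#' @param X matrix of day vectors (rows = days, 288 columns), centered.
#' @return matrix rows = days, `latentDim` columns.
#' @export
aeEncode <- function(ae, X) {
  params <- ae$params
  N <- nrow(X)
  A0 <- array(X, c(N, ncol(X), 1L))
  a <- poolForward(relu(convForward(A0, params$Wc1, params$bc1)$out))$out
  a <- poolForward(relu(convForward(a, params$Wc2, params$bc2)$out))$out
  a <- poolForward(relu(convForward(a, params$Wc3, params$bc3)$out))$out
  matrix(a, N, dim(a)[2] * dim(a)[3]) %*% params$Wz + rep(params$bz, each = N)
}

#' Reconstruct day vectors through the autoencoder
#'
#' @param ae autoencoder list.
#' @param X matrix of day vectors.
#' @return matrix of reconstructions, same shape as `X`.
#' @export
aeReconstruct <- function(ae, X) {
  aeForwardFull(ae$params, X, ae$config)$Y
}

#' @noRd
aeBackward <- function(params, fw, X, dY) {
  ca <- fw$cache
  N <- nrow(X)
  g <- list()
  dd3 <- array(dY, c(N, ncol(X), 1L))
  bk <- convBackward(dd3, ca$d3, params$Wd3)
  g$Wd3 <- bk$dW; g$bd3 <- bk$db
  du3 <- upsampleBackward(bk$dX)
  drd2 <- du3 * (ca$d2$out > 0)
  bk <- convBackward(drd2, ca$d2, params$Wd2)
  g$Wd2 <- bk$dW; g$bd2 <- bk$db
  du2 <- upsampleBackward(bk$dX)
  drd1 <- du2 * (ca$d1$out > 0)
  bk <- convBackward(drd1, ca$d1, params$Wd1)
  g$Wd1 <- bk$dW; g$bd1 <- bk$db
  dA <- upsampleBackward(bk$dX)
  dG <- matrix(dA, N, ca$dflat[2] * ca$dflat[3])
  g$Wg <- crossprod(fw$Z, dG); g$bg <- colSums(dG)
  dZ <- dG %*% t(params$Wg)
  g$Wz <- crossprod(ca$Fm, dZ); g$bz <- colSums(dZ)
  dFm <- dZ %*% t(params$Wz)
  dp3 <- array(dFm, ca$dflat)
  dr3 <- poolBackward(dp3, ca$p3) * (ca$c3$out > 0)
  bk <- convBackward(dr3, ca$c3, params$Wc3)
  g$Wc3 <- bk$dW; g$bc3 <- bk$db
  dr2 <- poolBackward(bk$dX, ca$p2) * (ca$c2$out > 0)
  bk <- convBackward(dr2, ca$c2, params$Wc2)
  g$Wc2 <- bk$dW; g$bc2 <- bk$db
  dr1 <- poolBackward(bk$dX, ca$p1) * (ca$c1$out > 0)
  bk <- convBackward(dr1, ca$c1, params$Wc1)
  g$Wc1 <- bk$dW; g$bc1 <- bk$db
  g
}

#' Train the autoencoder on independent day vectors
#'
#' Days from all participants are treated as independent observations. A
#' seeded fraction is held out; training minimizes reconstruction MAE with
#' Adam and reports the held-out MAE in deg C (centering is a shift, so the
#' error scale is unchanged).
#'
#' @param X matrix of centered day vectors (rows = days, 288 columns).
#' @param config an [aeConfig()].
#' @param seed RNG seed (initialization, split, minibatch order).
#' @param verbose print per-epoch losses.
#' @return list with `params`, `config`, `reconMAE` (held-out, deg C) and
#'   `history` (per-epoch train/validation MAE).
#' @export
trainAutoencoder <- function(X, config = aeConfig(), seed = 1L,
                             verbose = FALSE) {
  if (nrow(X) < 20L) stop("need at least 20 day vectors to train")
  ae <- buildAutoencoder(config, seed = mixSeed(seed, 1L))
  params <- ae$params
  set.seed(mixSeed(seed, 2L))
  n <- nrow(X)
  nVal <- max(1L, round(config$valFraction * n))
  valIdx <- sample.int(n, nVal)
  Xtr <- X[-valIdx, , drop = FALSE]
  Xval <- X[valIdx, , drop = FALSE]
  st <- adamInit(params)
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best <- Inf; bestParams <- params; wait <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(Xtr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    trLoss <- 0
    for (bi in batches) {
      Xb <- Xtr[bi, , drop = FALSE]
      fw <- aeForwardFull(params, Xb, config)
      res <- fw$Y - Xb
      if (any(!is.finite(res))) stop("autoencoder training diverged ",
                                     "(non-finite loss at epoch ", ep, ")")
      trLoss <- trLoss + sum(abs(res))
      dY <- sign(res) / length(res)
      gr <- aeBackward(params, fw, Xb, dY)
      up <- adamUpdate(params, gr, st, lr = config$lr)
      params <- up$params; st <- up$state
    }
    valMAE <- mean(abs(aeForwardFull(params, Xval, config)$Y - Xval))
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train = trLoss / length(Xtr),
                                   val = valMAE))
    if (verbose) message(sprintf("AE epoch %d train %.4f val %.4f",
                                 ep, trLoss / length(Xtr), valMAE))
    if (valMAE < best - 1e-6) {
      best <- valMAE; bestParams <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = bestParams, config = config, reconMAE = best, history = hist)
}
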