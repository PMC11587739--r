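#' Minimal neural-network primitives
#'
#' Batched 1-D convolution, max-pooling, up-sampling, dense layers, layer
#' normalization and an Adam optimizer, implemented as plain matrix algebra
#' on arrays shaped (batch, length, channels). These primitives back the
#' convolutional autoencoder and the masked LSTM; every backward pass is
#' verified against numerical differentiation in the test suite.
#'
#' @name nn-core
#' @keywords internal
NULL

#' Glorot-uniform weight initialization
#' @noRd
glorot <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dims)
}

relu <- function(x) pmax(x, 0)

sigm <- function(x) 1 / (1 + exp(-x))

#' Same-padding 1-D convolution, batched via im2col
#'
#' @param X array (N, L, Cin).
#' @param W array (K, Cin, Cout), K odd.
#' @param b numeric length Cout.
#' @return list(out = (N, L, Cout) array, P = patch matrix for backprop).
#' @noRd
convForward <- function(X, W, b) {
  d <- dim(X); N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (K - 1L) %/% 2L
  Xp <- array(0, c(N, L + 2L * pad, Cin))
  Xp[, pad + seq_len(L), ] <- X
  P <- matrix(0, N * L, K * Cin)
  for (k in seq_len(K))
    P[, (k - 1L) * Cin + seq_len(Cin)] <-
      matrix(Xp[, k:(k + L - 1L), , drop = FALSE], N * L, Cin)
  Wm <- matrix(aperm(W, c(2, 1, 3)), K * Cin, Cout)
  Y <- P %*% Wm
  Y <- Y + rep(b, each = N * L)
  list(out = array(Y, c(N, L, Cout)), P = P,
       dims = c(N = N, L = L, Cin = Cin, K = K, Cout = Cout, pad = pad))
}

#' @noRd
convBackward <- function(dY, cache, W) {
  dm <- cache$dims
  N <- dm[["N"]]; L <- dm[["L"]]; Cin <- dm[["Cin"]]
  K <- dm[["K"]]; Cout <- dm[["Cout"]]; pad <- dm[["pad"]]
  dYm <- matrix(dY, N * L, Cout)
  Wm <- matrix(aperm(W, c(2, 1, 3)), K * Cin, Cout)
  dP <- dYm %*% t(Wm)
  dWm <- crossprod(cache$P, dYm)
  dW <- aperm(array(dWm, c(Cin, K, Cout)), c(2, 1, 3))
  db <- colSums(dYm)
  dXp <- array(0, c(N, L + 2L * pad, Cin))
  for (k in seq_len(K))
    dXp[, k:(k + L - 1L), ] <- dXp[, k:(k + L - 1L), , drop = FALSE] +
      array(dP[, (k - 1L) * Cin + seq_len(Cin)], c(N, L, Cin))
  list(dX = dXp[, pad + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

#' Length-2, stride-2 max pooling along the length axis
#' @noRd
poolForward <- function(X) {
  L <- dim(X)[2]
  X1 <- X[, seq(1L, L, 2L), , drop = FALSE]
  X2 <- X[, seq(2L, L, 2L), , drop = FALSE]
  m <- X1 >= X2
  list(out = pmax(X1, X2), m = m, L = L)
}

#' @noRd
poolBackward <- function(dY, cache) {
  d <- dim(dY)
  dX <- array(0, c(d[1], cache$L, d[3]))
  dX[, seq(1L, cache$L, 2L), ] <- dY * cache$m
  dX[, seq(2L, cache$L, 2L), ] <- dY * !cache$m
  dX
}

#' Nearest-neighbour x2 up-sampling along the length axis
#' @noRd
upsampleForward <- function(X) {
  d <- dim(X)
  Y <- array(0, c(d[1], 2L * d[2], d[3]))
  Y[, seq(1L, 2L * d[2], 2L), ] <- X
  Y[, seq(2L, 2L * d[2], 2L), ] <- X
  Y
}

#' @noRd
upsampleBackward <- function(dY) {
  L2 <- dim(dY)[2]
  dY[, seq(1L, L2, 2L), , drop = FALSE] + dY[, seq(2L, L2, 2L), , drop = FALSE]
}

#' Adam optimizer state for a flat named list of parameter arrays
#' @noRd
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

#' One Adam update; returns list(params, state)
#' @noRd
adamUpdate <- function(params, grads, st, lr = 1e-3,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

#' Layer normalization over the feature axis of a matrix (rows = samples)
#' @noRd
layernormForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = sweep(xhat * rep(g, each = nrow(X)), 2, b, "+"),
       xhat = xhat, istd = istd)
}

#' @noRd
layernormBackward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = dg, db = db)
}
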