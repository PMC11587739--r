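#' End-to-end days-until-labor model
#'
#' Staged training of the full model: the convolutional autoencoder is
#' trained first on all training day vectors treated independently, then
#' frozen; day sequences are encoded to latent codes and the masked LSTM is
#' trained on them with true days-until-labor targets. Inputs are deg C day
#' vectors centered by the per-participant mean over the training period.
#'
#' @name labormodel
NULL

#' Model configuration defaults
#'
#' @param ae an [aeConfig()].
#' @param lstm an [lstmConfig()].
#' @param aeMaxDays cap on the number of day vectors used for autoencoder
#'   training (a seeded subsample keeps training affordable; the latent
#'   encoder still encodes every day).
#' @return nested config list.
#' @export
laborModelConfig <- function(ae = aeConfig(), lstm = lstmConfig(),
                             aeMaxDays = 400L) {
  list(ae = ae, lstm = lstm, aeMaxDays = as.integer(aeMaxDays),
       latentDim = ae$latentDim, lstmUnits = lstm$lstmUnits)
}

#' @noRd
centerOf <- function(dm) mean(tempMatrix(dm))

#' Build padded latent sequence arrays for a set of participants
#' @noRd
buildSequences <- function(ae, days, laborDays, centers) {
  ids <- names(days)
  n <- length(ids)
  lens <- vapply(days, ncol, integer(1))
  Tmax <- max(lens)
  D <- ae$config$latentDim
  X <- array(0, c(n, Tmax, D))
  Y <- matrix(0, n, Tmax)
  mask <- matrix(0, n, Tmax)
  kMat <- matrix(NA_integer_, n, Tmax)
  for (j in seq_len(n)) {
    id <- ids[j]
    dm <- days[[id]]
    Z <- aeEncode(ae, t(tempMatrix(dm)) - centers[[id]])
    X[j, seq_len(lens[j]), ] <- Z
    gd <- gestationalDays(dm)
    k <- gd + 1L                       # prediction day after consuming gd
    kMat[j, seq_len(lens[j])] <- k
    if (!is.null(laborDays))
      Y[j, seq_len(lens[j])] <- laborDays[[id]] - k
    mask[j, seq_len(lens[j])] <- 1
  }
  list(X = X, Y = Y, mask = mask, k = kMat, ids = ids, lens = lens)
}

#' Train the autoencoder + LSTM labor model
#'
#' @param days named list of interpolated [DayMatrix-class] objects, one per
#'   training participant (all with known spontaneous labor onset).
#' @param laborDays named numeric vector of labor-onset gestational days
#'   (may be fractional), names matching `days`.
#' @param config a [laborModelConfig()].
#' @param seed training seed; fixed seed gives identical weights.
#' @param verbose print training progress.
#' @return a [LaborModel-class].
#' @export
trainLaborModel <- function(days, laborDays, config = laborModelConfig(),
                            seed = 1L, verbose = FALSE) {
  if (!length(days)) stop("no training participants")
  missing <- setdiff(names(days), names(laborDays))
  if (length(missing))
    stop("training participants lack a labor date: ",
         paste(missing, collapse = ", "))
  centers <- vapply(days, centerOf, numeric(1))
  Xdays <- do.call(rbind, lapply(names(days), function(id)
    t(tempMatrix(days[[id]])) - centers[[id]]))
  set.seed(mixSeed(seed, 11L))
  if (nrow(Xdays) > config$aeMaxDays)
    Xdays <- Xdays[sample.int(nrow(Xdays), config$aeMaxDays), , drop = FALSE]
  ae <- trainAutoencoder(Xdays, config$ae, seed = seed, verbose = verbose)
  seqs <- buildSequences(ae, days, laborDays, centers)
  lstm <- trainLstm(seqs$X, seqs$Y, seqs$mask, config$lstm, seed = seed,
                    verbose = verbose)
  new("LaborModel", ae = ae, lstm = lstm,
      config = list(ae = ae$config, lstm = lstm$config,
                    latentDim = ae$config$latentDim,
                    lstmUnits = lstm$config$lstmUnits),
      centers = centers, seed = as.integer(seed),
      reconMAE = ae$reconMAE,
      history = list(ae = ae$history, lstm = lstm$history))
}

#' Predict days until labor for one participant
#'
#' Produces one prediction per day of available data: the estimate for
#' gestational day k uses only days strictly before k. The signed error
#' convention is e = y - yhat (negative when labor is predicted later than
#' it occurs).
#'
#' @param model a [LaborModel-class].
#' @param dm interpolated [DayMatrix-class] for the participant.
#' @param laborDay true labor-onset gestational day (NA if unknown); used
#'   only to fill the `y` and `e` bookkeeping columns.
#' @param center centering constant (deg C); defaults to the participant's
#'   own mean over the available days.
#' @return prediction trace data.frame: participant_id, k, y, y_hat, e.
#' @export
predictDaysToLabor <- function(model, dm, laborDay = NA_real_,
                               center = NULL) {
  if (ncol(dm) < 1L) stop("participant has no day vectors")
  if (anyNA(tempMatrix(dm))) stop("day vectors contain missing values; ",
                                  "run interpolateGaps() first")
  if (is.null(center)) center <- centerOf(dm)
  Z <- aeEncode(model@ae, t(tempMatrix(dm)) - center)
  X <- array(Z, c(1L, nrow(Z), ncol(Z)))
  mask <- matrix(1, 1L, nrow(Z))
  yhat <- lstmPredict(model@lstm, X, mask)[1L, ]
  k <- gestationalDays(dm) + 1L
  y <- if (is.na(laborDay)) rep(NA_real_, length(k)) else laborDay - k
  data.frame(participant_id = participantId(dm), k = k, y = y,
             y_hat = yhat, e = y - yhat)
}

#' Predict traces for a set of participants
#'
#' @param model a [LaborModel-class].
#' @param days named list of [DayMatrix-class].
#' @param laborDays named numeric of labor gestational days (NA allowed).
#' @return combined trace data.frame.
#' @export
predictCohort <- function(model, days, laborDays = NULL) {
  do.call(rbind, lapply(names(days), function(id) {
    ld <- if (is.null(laborDays) || is.na(laborDays[id] %||% NA))
      NA_real_ else laborDays[[id]]
    predictDaysToLabor(model, days[[id]], laborDay = ld)
  }))
}
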