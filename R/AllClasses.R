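#' @import methods
#' @importFrom stats approx density dnorm fft kruskal.test pnorm quantile
#'   rbinom rexp rlnorm rnorm rpois runif sd shapiro.test friedman.test
#'   setNames median cor var
#' @importFrom utils head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom data.table fread fwrite rbindlist
#' @importFrom jsonlite write_json
#' @importFrom zoo rollapply zoo
NULL

#' Cohort simulation configuration
#'
#' Holds every tunable of the synthetic-cohort generator: group sizes, the
#' labor gestational-age (GA) distribution, the thermal signal model
#' (baseline, slow gestational trend, 24-h circadian sinusoid with linear
#' amplitude damping over the final 10 days, a linear pre-labor drop over the
#' final 7 days for spontaneous labors, a constant level offset for
#' non-spontaneous groups), wear/non-wear gap structure, and the hormone
#' panel model. Units are degrees Celsius, days and minutes throughout.
#'
#' @slot nSpontaneous,nInduced,nCesarean group sizes.
#' @slot laborGaMean,laborGaSd,laborGaRange spontaneous labor GA distribution
#'   (days); draws are normal, truncated to `laborGaRange`.
#' @slot laborGaMeanNonspont,laborGaSdNonspont,laborGaRangeNonspont same for
#'   induced/cesarean delivery day.
#' @slot gaStart first simulated gestational day.
#' @slot baselineMean,baselineSd per-participant baseline temperature (deg C).
#' @slot trendSlope slow gestational warming trend (deg C per day).
#' @slot circadianAmplitude 24-h sinusoid amplitude (deg C).
#' @slot circadianDampingRate fractional amplitude loss per day over the
#'   final 10 days (spontaneous only); 0.1 means the amplitude reaches zero
#'   at labor onset.
#' @slot acrophaseHour local clock hour of the circadian peak.
#' @slot prelaborDrop total linear temperature decline (deg C) over the final
#'   7 days before spontaneous labor.
#' @slot groupOffset induced-minus-spontaneous mean level difference (deg C).
#' @slot noiseSd white measurement noise (deg C).
#' @slot nonwearGapRate expected non-wear gaps per day (Poisson).
#' @slot nonwearGapLenMean mean non-wear gap length (minutes, exponential).
#' @slot missingMinuteRate probability a wear minute is missing outright
#'   (dead battery / transmission loss).
#' @slot hormoneCV coefficient of variation of the multiplicative log-normal
#'   hormone noise.
#' @slot apgDecline fractional decline of alpha-pregnanediol across the 10
#'   pre-labor days (spontaneous).
#' @slot estrogenDecline fractional decline of estrogens across the window.
#' @slot e3ApgRatioEffect multiplicative elevation of the spontaneous
#'   E3:alpha-pregnanediol ratio relative to induced.
#' @slot hormoneMissingRate probability a sampling day is missed.
#' @slot inducedIntrinsicDelay if finite, induced participants carry an
#'   interrupted spontaneous trajectory whose intrinsic labor day lies this
#'   many days (exponential mean) after the induction date.
#' @slot seed master seed.
#' @export
setClass("CohortConfig", representation(
  nSpontaneous = "integer", nInduced = "integer", nCesarean = "integer",
  laborGaMean = "numeric", laborGaSd = "numeric", laborGaRange = "numeric",
  laborGaMeanNonspont = "numeric", laborGaSdNonspont = "numeric",
  laborGaRangeNonspont = "numeric",
  gaStart = "numeric",
  baselineMean = "numeric", baselineSd = "numeric", trendSlope = "numeric",
  circadianAmplitude = "numeric", circadianDampingRate = "numeric",
  acrophaseHour = "numeric", prelaborDrop = "numeric", groupOffset = "numeric",
  noiseSd = "numeric",
  nonwearGapRate = "numeric", nonwearGapLenMean = "numeric",
  missingMinuteRate = "numeric",
  hormoneCV = "numeric", apgDecline = "numeric", estrogenDecline = "numeric",
  e3ApgRatioEffect = "numeric", hormoneMissingRate = "numeric",
  inducedIntrinsicDelay = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (any(c(object@nSpontaneous, object@nInduced, object@nCesarean) < 0L))
    msg <- c(msg, "group counts must be >= 0")
  if (object@laborGaSd < 0 || object@laborGaSdNonspont < 0)
    msg <- c(msg, "labor GA sd must be >= 0")
  if (object@circadianAmplitude < 0 || object@noiseSd < 0 ||
      object@baselineSd < 0)
    msg <- c(msg, "amplitudes and noise must be >= 0")
  if (object@gaStart >= min(object@laborGaRange[1],
                            object@laborGaRangeNonspont[1]))
    msg <- c(msg, "gaStart must precede the earliest possible labor GA")
  if (length(object@laborGaRange) != 2L ||
      length(object@laborGaRangeNonspont) != 2L)
    msg <- c(msg, "labor GA ranges must have length 2")
  if (length(msg)) msg else TRUE
})

#' Per-participant daily temperature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one participant's
#' cleaned temperature days: the `"temp"` assay is a 288 x D matrix whose
#' columns are civil days starting at 10:00 local clock time and whose rows
#' are consecutive 5-minute slots. `colData` carries the gestational day
#' index (`gday`) of each column.
#'
#' @export
setClass("DayMatrix", contains = "SummarizedExperiment")

setValidity("DayMatrix", function(object) {
  msg <- character(0)
  if (nrow(object) != 288L)
    msg <- c(msg, "a DayMatrix must have exactly 288 five-minute slots")
  if (!"temp" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'temp' is required")
  gd <- object$gday
  if (is.null(gd)) msg <- c(msg, "colData column 'gday' is required")
  else if (ncol(object) > 1L && any(diff(gd) <= 0))
    msg <- c(msg, "gestational day indices must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' One simulated participant
#'
#' Bundles the clinical record (one-row data.frame), the per-minute
#' temperature series, the 5-minute wear/non-wear labels, and the daily
#' urinary hormone panel produced by the cohort generator.
#'
#' @export
setClass("SynthParticipant", representation(
  record = "data.frame", minutes = "data.frame",
  activity = "data.frame", hormones = "data.frame"
))

#' Trained days-until-labor model
#'
#' Container for a fitted convolutional autoencoder plus masked LSTM
#' regressor: the weight lists of both stages, the architecture/training
#' configuration, per-participant centering constants, the training seed and
#' the held-out reconstruction error of the autoencoder (deg C).
#'
#' @export
setClass("LaborModel", representation(
  ae = "list", lstm = "list", config = "list",
  centers = "numeric", seed = "integer", reconMAE = "numeric",
  history = "list"
))
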