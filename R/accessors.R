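#' Construct a cohort configuration
#'
#' Defaults encode the study conditions the package emulates: 54 spontaneous
#' and 37 non-spontaneous (34 induced + 3 pre-labor cesarean) analyzed
#' pregnancies; spontaneous labor GA normal with mean 279.3 d (39.9 wk), sd
#' 7.7 d (1.1 wk), truncated to 261.8--293.3 d (37.4--41.9 wk); induced /
#' cesarean delivery GA mean 276.5 d (39.5 wk), sd 8.4 d (1.2 wk), truncated
#' to 252.7--288.4 d (36.1--41.2 wk); simulation from gestational day 240; a
#' 0.44 deg C pre-labor drop over the final 7 days and a +0.44 deg C level
#' offset for non-spontaneous groups.
#'
#' @param nSpontaneous,nInduced,nCesarean group sizes.
#' @param laborGaMean,laborGaSd,laborGaRange spontaneous labor GA (days).
#' @param laborGaMeanNonspont,laborGaSdNonspont,laborGaRangeNonspont
#'   induced/cesarean delivery GA (days).
#' @param gaStart first simulated gestational day.
#' @param baselineMean,baselineSd,trendSlope baseline level model (deg C,
#'   deg C, deg C/day).
#' @param circadianAmplitude,circadianDampingRate,acrophaseHour circadian
#'   component (deg C, fraction/day over the final 10 days, clock hour).
#' @param prelaborDrop,groupOffset pre-labor decline and group offset (deg C).
#' @param noiseSd white noise sd (deg C).
#' @param nonwearGapRate,nonwearGapLenMean,missingMinuteRate gap structure.
#' @param hormoneCV,apgDecline,estrogenDecline,e3ApgRatioEffect,hormoneMissingRate
#'   hormone panel model.
#' @param inducedIntrinsicDelay see [CohortConfig-class]; `NA` (default)
#'   disables intrinsic trajectories for induced participants.
#' @param seed master seed.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nSpontaneous = 2L, nInduced = 1L, nCesarean = 0L)
#' @export
cohortConfig <- function(nSpontaneous = 54L, nInduced = 34L, nCesarean = 3L,
                         laborGaMean = 279.3, laborGaSd = 7.7,
                         laborGaRange = c(261.8, 293.3),
                         laborGaMeanNonspont = 276.5, laborGaSdNonspont = 8.4,
                         laborGaRangeNonspont = c(252.7, 288.4),
                         gaStart = 240,
                         baselineMean = 35.5, baselineSd = 0.3,
                         trendSlope = 0.01,
                         circadianAmplitude = 0.35,
                         circadianDampingRate = 0.05,
                         acrophaseHour = 3,
                         prelaborDrop = 0.44, groupOffset = 0.44,
                         noiseSd = 0.25,
                         nonwearGapRate = 1, nonwearGapLenMean = 60,
                         missingMinuteRate = 0.02,
                         hormoneCV = 0.12, apgDecline = 0.4,
                         estrogenDecline = 0.15, e3ApgRatioEffect = 2,
                         hormoneMissingRate = 0.1,
                         inducedIntrinsicDelay = NA_real_,
                         seed = 1L) {
  new("CohortConfig",
      nSpontaneous = as.integer(nSpontaneous),
      nInduced = as.integer(nInduced), nCesarean = as.integer(nCesarean),
      laborGaMean = laborGaMean, laborGaSd = laborGaSd,
      laborGaRange = laborGaRange,
      laborGaMeanNonspont = laborGaMeanNonspont,
      laborGaSdNonspont = laborGaSdNonspont,
      laborGaRangeNonspont = laborGaRangeNonspont,
      gaStart = gaStart, baselineMean = baselineMean, baselineSd = baselineSd,
      trendSlope = trendSlope, circadianAmplitude = circadianAmplitude,
      circadianDampingRate = circadianDampingRate,
      acrophaseHour = acrophaseHour, prelaborDrop = prelaborDrop,
      groupOffset = groupOffset, noiseSd = noiseSd,
      nonwearGapRate = nonwearGapRate,
      nonwearGapLenMean = nonwearGapLenMean,
      missingMinuteRate = missingMinuteRate,
      hormoneCV = hormoneCV, apgDecline = apgDecline,
      estrogenDecline = estrogenDecline,
      e3ApgRatioEffect = e3ApgRatioEffect,
      hormoneMissingRate = hormoneMissingRate,
      inducedIntrinsicDelay = inducedIntrinsicDelay,
      seed = as.integer(seed))
}

#' Construct a DayMatrix
#'
#' @param temp 288 x D numeric matrix (5-minute slots x days, days starting
#'   at 10:00 local time); `NA` marks missing epochs.
#' @param gday integer vector of gestational day indices, one per column.
#' @param participantId participant identifier.
#' @return a [DayMatrix-class].
#' @export
DayMatrix <- function(temp, gday, participantId = "p1") {
  temp <- as.matrix(temp)
  dimnames(temp) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(temp = temp),
    colData = S4Vectors::DataFrame(gday = as.integer(gday)),
    metadata = list(participantId = participantId, dayStartClock = "10:00"))
  new("DayMatrix", se)
}

#' @describeIn DayMatrix temperature matrix accessor (288 x D).
#' @param x a `DayMatrix`.
#' @export
tempMatrix <- function(x) SummarizedExperiment::assay(x, "temp")

#' @describeIn DayMatrix gestational day indices of the columns.
#' @export
gestationalDays <- function(x) x$gday

#' @describeIn DayMatrix participant identifier.
#' @export
participantId <- function(x) S4Vectors::metadata(x)$participantId

setMethod("show", "DayMatrix", function(object) {
  cat("DayMatrix for participant", participantId(object), "\n")
  cat(" ", ncol(object), "days x 288 five-minute slots (days start 10:00)\n")
  gd <- gestationalDays(object)
  if (length(gd))
    cat("  gestational days", min(gd), "-", max(gd), "\n")
  cat("  missing epochs:", sum(is.na(tempMatrix(object))), "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:",
      object@nSpontaneous, "spontaneous /",
      object@nInduced, "induced /",
      object@nCesarean, "cesarean\n")
  cat(sprintf("  labor GA ~ N(%.1f, %.1f) d trunc [%.1f, %.1f]; start GA %d\n",
              object@laborGaMean, object@laborGaSd,
              object@laborGaRange[1], object@laborGaRange[2],
              as.integer(object@gaStart)))
  cat(sprintf("  circadian %.2f C (damping %.2f/d), drop %.2f C/7 d, offset %.2f C, noise %.2f C\n",
              object@circadianAmplitude, object@circadianDampingRate,
              object@prelaborDrop, object@groupOffset, object@noiseSd))
})

setMethod("show", "SynthParticipant", function(object) {
  r <- object@record
  cat(sprintf("SynthParticipant %s (%s): labor GA %.1f d, %d minutes, %d hormone rows\n",
              r$participant_id, r$group, r$labor_ga_days,
              nrow(object@minutes), nrow(object@hormones)))
})

setMethod("show", "LaborModel", function(object) {
  cat("LaborModel (conv autoencoder + masked LSTM)\n")
  cat(sprintf("  latent dim %d, LSTM units %d, seed %d\n",
              object@config$latentDim, object@config$lstmUnits, object@seed))
  if (length(object@reconMAE))
    cat(sprintf("  held-out reconstruction MAE: %.3f deg C\n", object@reconMAE))
})

#' @describeIn cohortConfig accessor for the master seed.
#' @param config a `CohortConfig`.
#' @export
cohortSeed <- function(config) config@seed
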