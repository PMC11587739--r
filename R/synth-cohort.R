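#' Synthetic pregnancy cohort generator
#'
#' Generates per-minute finger skin-temperature series, 5-minute wear labels,
#' clinical records and daily urinary hormone panels carrying the statistical
#' structure the downstream analysis assumes: a 24-h circadian rhythm whose
#' amplitude damps linearly over the final 10 days before spontaneous labor,
#' a linear pre-labor temperature drop over the final 7 days, a constant
#' warm offset for non-spontaneous pregnancies, white measurement noise,
#' non-wear gaps, and 10-day hormone trajectories with declining
#' alpha-pregnanediol and an elevated E3:alpha-pregnanediol ratio in
#' spontaneous labors.
#'
#' @name synthCohort
NULL

.HORMONE_BASE <- c(E1 = 40, E2 = 5, E3 = 1500, aPg = 1000, bPg = 150,
                   cortisol = 60, melatonin = 30)

.T0 <- function() as.POSIXct("2023-01-01 10:00:00", tz = "UTC")

#' Deterministic temperature signal (no noise, no gaps)
#'
#' The noiseless sum of the generator's components for a vector of times:
#' baseline + gestational trend + damped circadian sinusoid + pre-labor drop
#' + group offset. Exposed so the composition is inspectable; the generator
#' adds noise and gaps on top of this.
#'
#' @param tmin numeric vector of minutes since the series start.
#' @param config a [CohortConfig-class].
#' @param laborGa labor (or intrinsic labor) gestational age, days.
#' @param baseline participant baseline temperature, deg C.
#' @param group one of `"spontaneous"`, `"induced"`, `"cesarean"`.
#' @param signatureGa gestational day the pre-labor signature is keyed to
#'   (defaults to `laborGa`; differs for interrupted induced trajectories).
#' @return numeric vector of temperatures, deg C.
#' @export
temperatureSignal <- function(tmin, config, laborGa, baseline,
                              group = "spontaneous",
                              signatureGa = laborGa) {
  g <- config@gaStart + tmin / 1440          # continuous gestational day
  d <- signatureGa - g                       # days until (intrinsic) labor
  hasSignature <- group == "spontaneous" || !is.na(config@inducedIntrinsicDelay)
  if (group == "cesarean") hasSignature <- FALSE
  damp <- rep(1, length(tmin))
  drop <- rep(0, length(tmin))
  if (hasSignature) {
    damp <- pmax(0, pmin(1, 1 - config@circadianDampingRate * (10 - d)))
    drop <- -config@prelaborDrop * pmax(0, pmin(1, (7 - d) / 7))
  }
  clockHour <- ((tmin / 60) + 10) %% 24      # series starts at 10:00
  circ <- config@circadianAmplitude * damp *
    cos(2 * pi * (clockHour - config@acrophaseHour) / 24)
  offset <- if (group == "spontaneous") 0 else config@groupOffset
  baseline + config@trendSlope * (g - config@gaStart) + circ + drop + offset
}

#' Generate one synthetic participant
#'
#' @param config a [CohortConfig-class].
#' @param group `"spontaneous"`, `"induced"` or `"cesarean"`.
#' @param seed integer seed for this participant's RNG stream.
#' @param id participant identifier.
#' @return a [SynthParticipant-class].
#' @export
generateParticipant <- function(config, group, seed, id = "p1") {
  group <- as.character(group)
  if (!group %in% c("spontaneous", "induced", "cesarean"))
    stop("unknown labor group label: ", group)
  set.seed(seed)
  spont <- group == "spontaneous"
  laborGa <- if (spont)
    rtruncnorm(1, config@laborGaMean, config@laborGaSd,
               config@laborGaRange[1], config@laborGaRange[2])
  else
    rtruncnorm(1, config@laborGaMeanNonspont, config@laborGaSdNonspont,
               config@laborGaRangeNonspont[1], config@laborGaRangeNonspont[2])
  signatureGa <- laborGa
  if (group == "induced" && !is.na(config@inducedIntrinsicDelay))
    signatureGa <- laborGa + rexp(1, 1 / config@inducedIntrinsicDelay)
  baseline <- rnorm(1, config@baselineMean, config@baselineSd)

  nMin <- floor((laborGa - config@gaStart) * 1440)
  tmin <- seq_len(nMin) - 1
  temp <- temperatureSignal(tmin, config, laborGa, baseline, group,
                            signatureGa)
  if (config@noiseSd > 0) temp <- temp + rnorm(nMin, 0, config@noiseSd)

  # non-wear gaps: Poisson count per day, exponential lengths, aligned to
  # 5-min epochs; the ring keeps recording (ambient-contaminated values)
  nDays <- ceiling(nMin / 1440)
  nonwear <- logical(nMin)
  if (config@nonwearGapRate > 0) {
    for (day in seq_len(nDays) - 1) {
      for (gp in seq_len(rpois(1, config@nonwearGapRate))) {
        startEp <- day * 288 + sample.int(288, 1) - 1
        lenEp <- max(1, ceiling(rexp(1, 1 / config@nonwearGapLenMean) / 5))
        idx <- (startEp * 5 + 1):min(nMin, (startEp + lenEp) * 5)
        idx <- idx[idx >= 1 & idx <= nMin]
        nonwear[idx] <- TRUE
      }
    }
    temp[nonwear] <- rnorm(sum(nonwear), 28, 0.5)
  }
  if (config@missingMinuteRate > 0) {
    miss <- runif(nMin) < config@missingMinuteRate
    temp[miss] <- NA_real_
  }

  t0 <- .T0()
  minutes <- data.frame(participant_id = id,
                        time = t0 + tmin * 60, temp_c = temp)
  epStart <- t0 + seq(0, by = 300, length.out = ceiling(nMin / 5))
  epNonwear <- colSums(matrix(c(nonwear, rep(FALSE, length(epStart) * 5 - nMin)),
                              nrow = 5)) > 0
  activity <- data.frame(participant_id = id, epoch_start = epStart,
                         label = ifelse(epNonwear, "nonwear", "wear"))
  record <- data.frame(participant_id = id, group = group,
                       labor_ga_days = laborGa, edd_ga_days = 280,
                       ga_start = config@gaStart,
                       baseline_c = baseline,
                       intrinsic_ga_days = signatureGa)
  hormones <- generateHormonePanel(record, config, mixSeed(seed, 7919L))
  new("SynthParticipant", record = record, minutes = minutes,
      activity = activity, hormones = hormones)
}

#' Generate a full synthetic cohort
#'
#' Participant seeds are derived deterministically from the configured master
#' seed and the participant index, so generation order cannot change results.
#'
#' @param config a [CohortConfig-class].
#' @return list of [SynthParticipant-class] objects (spontaneous first, then
#'   induced, then cesarean).
#' @export
generateCohort <- function(config) {
  validObject(config)
  groups <- c(rep("spontaneous", config@nSpontaneous),
              rep("induced", config@nInduced),
              rep("cesarean", config@nCesarean))
  if (!length(groups)) return(list())
  prefix <- c(spontaneous = "S", induced = "I", cesarean = "C")
  counts <- c(spontaneous = 0L, induced = 0L, cesarean = 0L)
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    counts[g] <- counts[g] + 1L
    id <- sprintf("%s%02d", prefix[[g]], counts[[g]])
    out[[i]] <- generateParticipant(config, g, mixSeed(config@seed, i), id)
  }
  out
}

#' Cohort clinical records as one data.frame
#' @param cohort list of [SynthParticipant-class].
#' @export
cohortRecords <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) p@record))
}

#' Generate a 10-day urinary hormone panel
#'
#' Daily values for E1, E2, E3, alpha- and beta-pregnanediol, cortisol and
#' melatonin over the 10 days preceding labor (days -10..-1). Spontaneous
#' panels carry a linear alpha-pregnanediol decline and a configured
#' elevation of the E3:alpha-pregnanediol ratio relative to induced
#' pregnancies; noise is multiplicative log-normal; whole sampling days may
#' be missing at the configured rate.
#'
#' @param record one-row participant record (needs `group`, `participant_id`).
#' @param config a [CohortConfig-class].
#' @param seed RNG seed.
#' @param days integer vector of days-to-labor to sample (default -10..-1);
#'   pass a single day to emulate the one-sample panels real cohorts contain.
#' @return long data.frame (participant_id, day_to_labor, analyte, value).
#' @export
generateHormonePanel <- function(record, config, seed, days = -10:-1) {
  stopifnot(!is.null(record$group))
  set.seed(seed)
  spont <- record$group == "spontaneous"
  u <- (days + 10) / 9                     # 0 at day -10, 1 at day -1
  rows <- list()
  sdlog <- sqrt(log(1 + config@hormoneCV^2))
  for (an in names(.HORMONE_BASE)) {
    mult <- rep(1, length(days))
    if (spont) {
      if (an == "aPg") mult <- 1 - config@apgDecline * u
      if (an %in% c("E1", "E2", "E3")) mult <- 1 - config@estrogenDecline * u
      if (an == "bPg") mult <- 1 - 0.5 * config@apgDecline * u
    } else if (an == "E3") {
      mult <- mult / config@e3ApgRatioEffect
    }
    val <- .HORMONE_BASE[[an]] * mult
    if (config@hormoneCV > 0)
      val <- val * rlnorm(length(days), -sdlog^2 / 2, sdlog)
    rows[[an]] <- data.frame(participant_id = record$participant_id,
                             day_to_labor = days, analyte = an, value = val)
  }
  panel <- do.call(rbind, rows)
  if (config@hormoneMissingRate > 0 && length(days) > 1) {
    missDays <- days[runif(length(days)) < config@hormoneMissingRate]
    if (length(missDays) == length(days)) missDays <- missDays[-1]
    panel <- panel[!panel$day_to_labor %in% missDays, ]
  }
  rownames(panel) <- NULL
  panel
}
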