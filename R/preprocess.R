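#' Preprocessing: minute temperatures to clean daily 288-vectors
#'
#' Implements the cleaning pipeline: 5-minute averaging, label-based
#' non-wear removal, segmentation into 24-h civil days starting at 10:00,
#' linear interpolation of gaps, data-density computation, and the cohort
#' inclusion filters (at least 21 contiguous days of pre-labor data and at
#' least 75% data density).
#'
#' @name preprocess
NULL

.PLAUSIBLE_RANGE <- c(20, 45)

#' Average a per-minute series over 5-minute epochs
#'
#' Readings outside the plausible skin range (20--45 deg C) are treated as
#' missing before averaging; an epoch with no available minutes is missing.
#' The output tiles the full span of the input with a complete epoch grid.
#'
#' @param minutes data.frame with columns `time` (POSIXct, strictly
#'   increasing) and `temp_c`.
#' @return data.frame with columns `epoch` (POSIXct, 5-min grid) and `temp_c`.
#' @export
aggregate5min <- function(minutes) {
  if (!nrow(minutes)) stop("empty minute series")
  tt <- minutes$time
  if (any(diff(as.numeric(tt)) <= 0))
    stop("timestamps must be strictly increasing")
  temp <- minutes$temp_c
  temp[!is.na(temp) &
       (temp < .PLAUSIBLE_RANGE[1] | temp > .PLAUSIBLE_RANGE[2])] <- NA_real_
  ep <- floorTime(tt, 5)
  grid <- seq(ep[1], ep[length(ep)], by = 300)
  idx <- match(as.numeric(ep), as.numeric(grid))
  sums <- tapply(ifelse(is.na(temp), 0, temp), idx, sum)
  cnts <- tapply(!is.na(temp), idx, sum)
  val <- rep(NA_real_, length(grid))
  pos <- as.integer(names(sums))
  ok <- cnts > 0
  val[pos[ok]] <- sums[ok] / cnts[ok]
  data.frame(epoch = grid, temp_c = as.numeric(val))
}

#' Remove non-wear epochs using device activity labels
#'
#' @param epochs data.frame from [aggregate5min()].
#' @param labels data.frame with `epoch_start` (POSIXct) and `label`
#'   (`"wear"`/`"nonwear"`); must cover every epoch of the series.
#' @return the series with non-wear epochs set to missing.
#' @export
removeNonwear <- function(epochs, labels) {
  m <- match(as.numeric(epochs$epoch), as.numeric(labels$epoch_start))
  if (anyNA(m))
    stop("activity labels do not tile the series span: ",
         sum(is.na(m)), " unlabeled epochs")
  epochs$temp_c[labels$label[m] == "nonwear"] <- NA_real_
  epochs
}

#' Segment a 5-minute series into 10:00-anchored civil days
#'
#' A day spans [10:00, next 10:00) local clock time and holds 288 slots;
#' partial leading and trailing days are dropped. Slot membership is decided
#' by each epoch's clock label, so civil days remain aligned across daylight
#' saving transitions.
#'
#' @param epochs data.frame from [aggregate5min()] / [removeNonwear()].
#' @param gaAtStart gestational day index of the first (possibly partial)
#'   10:00-anchored day in the series.
#' @param participantId identifier stored in the result.
#' @return a [DayMatrix-class] (possibly with missing entries).
#' @export
segmentDays <- function(epochs, gaAtStart, participantId = "p1") {
  tt <- epochs$epoch
  dayStart <- floorDayStart(tt)
  cm <- clockMinutes(tt)
  slot <- ((cm - 600L) %% 1440L) %/% 5L + 1L
  spanStart <- tt[1]
  spanEnd <- tt[length(tt)] + 300
  starts <- sort(unique(dayStart))
  complete <- as.numeric(starts) >= as.numeric(spanStart) &
    (as.numeric(starts) + 86400) <= as.numeric(spanEnd)
  starts <- starts[complete]
  if (!length(starts))
    return(DayMatrix(matrix(numeric(0), 288, 0), integer(0), participantId))
  firstBoundary <- floorDayStart(spanStart)
  gday <- gaAtStart +
    as.integer(round((as.numeric(starts) - as.numeric(firstBoundary)) / 86400))
  mat <- matrix(NA_real_, 288, length(starts))
  col <- match(as.numeric(dayStart), as.numeric(starts))
  keep <- !is.na(col)
  mat[cbind(slot[keep], col[keep])] <- epochs$temp_c[keep]
  DayMatrix(mat, gday, participantId)
}

#' Linearly interpolate missing epochs in a DayMatrix
#'
#' Missing runs are filled by straight lines between the flanking observed
#' values, across day boundaries within the participant; leading/trailing
#' missing stretches are filled flat from the nearest observation.
#'
#' @param dm a [DayMatrix-class].
#' @return a [DayMatrix-class] with no missing entries.
#' @export
interpolateGaps <- function(dm) {
  mat <- tempMatrix(dm)
  v <- as.vector(mat)              # chronological: slots within day, days
  obs <- which(!is.na(v))
  if (!length(obs)) stop("participant has no observed temperature data")
  if (length(obs) < length(v)) {
    v <- approx(obs, v[obs], xout = seq_along(v), rule = 2)$y
  }
  DayMatrix(matrix(v, nrow = 288), gestationalDays(dm), participantId(dm))
}

#' Data density of a 5-minute series
#'
#' Fraction of expected 5-minute epochs actually observed across the series
#' span, computed before any interpolation.
#'
#' @param epochs data.frame from [aggregate5min()] (full epoch grid).
#' @return a fraction in [0, 1].
#' @export
computeDensity <- function(epochs) {
  if (nrow(epochs) < 288) stop("series span must be at least one day")
  mean(!is.na(epochs$temp_c))
}

#' Longest run of consecutive usable days
#'
#' A day counts as covered when at least `dayFloor` of its 288 epochs are
#' observed; the statistic is the longest run of consecutive covered days.
#'
#' @param dm a raw (pre-interpolation) [DayMatrix-class].
#' @param dayFloor per-day observed fraction required (default 0.5).
#' @return integer day count.
#' @export
contiguousDays <- function(dm, dayFloor = 0.5) {
  if (!ncol(dm)) return(0L)
  covered <- colMeans(!is.na(tempMatrix(dm))) >= dayFloor
  r <- rle(covered)
  runs <- r$lengths[r$values]
  if (!length(runs)) 0L else as.integer(max(runs))
}

#' Apply the cohort inclusion filters
#'
#' Participants are excluded when they have fewer than `minContiguous`
#' contiguous days of pre-labor temperature data or less than `minDensity`
#' data density; both thresholds are strict ("less than" excludes), so a
#' participant at exactly 21 days and 0.75 density is included.
#'
#' @param dm raw [DayMatrix-class] (before interpolation).
#' @param density data density from [computeDensity()].
#' @param minContiguous,minDensity inclusion thresholds.
#' @return one-row data.frame: participant_id, included, contiguous_days,
#'   density, reason.
#' @export
applyInclusionFilters <- function(dm, density, minContiguous = 21,
                                  minDensity = 0.75) {
  cd <- contiguousDays(dm)
  reasons <- character(0)
  if (cd < minContiguous) reasons <- c(reasons, "contiguity")
  if (density < minDensity) reasons <- c(reasons, "density")
  data.frame(participant_id = participantId(dm),
             included = !length(reasons),
             contiguous_days = cd, density = density,
             reason = if (length(reasons)) paste(reasons, collapse = "+")
                      else "included")
}

#' Run the full preprocessing pipeline for one participant
#'
#' Order follows the cleaning pipeline: 5-min averaging, non-wear removal,
#' density computation (pre-interpolation), day segmentation, inclusion
#' filters, then gap interpolation.
#'
#' @param minutes per-minute data.frame (`time`, `temp_c`).
#' @param activity label data.frame (`epoch_start`, `label`).
#' @param gaAtStart gestational day index at the series start.
#' @param participantId identifier.
#' @param minContiguous,minDensity inclusion thresholds.
#' @return list with elements `days` (interpolated [DayMatrix-class]),
#'   `rawDays`, `report` (inclusion report row) and `density`.
#' @export
preprocessParticipant <- function(minutes, activity, gaAtStart,
                                  participantId = "p1",
                                  minContiguous = 21, minDensity = 0.75) {
  ep <- aggregate5min(minutes)
  ep <- removeNonwear(ep, activity)
  density <- computeDensity(ep)
  raw <- segmentDays(ep, gaAtStart, participantId)
  report <- applyInclusionFilters(raw, density, minContiguous, minDensity)
  list(days = interpolateGaps(raw), rawDays = raw,
       report = report, density = density)
}

#' Preprocess a whole synthetic cohort
#'
#' @param cohort list of [SynthParticipant-class].
#' @param ... passed to [preprocessParticipant()].
#' @return list with `days` (named list of interpolated [DayMatrix-class]
#'   for included participants), `reports` (all inclusion reports) and
#'   `records` (clinical records of included participants).
#' @export
preprocessCohort <- function(cohort, ...) {
  reports <- list(); days <- list(); recs <- list()
  for (p in cohort) {
    id <- p@record$participant_id
    res <- preprocessParticipant(p@minutes, p@activity,
                                 floor(p@record$ga_start), id, ...)
    reports[[id]] <- res$report
    if (res$report$included) {
      days[[id]] <- res$days
      recs[[id]] <- p@record
    }
  }
  list(days = days, reports = do.call(rbind, reports),
       records = if (length(recs)) do.call(rbind, recs) else NULL)
}
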