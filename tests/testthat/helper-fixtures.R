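# Shared fixtures and independent oracles. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# a clean config: no noise, no gaps, fixed baseline; late gaStart values
# (used to keep test series short) shift the labor-GA truncation up so the
# config invariant gaStart < min labor GA still holds
cleanConfig <- function(..., gaStart = 240) {
  args <- list(...)
  if (gaStart >= 252) {
    if (is.null(args$laborGaRange)) {
      args$laborGaRange <- c(gaStart + 8, 295)
      args$laborGaMean <- gaStart + 12
    }
    if (is.null(args$laborGaRangeNonspont)) {
      args$laborGaRangeNonspont <- c(gaStart + 8, 295)
      args$laborGaMeanNonspont <- gaStart + 12
    }
  }
  do.call(cohortConfig,
          c(list(nSpontaneous = 1L, nInduced = 0L, nCesarean = 0L,
                 noiseSd = 0, nonwearGapRate = 0, missingMinuteRate = 0,
                 baselineSd = 0, hormoneCV = 0, hormoneMissingRate = 0,
                 gaStart = gaStart), args))
}

# small day matrices with a known sinusoid, for model-stage tests
sinusoidDays <- function(nDays, amplitude = 0.5, noise = 0, seed = 1) {
  set.seed(seed)
  hours <- (seq_len(288) - 1) / 12
  X <- t(sapply(seq_len(nDays), function(i)
    amplitude * cos(2 * pi * (hours - 3) / 24) + rnorm(288, 0, noise)))
  X
}

# brute-force 5-min epoch means (independent of aggregate5min internals)
oracleEpochMeans <- function(time, temp) {
  ep <- as.POSIXct(floor(as.numeric(time) / 300) * 300,
                   origin = "1970-01-01", tz = "UTC")
  grid <- seq(min(ep), max(ep), by = 300)
  sapply(grid, function(g) {
    v <- temp[ep == g]
    v <- v[!is.na(v) & v >= 20 & v <= 45]
    if (length(v)) mean(v) else NA_real_
  })
}

# independent piecewise-linear interpolation with flat edges
oracleInterp <- function(v) {
  obs <- which(!is.na(v))
  out <- v
  for (i in seq_along(v)) {
    if (!is.na(v[i])) next
    lo <- obs[obs < i]; hi <- obs[obs > i]
    if (!length(lo)) out[i] <- v[hi[1]]
    else if (!length(hi)) out[i] <- v[lo[length(lo)]]
    else {
      a <- lo[length(lo)]; b <- hi[1]
      out[i] <- v[a] + (v[b] - v[a]) * (i - a) / (b - a)
    }
  }
  out
}

# Kruskal-Wallis statistic from the rank formula, with tie correction
oracleKW <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(g) length(g) * (mean(g) - (N + 1) / 2)^2))
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# signed Mann-Kendall S by direct double loop
oracleS <- function(x) {
  s <- 0
  for (i in seq_along(x)) for (j in seq_along(x)) if (j > i)
    s <- s + sign(x[j] - x[i])
  s
}

# small cached preprocessed cohort used by several files
tinyPreppedCohort <- function(nSpont = 6L, nInd = 0L, seed = 33L, ...) {
  cfg <- cohortConfig(nSpontaneous = nSpont, nInduced = nInd, nCesarean = 0L,
                      noiseSd = 0.05, nonwearGapRate = 0.2,
                      missingMinuteRate = 0.01, gaStart = 248,
                      circadianAmplitude = 0.5, circadianDampingRate = 0.09,
                      seed = seed, ...)
  prep <- preprocessCohort(generateCohort(cfg))
  prep$laborDays <- setNames(prep$records$labor_ga_days,
                             prep$records$participant_id)
  prep
}

# a tiny, quickly trainable model configuration
tinyModelConfig <- function() {
  laborModelConfig(
    ae = aeConfig(filters = c(8L, 8L, 8L), latentDim = 8L, epochs = 4L,
                  batchSize = 64L),
    lstm = lstmConfig(latentDim = 8L, lstmUnits = 16L, denseUnits = 16L,
                      epochs = 40L),
    aeMaxDays = 120L)
}
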