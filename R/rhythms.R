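#' Circadian rhythm analysis via the generalized Morse wavelet
#'
#' Continuous wavelet transform with the generalized Morse mother wavelet
#' (shape parameters beta and gamma), band-averaged circadian power in the
#' 23--25 h period band, 72-h smoothing, last-10-day trend classification,
#' Mann-Kendall trend tests and nonparametric group tests.
#'
#' @name rhythms
NULL

#' Wavelet analysis configuration
#'
#' @param beta,gamma Morse shape parameters (defaults 5 and 3: a low
#'   oscillation count suited to detecting transitions in biological
#'   rhythms).
#' @param periods analysis period grid in hours; the default is log-spaced
#'   at 32 voices per octave covering 2--48 h.
#' @return a list with class `"WaveletConfig"`.
#' @export
waveletConfig <- function(beta = 5, gamma = 3,
                          periods = 2^unique(c(seq(1, log2(48), by = 1 / 32),
                                               log2(48)))) {
  stopifnot(beta > 0, gamma > 0)
  if (min(periods) > 2 || max(periods) < 48)
    stop("period grid must cover at least [2, 48] h")
  structure(list(beta = beta, gamma = gamma, periods = sort(periods)),
            class = "WaveletConfig")
}

#' Generalized Morse wavelet frequency response
#'
#' Frequency-domain form a(beta,gamma) * w^beta * exp(-w^gamma) for w > 0
#' (analytic: zero for w <= 0), peak-normalized so the response equals 2 at
#' the peak frequency (beta/gamma)^(1/gamma). With this normalization a unit
#' cosine at the wavelet's center period transforms to unit magnitude.
#'
#' @param w angular frequency vector.
#' @param beta,gamma shape parameters.
#' @return numeric vector, the (real) frequency response.
#' @export
morseResponse <- function(w, beta, gamma) {
  a <- 2 * exp((beta / gamma) * (1 - log(beta / gamma)))
  out <- numeric(length(w))
  pos <- w > 0
  out[pos] <- a * exp(beta * log(w[pos]) - w[pos]^gamma)
  out
}

#' Morse continuous wavelet transform power surface
#'
#' Computed in the frequency domain: for each analysis period the series
#' spectrum is multiplied by the scaled Morse response and inverse
#' transformed; power is the squared transform magnitude.
#'
#' @param x evenly sampled temperature series (gaps already interpolated).
#' @param dtHours sampling interval in hours (1/12 for 5-min data).
#' @param config a [waveletConfig()].
#' @return list with `power` (periods x time matrix), `periods` (hours) and
#'   `timeHours`.
#' @export
morseWaveletPower <- function(x, dtHours = 1 / 12, config = waveletConfig()) {
  n <- length(x)
  if (n * dtHours < 2 * max(config$periods))
    stop("series must span at least twice the longest analysis period")
  xf <- fft(x - mean(x))
  w <- 2 * pi * (seq_len(n) - 1) / (n * dtHours)    # rad per hour
  w[w > pi / dtHours] <- w[w > pi / dtHours] - 2 * pi / dtHours
  wPeak <- (config$beta / config$gamma)^(1 / config$gamma)
  pow <- matrix(0, length(config$periods), n)
  for (j in seq_along(config$periods)) {
    s <- wPeak * config$periods[j] / (2 * pi)
    W <- fft(xf * morseResponse(s * w, config$beta, config$gamma),
             inverse = TRUE) / n
    pow[j, ] <- Mod(W)^2
  }
  list(power = pow, periods = config$periods,
       timeHours = (seq_len(n) - 1) * dtHours)
}

#' Band-averaged circadian power
#'
#' Mean wavelet power per time point over the analysis periods falling in
#' the circadian band (default 23--25 h). A squared-amplitude measure: a
#' sinusoid of amplitude A at 24 h yields band power proportional to A^2.
#'
#' @param surface output of [morseWaveletPower()].
#' @param band numeric length-2, band limits in hours.
#' @return data.frame with `timeHours` and `power`.
#' @export
circadianPower <- function(surface, band = c(23, 25)) {
  sel <- surface$periods >= band[1] & surface$periods <= band[2]
  if (!any(sel)) stop("period grid does not intersect the requested band")
  data.frame(timeHours = surface$timeHours,
             power = colMeans(surface$power[sel, , drop = FALSE]))
}

#' Centered 72-h moving average
#'
#' @param x evenly sampled series.
#' @param samplesPerDay samples per 24 h (288 for 5-min data).
#' @return smoothed series, windows truncated at the edges.
#' @export
smooth72h <- function(x, samplesPerDay = 288) {
  width <- 3 * samplesPerDay + 1          # odd, centered
  as.numeric(zoo::rollapply(zoo::zoo(x), width = width, FUN = mean,
                            partial = TRUE, align = "center"))
}

#' Classify a temperature trend over the final days
#'
#' Ordinary least-squares slope of the smoothed series over the last
#' `windowDays`; a negative slope is `"trending_down"`, otherwise
#' (including an exactly flat series) `"trending_up"`, grouping zero-slope
#' series with the no-trend/upward class.
#'
#' @param x smoothed, evenly sampled series.
#' @param samplesPerDay samples per 24 h.
#' @param windowDays trailing window length in days (default 10).
#' @param participantId identifier.
#' @return one-row data.frame: participant_id, label, slope (deg C per day).
#' @export
classifyTrend <- function(x, samplesPerDay = 288, windowDays = 10,
                          participantId = "p1") {
  need <- windowDays * samplesPerDay
  if (length(x) < need)
    stop("series does not cover the trend window (need ",
         need, " samples, have ", length(x), ")")
  y <- tail(x, need)
  tDays <- (seq_along(y) - 1) / samplesPerDay
  slope <- olsSlope(tDays, y)
  data.frame(participant_id = participantId,
             label = if (slope < 0) "trending_down" else "trending_up",
             slope = slope)
}

#' Mann-Kendall trend test
#'
#' S = sum over pairs i < j of sign(x_j - x_i); tau = S / (n(n-1)/2). For
#' small tie-free samples (n <= 10) the two-sided p-value comes from the
#' exact permutation distribution of S (computed by the inversion-count
#' recursion); otherwise from the normal approximation with tie and
#' continuity corrections.
#'
#' @param x numeric series (n >= 4).
#' @return list with `S`, `tau`, `p.value`, `varS`, `n`, `exact`.
#' @export
mannKendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("Mann-Kendall test needs at least 4 observations")
  d <- sign(outer(x, x, "-"))             # d[j, i] = sign(x_j - x_i)
  S <- sum(d[lower.tri(d)])               # pairs i < j
  ties <- table(x)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
           sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  exact <- n <= 10 && !length(ties)
  if (exact) {
    # counts of permutations by inversion number: prod_i (1 + q + .. q^{i-1})
    cnt <- 1
    for (i in seq_len(n)) {
      newcnt <- numeric(length(cnt) + i - 1)
      for (j in 0:(i - 1))
        newcnt[j + seq_along(cnt)] <- newcnt[j + seq_along(cnt)] + cnt
      cnt <- newcnt
    }
    inv <- 0:(n * (n - 1) / 2)
    Sval <- n * (n - 1) / 2 - 2 * inv
    p <- sum(cnt[abs(Sval) >= abs(S)]) / sum(cnt)
  } else {
    z <- if (S > 0) (S - 1) / sqrt(varS)
         else if (S < 0) (S + 1) / sqrt(varS) else 0
    p <- 2 * pnorm(-abs(z))
  }
  list(S = S, tau = S / (n * (n - 1) / 2),
       p.value = min(1, p), varS = varS, n = n, exact = exact)
}

#' Nonparametric group comparisons of time series
#'
#' Friedman test (nonparametric repeated-measures ANOVA) comparing the two
#' groups' mean series blocked by time point, and a Kruskal-Wallis test
#' comparing the per-participant mean levels between groups.
#'
#' @param spont,induced participant x time matrices on aligned time grids.
#' @return list with elements `friedman` and `kw` (both `htest`).
#' @export
groupTests <- function(spont, induced) {
  if (ncol(spont) != ncol(induced))
    stop("time grids are misaligned between groups")
  meanMat <- cbind(spontaneous = colMeans(spont), induced = colMeans(induced))
  fr <- friedman.test(meanMat)
  kw <- kruskal.test(list(rowMeans(spont), rowMeans(induced)))
  list(friedman = fr, kw = kw)
}
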