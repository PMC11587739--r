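#' Derive a per-stream random seed from a master seed
#'
#' Deterministic integer mixing used to give every participant (and every
#' training stage) its own reproducible RNG stream, independent of the order
#' in which participants are generated.
#'
#' @param seed master seed (integer).
#' @param index stream index (integer >= 0).
#' @return an integer in [1, 2147483562].
#' @export
mixSeed <- function(seed, index) {
  x <- as.numeric(seed) %% 2147483563
  x <- (x * 40014) %% 2147483563
  x <- (x + as.numeric(index) * 40692 + 1) %% 2147483563
  as.integer(x %% 2147483562 + 1)
}

#' Truncated normal draws by rejection
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Floor a POSIXct time to the previous boundary of `unit` minutes
#' @noRd
floorTime <- function(t, unit_min) {
  as.POSIXct(floor(as.numeric(t) / (unit_min * 60)) * unit_min * 60,
             origin = "1970-01-01", tz = attr(t, "tzone") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minutes past local midnight for a POSIXct vector
#' @noRd
clockMinutes <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour * 60L + lt$min
}

#' Floor a time to the previous 10:00 local-clock day boundary
#' @noRd
floorDayStart <- function(t, boundary_min = 600L) {
  cm <- clockMinutes(t)
  off <- (cm - boundary_min) %% 1440L
  t - off * 60 - as.POSIXlt(t)$sec
}

#' Ordinary least squares slope of y against x
#' @noRd
olsSlope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc * xc)
}
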