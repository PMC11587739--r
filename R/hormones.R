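#' Urinary hormone panel preparation and temperature-trend comparisons
#'
#' Prepares 10-day pre-labor hormone panels (drop single-day panels,
#' linearly interpolate onto the daily grid, per-analyte min-max
#' normalization) and relates alpha-pregnanediol and the
#' E3:alpha-pregnanediol ratio to labor type and temperature-trend groups.
#'
#' @name hormones
NULL

.PANEL_GRID <- -10:-1

#' Prepare a hormone panel for analysis
#'
#' Analytes observed on fewer than two days are removed; a panel with at
#' most one distinct sampling day overall is dropped (returns `NULL`).
#' Remaining analytes are linearly interpolated onto the daily grid
#' -10..-1 (flat extension at the edges) and min-max normalized to [0, 1]
#' per analyte. Observed values are preserved before normalization; the
#' interpolation never extrapolates beyond flat edge-fill.
#'
#' @param panel long data.frame (participant_id, day_to_labor, analyte,
#'   value), concentrations creatinine-normalized and non-negative.
#' @return `NULL` if dropped, else list with `raw` and `norm`: data.frames
#'   with a `day_to_labor` column plus one column per analyte, and
#'   `participant_id`.
#' @export
preparePanel <- function(panel) {
  if (any(panel$value < 0, na.rm = TRUE))
    stop("negative hormone concentrations are not allowed")
  if (length(unique(panel$day_to_labor)) <= 1) return(NULL)
  raw <- data.frame(day_to_labor = .PANEL_GRID)
  norm <- data.frame(day_to_labor = .PANEL_GRID)
  for (an in unique(panel$analyte)) {
    sub <- panel[panel$analyte == an & !is.na(panel$value), ]
    sub <- sub[order(sub$day_to_labor), ]
    if (nrow(sub) < 2) next
    y <- approx(sub$day_to_labor, sub$value, xout = .PANEL_GRID, rule = 2)$y
    raw[[an]] <- y
    rng <- range(y)
    norm[[an]] <- if (diff(rng) == 0) rep(0, length(y))
                  else (y - rng[1]) / diff(rng)
  }
  if (ncol(raw) == 1) return(NULL)
  list(participant_id = panel$participant_id[1], raw = raw, norm = norm)
}

#' Estriol to alpha-pregnanediol ratio
#'
#' Pointwise E3 / alpha-pregnanediol on raw (pre-normalization)
#' concentrations; the ratio is invariant to common multiplicative assay
#' drift applied to both analytes.
#'
#' @param prepared output of [preparePanel()].
#' @return data.frame (day_to_labor, ratio).
#' @export
e3ApgRatio <- function(prepared) {
  raw <- prepared$raw
  if (is.null(raw$E3) || is.null(raw$aPg))
    stop("panel must carry both E3 and aPg on the grid")
  if (any(raw$aPg == 0)) stop("alpha-pregnanediol is zero on the grid")
  data.frame(day_to_labor = raw$day_to_labor, ratio = raw$E3 / raw$aPg)
}

#' Compare alpha-pregnanediol by temperature trend group
#'
#' Splits prepared panels by the participant's temperature trend label,
#' reports normalized alpha-pregnanediol group means with 95% t-intervals
#' per day, and runs a Kruskal-Wallis test on per-participant medians over
#' the final week (days -7..-1).
#'
#' @param prepared list of [preparePanel()] outputs (NULLs allowed).
#' @param labels data.frame (participant_id, label) from [classifyTrend()].
#' @return list with `perDay` (day, label, mean, lo, hi, n), `medians`
#'   (participant_id, label, median_aPg) and `kw` (`htest` or NULL when a
#'   group is empty).
#' @export
compareByTrendGroup <- function(prepared, labels) {
  prepared <- Filter(Negate(is.null), prepared)
  med <- list(); rows <- list()
  for (p in prepared) {
    lab <- labels$label[match(p$participant_id, labels$participant_id)]
    if (is.na(lab)) stop("no trend label for participant ", p$participant_id)
    if (is.null(p$norm$aPg)) next
    med[[p$participant_id]] <- data.frame(
      participant_id = p$participant_id, label = lab,
      median_aPg = median(p$norm$aPg[p$norm$day_to_labor >= -7]))
    rows[[p$participant_id]] <- data.frame(
      day_to_labor = p$norm$day_to_labor, label = lab, aPg = p$norm$aPg)
  }
  med <- do.call(rbind, med)
  long <- do.call(rbind, rows)
  perDay <- do.call(rbind, lapply(split(long, list(long$day_to_labor, long$label)),
    function(g) {
      if (!nrow(g)) return(NULL)
      n <- nrow(g); m <- mean(g$aPg)
      hw <- if (n > 1) stats::qt(0.975, n - 1) * sd(g$aPg) / sqrt(n) else 0
      data.frame(day_to_labor = g$day_to_labor[1], label = g$label[1],
                 mean = m, lo = m - hw, hi = m + hw, n = n)
    }))
  rownames(perDay) <- NULL
  groups <- unique(med$label)
  kw <- if (length(groups) >= 2) kruskal.test(med$median_aPg, factor(med$label))
        else NULL
  list(perDay = perDay, medians = med, kw = kw)
}
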