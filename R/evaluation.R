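#' Model evaluation: subject-wise CV, calibrated windows, ablations
#'
#' Subject-wise k-fold cross-validation, signed-error curves over
#' days-to-labor and gestational age, kernel-density calibration of
#' prediction windows at coverage probabilities P, clinical TP/FP/FN window
#' accounting, the traditional due-date baseline, held-out evaluation of
#' induced/cesarean participants, and input-perturbation ablations.
#'
#' @name evaluation
NULL

#' Subject-wise k-fold assignment
#'
#' Random, seeded partition of participants into k disjoint folds whose
#' sizes differ by at most one; a participant's data is wholly in one fold.
#'
#' @param ids participant identifiers.
#' @param k fold count (default 9).
#' @param seed RNG seed.
#' @return data.frame (participant_id, fold).
#' @export
kfoldSplit <- function(ids, k = 9L, seed = 1L) {
  n <- length(ids)
  if (k > n) stop("k must not exceed the participant count")
  set.seed(seed)
  perm <- sample(sort(ids))
  data.frame(participant_id = perm,
             fold = rep(seq_len(k), length.out = n),
             stringsAsFactors = FALSE)
}

#' Subject-wise cross-validation of the labor model
#'
#' For every fold, trains on the remaining folds and predicts the held-out
#' participants, so each trace is produced by a model that never saw that
#' participant.
#'
#' @param days named list of interpolated [DayMatrix-class].
#' @param laborDays named numeric labor gestational days.
#' @param folds data.frame from [kfoldSplit()].
#' @param config a [laborModelConfig()].
#' @param seed training seed (per-fold seeds derived from it).
#' @param verbose progress messages.
#' @return list with `traces` (combined data.frame, plus a `fold` column)
#'   and `models` (per-fold [LaborModel-class]).
#' @export
crossValidate <- function(days, laborDays, folds, config = laborModelConfig(),
                          seed = 1L, verbose = FALSE) {
  traces <- list(); models <- list()
  for (f in sort(unique(folds$fold))) {
    testIds <- folds$participant_id[folds$fold == f]
    trainIds <- setdiff(names(days), testIds)
    if (verbose) message("fold ", f, ": training on ", length(trainIds),
                         " participants")
    model <- trainLaborModel(days[trainIds], laborDays,
                             config, seed = mixSeed(seed, 100L + f))
    tr <- predictCohort(model, days[testIds], laborDays)
    tr$fold <- f
    traces[[as.character(f)]] <- tr
    models[[as.character(f)]] <- model
  }
  list(traces = do.call(rbind, traces), models = models)
}

#' Signed-error and MAE curves
#'
#' Aggregates traces across participants at each value of the chosen axis:
#' mean signed error (e = y - yhat; negative when labor is predicted later
#' than actual), MAE, 95% t-intervals, and a Mann-Kendall trend test on the
#' mean curve.
#'
#' @param traces trace data.frame.
#' @param axis `"days_to_labor"` (rounded y) or `"gestational_age"` (k).
#' @return list with `curve` (axis, n, mean_e, lo, hi, mae) and `trend`
#'   ([mannKendall()] on the mean curve).
#' @export
errorCurves <- function(traces, axis = c("days_to_labor", "gestational_age")) {
  axis <- match.arg(axis)
  if (!nrow(traces)) stop("no traces")
  ax <- if (axis == "days_to_labor") round(traces$y) else traces$k
  sp <- split(traces$e, ax)
  curve <- do.call(rbind, lapply(names(sp), function(v) {
    e <- sp[[v]]; n <- length(e); m <- mean(e)
    hw <- if (n > 1) stats::qt(0.975, n - 1) * sd(e) / sqrt(n) else 0
    data.frame(axis = as.numeric(v), n = n, mean_e = m,
               lo = m - hw, hi = m + hw, mae = mean(abs(e)))
  }))
  curve <- curve[order(curve$axis), ]
  rownames(curve) <- NULL
  trend <- if (nrow(curve) >= 4) mannKendall(curve$mean_e) else NULL
  list(curve = curve, trend = trend, axis = axis)
}

#' Error distribution at a fixed time before labor
#'
#' Pools the cross-validated signed errors at days-to-labor T into a kernel
#' density estimate (Gaussian kernel, Silverman bandwidth) and records the
#' Shapiro-Wilk normality p-value.
#'
#' @param traces trace data.frame.
#' @param T days to labor at which errors are collected (rounded y match).
#' @return list with `T`, `errors`, `kde` (stats::density), `normality_p`.
#' @export
buildErrorDistribution <- function(traces, T) {
  e <- traces$e[round(traces$y) == T & !is.na(traces$e)]
  if (length(e) < 5) stop("need at least 5 errors at T = ", T)
  degenerate <- sd(e) == 0
  kde <- if (degenerate) NULL else density(e, bw = "nrd0")
  np <- if (degenerate || length(e) < 3) NA_real_
        else tryCatch(shapiro.test(e)$p.value, error = function(...) NA_real_)
  structure(list(T = T, errors = e, kde = kde, normality_p = np,
                 degenerate = degenerate), class = "ErrorDistribution")
}

#' @noRd
kdeQuantile <- function(kde, probs) {
  dx <- diff(kde$x[1:2])
  cdf <- c(0, cumsum((kde$y[-1] + kde$y[-length(kde$y)]) / 2) * dx)
  cdf <- cdf / cdf[length(cdf)]
  approx(cdf, kde$x, xout = probs, ties = "ordered")$y
}

#' Probability mass of an error distribution inside a window
#'
#' Trapezoid integral of the KDE between -eps1 and eps2.
#'
#' @param dist a [buildErrorDistribution()] result.
#' @param eps1,eps2 window bounds (error scale).
#' @return probability in [0, 1].
#' @export
windowMass <- function(dist, eps1, eps2) {
  kde <- dist$kde
  dx <- diff(kde$x[1:2])
  cdf <- c(0, cumsum((kde$y[-1] + kde$y[-length(kde$y)]) / 2) * dx)
  cdf <- cdf / cdf[length(cdf)]
  at <- function(v) approx(kde$x, cdf, xout = v, rule = 2, ties = "ordered")$y
  at(eps2) - at(-eps1)
}

#' Calibrated prediction window
#'
#' Equal-tailed window: each tail outside (-eps1, eps2) holds (1-P)/2 of
#' the KDE mass, so the area between the bounds is P. The window in
#' days-from-now around the predicted labor date is [W1, W2] =
#' [yhat - eps1, yhat + eps2]; the reported width is |W| = eps1 + eps2.
#'
#' @param dist an [buildErrorDistribution()] result.
#' @param yhat model prediction (days until labor) at time T.
#' @param P coverage probability in (0, 1).
#' @return one-row data.frame: T, P, eps1, eps2, W1, W2, width.
#' @export
predictionWindow <- function(dist, yhat, P) {
  if (P <= 0 || P >= 1) stop("P must lie in (0, 1)")
  if (isTRUE(dist$degenerate)) {
    eps1 <- eps2 <- 0
  } else {
    q <- kdeQuantile(dist$kde, c((1 - P) / 2, 1 - (1 - P) / 2))
    eps1 <- -q[1]; eps2 <- q[2]
  }
  data.frame(T = dist$T, P = P, eps1 = eps1, eps2 = eps2,
             W1 = yhat - eps1, W2 = yhat + eps2, width = eps1 + eps2)
}

#' Classify a window outcome
#'
#' True positive when labor falls inside the closed window; false positive
#' when labor occurs after the window (prediction too early), with
#' miss-days measured from the right edge; false negative when labor occurs
#' before the window, measured from the left edge.
#'
#' @param trueDaysToLabor actual days until labor at the prediction time.
#' @param window one-row data.frame from [predictionWindow()].
#' @param participantId identifier.
#' @return one-row data.frame: participant_id, label, miss_days.
#' @export
classifyOutcome <- function(trueDaysToLabor, window, participantId = "p1") {
  if (trueDaysToLabor > window$W2) {
    label <- "FP"; miss <- trueDaysToLabor - window$W2
  } else if (trueDaysToLabor < window$W1) {
    label <- "FN"; miss <- window$W1 - trueDaysToLabor
  } else {
    label <- "TP"; miss <- 0
  }
  data.frame(participant_id = participantId, label = label, miss_days = miss)
}

#' Window accounting across a cohort at fixed T and P
#'
#' Builds the error distribution at T from the traces, derives each
#' participant's window from their own prediction, classifies outcomes and
#' tabulates TP/FP/FN counts, percentages (one decimal) and miss-day
#' summaries.
#'
#' @param traces cross-validated trace data.frame.
#' @param T days-to-labor cross-section.
#' @param probs coverage probabilities.
#' @return list with `outcomes` (per participant x P) and `summary`
#'   (T, P, width, tp, fp, fn, tp_pct, fp_pct, fn_pct, fp_miss_mean,
#'   fp_miss_sd, fn_miss_mean, fn_miss_sd, n).
#' @export
windowReport <- function(traces, T, probs = c(0.7, 0.8, 0.9, 0.95)) {
  dist <- buildErrorDistribution(traces, T)
  at <- traces[round(traces$y) == T & !is.na(traces$e), ]
  outcomes <- list(); summ <- list()
  for (P in probs) {
    rows <- do.call(rbind, lapply(seq_len(nrow(at)), function(i) {
      w <- predictionWindow(dist, at$y_hat[i], P)
      cbind(classifyOutcome(at$y[i], w, at$participant_id[i]), P = P,
            width = w$width)
    }))
    outcomes[[as.character(P)]] <- rows
    n <- nrow(rows)
    cnt <- function(l) sum(rows$label == l)
    missStats <- function(l) {
      m <- rows$miss_days[rows$label == l]
      if (!length(m)) c(NA_real_, NA_real_)
      else c(mean(m), if (length(m) > 1) sd(m) else 0)
    }
    fpm <- missStats("FP"); fnm <- missStats("FN")
    summ[[as.character(P)]] <- data.frame(
      T = T, P = P, width = rows$width[1],
      tp = cnt("TP"), fp = cnt("FP"), fn = cnt("FN"),
      tp_pct = round(100 * cnt("TP") / n, 1),
      fp_pct = round(100 * cnt("FP") / n, 1),
      fn_pct = round(100 * cnt("FN") / n, 1),
      fp_miss_mean = fpm[1], fp_miss_sd = fpm[2],
      fn_miss_mean = fnm[1], fn_miss_sd = fnm[2], n = n)
  }
  list(outcomes = do.call(rbind, outcomes), summary = do.call(rbind, summ))
}

#' Coverage calibration of the window construction
#'
#' Draws errors at a fixed T from a known distribution, builds the KDE
#' window from one sample and measures the empirical rate at which fresh
#' errors fall inside it; a calibrated construction attains P.
#'
#' @param n simulated participants per check.
#' @param probs coverage probabilities to check.
#' @param sdE error scale of the simulated distribution.
#' @param seed RNG seed.
#' @return data.frame (P, empirical, n).
#' @export
coverageCalibration <- function(n = 1000L, probs = c(0.7, 0.8, 0.9, 0.95),
                                sdE = 2, seed = 1L) {
  set.seed(seed)
  eFit <- rnorm(n, 0, sdE)
  traces <- data.frame(participant_id = as.character(seq_len(n)),
                       y = 7, y_hat = 7 - eFit, e = eFit)
  dist <- buildErrorDistribution(traces, 7)
  eNew <- rnorm(n, 0, sdE)
  out <- lapply(probs, function(P) {
    w <- predictionWindow(dist, 0, P)   # bounds relative to prediction
    data.frame(P = P, empirical = mean(eNew >= -w$eps1 & eNew <= w$eps2),
               n = n)
  })
  do.call(rbind, out)
}

#' Traditional due-date baseline error
#'
#' @param records data.frame with `labor_ga_days` and `edd_ga_days` (280).
#' @return list with `perParticipant` (participant_id, edd_error_days) and
#'   `meanError`.
#' @export
eddBaseline <- function(records) {
  err <- abs(records$labor_ga_days - records$edd_ga_days)
  list(perParticipant = data.frame(participant_id = records$participant_id,
                                   edd_error_days = err),
       meanError = mean(err))
}

#' Evaluate the model on held-out induced/cesarean participants
#'
#' Signed-error curves against days-to-delivery, per-participant mean error
#' and SD, the late-skew report (negative mean signed error = predictions
#' fall later than the actual induction) and a Kruskal-Wallis comparison of
#' per-participant error SDs against the spontaneous traces.
#'
#' @param model a [LaborModel-class] trained on spontaneous labors only.
#' @param days named list of [DayMatrix-class] for the held-out group.
#' @param laborDays named numeric delivery gestational days.
#' @param spontTraces optional spontaneous traces for the dispersion
#'   comparison.
#' @return list with `traces`, `curves`, `perParticipant`, `meanSignedError`,
#'   `dispersionTest` (or NULL), or NULL (with a message) when empty.
#' @export
evaluateNonspontaneous <- function(model, days, laborDays,
                                   spontTraces = NULL) {
  if (!length(days)) {
    message("non-spontaneous cohort empty; stage skipped")
    return(NULL)
  }
  traces <- predictCohort(model, days, laborDays)
  per <- do.call(rbind, lapply(split(traces, traces$participant_id),
    function(g) data.frame(participant_id = g$participant_id[1],
                           mean_e = mean(g$e), sd_e = sd(g$e))))
  disp <- NULL
  if (!is.null(spontTraces)) {
    sper <- vapply(split(spontTraces$e, spontTraces$participant_id), sd,
                   numeric(1))
    disp <- kruskal.test(list(spontaneous = sper, nonspontaneous = per$sd_e))
  }
  list(traces = traces, curves = errorCurves(traces, "days_to_labor"),
       perParticipant = per, meanSignedError = mean(traces$e),
       dispersionTest = disp)
}

#' Input-perturbation ablations
#'
#' Re-runs a trained model (no retraining) on perturbed copies of the input
#' days: the named segment is flatlined (replaced by the centering value,
#' i.e. zeros on the model scale), replaced by Gaussian noise, or has
#' Gaussian noise added.
#'
#' @param model a [LaborModel-class].
#' @param days named list of interpolated [DayMatrix-class].
#' @param laborDays named numeric labor days.
#' @param mode `"flatline"`, `"replace-noise"` or `"add-noise"`.
#' @param segment `"first-10"`, `"last-5"`, `"random-10"` or `"all"`.
#' @param noiseSd Gaussian sd (deg C) for the noise modes.
#' @param seed RNG seed for noise and random segments.
#' @return trace data.frame for the perturbed inputs.
#' @export
ablate <- function(model, days, laborDays,
                   mode = c("flatline", "replace-noise", "add-noise"),
                   segment = c("first-10", "last-5", "random-10", "all"),
                   noiseSd = 0.5, seed = 1L) {
  mode <- match.arg(mode); segment <- match.arg(segment)
  set.seed(seed)
  out <- lapply(names(days), function(id) {
    dm <- days[[id]]
    center <- centerOf(dm)
    mat <- tempMatrix(dm)
    D <- ncol(mat)
    idx <- switch(segment,
      "first-10" = seq_len(min(10L, D)),
      "last-5" = seq.int(max(1L, D - 4L), D),
      "random-10" = sort(sample.int(D, min(10L, D))),
      "all" = seq_len(D))
    if (length(idx) < switch(segment, "first-10" = 10L, "last-5" = 5L,
                             "random-10" = 10L, "all" = 0L))
      warning("segment truncated to available days for ", id)
    sub <- mat[, idx, drop = FALSE]
    mat[, idx] <- switch(mode,
      "flatline" = center,
      "replace-noise" = center + rnorm(length(sub), 0, noiseSd),
      "add-noise" = sub + rnorm(length(sub), 0, noiseSd))
    dm2 <- DayMatrix(mat, gestationalDays(dm), id)
    predictDaysToLabor(model, dm2, laborDay = laborDays[[id]],
                       center = center)
  })
  do.call(rbind, out)
}
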