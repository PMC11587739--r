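test_that("subject-wise folds are disjoint, covering and balanced", {
  ids <- sprintf("P%02d", 1:54)
  f <- kfoldSplit(ids, k = 9, seed = 3)
  expect_identical(sort(unique(f$fold)), 1:9)
  expect_true(all(table(f$fold) == 6))
  expect_identical(sort(f$participant_id), sort(ids))
  expect_identical(anyDuplicated(f$participant_id), 0L)
  # order of the input must not matter under a fixed seed
  f2 <- kfoldSplit(rev(ids), k = 9, seed = 3)
  expect_identical(f[order(f$participant_id), ],
                   f2[order(f2$participant_id), ])
  # uneven splits differ by at most one; degenerate k = 1 allowed
  f3 <- kfoldSplit(ids[1:20], k = 3, seed = 1)
  expect_lte(diff(range(table(f3$fold))), 1)
  expect_identical(unique(kfoldSplit(ids, k = 1, seed = 1)$fold), 1L)
  expect_error(kfoldSplit(ids[1:3], k = 5), "exceed")
})

test_that("error curves honor the e = y - yhat sign convention", {
  tr <- data.frame(participant_id = rep(c("a", "b"), each = 10),
                   k = rep(241:250, 2), y = rep(10:1, 2))
  perfect <- transform(tr, y_hat = y, e = y - y)
  ec <- errorCurves(perfect, "days_to_labor")
  expect_true(all(ec$curve$mean_e == 0))
  biased <- transform(tr, y_hat = y + 2, e = y - (y + 2))
  ecb <- errorCurves(biased, "days_to_labor")
  expect_true(all(abs(ecb$curve$mean_e + 2) < 1e-12))
  # t-interval agrees with a bootstrap once cells are reasonably filled
  set.seed(6)
  big <- data.frame(participant_id = rep(sprintf("p%02d", 1:30), each = 5),
                    k = 1, y = rep(5:1, 30))
  big$y_hat <- big$y + rnorm(nrow(big))
  big$e <- big$y - big$y_hat
  ecn <- errorCurves(big, "days_to_labor")$curve
  for (row in c(2, 4)) {
    e <- big$e[big$y == ecn$axis[row]]
    boot <- replicate(4000, mean(sample(e, replace = TRUE)))
    bootHw <- diff(quantile(boot, c(0.025, 0.975))) / 2
    tHw <- (ecn$hi[row] - ecn$lo[row]) / 2
    expect_lt(abs(tHw - bootHw) / bootHw, 0.10)
  }
})

test_that("the error KDE is normalized and windows behave like normal quantiles", {
  set.seed(2)
  e <- rnorm(500)
  tr <- data.frame(participant_id = as.character(1:500), y = 7,
                   y_hat = 7 - e, e = e)
  d <- buildErrorDistribution(tr, 7)
  dx <- diff(d$kde$x[1:2])
  expect_equal(sum(d$kde$y) * dx, 1, tolerance = 1e-3)
  expect_true(is.finite(d$normality_p))
  w <- predictionWindow(d, 0, 0.95)
  expect_lt(abs(w$eps1 - 1.96), 0.15)
  expect_lt(abs(w$eps2 - 1.96), 0.15)
  expect_lt(abs(w$width - 2 * 1.96) / (2 * 1.96), 0.10)
  # symmetric distribution: equal tails
  expect_lt(abs(w$eps1 - w$eps2), 0.2)
  # the KDE mass inside the window equals P
  expect_equal(windowMass(d, w$eps1, w$eps2), 0.95, tolerance = 1e-3)
  # width is monotone in P
  widths <- sapply(c(0.7, 0.8, 0.9, 0.95), function(P)
    predictionWindow(d, 0, P)$width)
  expect_true(all(diff(widths) > 0))
  expect_error(predictionWindow(d, 0, 1.2), "P must")
  expect_error(buildErrorDistribution(tr[1:3, ], 7), "at least 5")
})

test_that("degenerate all-identical errors collapse the window to a point", {
  tr <- data.frame(participant_id = as.character(1:8), y = 7, y_hat = 5,
                   e = 2)
  d <- buildErrorDistribution(tr, 7)
  expect_true(d$degenerate)
  w <- predictionWindow(d, 5, 0.9)
  expect_equal(w$width, 0)
  expect_equal(w$W1, 5)
})

test_that("window outcomes use a closed interval and the printed edge semantics", {
  w <- data.frame(T = 7, P = 0.8, eps1 = 2, eps2 = 3, W1 = 5, W2 = 10,
                  width = 5)
  expect_identical(classifyOutcome(10, w)$label, "TP")   # boundary
  expect_identical(classifyOutcome(5, w)$label, "TP")
  fp <- classifyOutcome(10.6, w)
  expect_identical(fp$label, "FP")
  expect_equal(fp$miss_days, 0.6)
  fn <- classifyOutcome(4.1, w)
  expect_identical(fn$label, "FN")
  expect_equal(fn$miss_days, 0.9, tolerance = 1e-9)
})

test_that("window reports tabulate exhaustive outcomes with monotone TP", {
  set.seed(12)
  n <- 60
  e <- rnorm(n, 0, 1.5)
  tr <- data.frame(participant_id = as.character(1:n), y = 7, y_hat = 7 - e,
                   e = e)
  rep <- windowReport(tr, 7)
  s <- rep$summary
  expect_true(all(s$tp + s$fp + s$fn == n))
  expect_true(all(diff(s$tp) >= 0))
  expect_true(all(diff(s$fp) <= 0))
  expect_true(all(diff(s$fn) <= 0))
  expect_true(all(diff(s$width) >= 0))
})

test_that("window coverage is calibrated within 3 percent at n = 1000", {
  cal <- coverageCalibration(n = 1000L, seed = 4L)
  expect_true(all(abs(cal$empirical - cal$P) <= 0.03))
})

test_that("the due-date baseline is plain arithmetic", {
  recs <- data.frame(participant_id = c("a", "b", "c"),
                     labor_ga_days = c(280, 287, 273), edd_ga_days = 280)
  base <- eddBaseline(recs)
  expect_equal(base$perParticipant$edd_error_days, c(0, 7, 7))
  expect_equal(base$meanError, mean(c(0, 7, 7)))
})

test_that("cross-validation predicts every participant exactly once, subject-wise", {
  prep <- tinyPreppedCohort(nSpont = 6L, seed = 44L)
  folds <- kfoldSplit(names(prep$days), k = 2, seed = 2)
  cv <- crossValidate(prep$days, prep$laborDays, folds, tinyModelConfig(),
                      seed = 3L)
  got <- unique(cv$traces[, c("participant_id", "fold")])
  expect_identical(sort(got$participant_id), sort(names(prep$days)))
  expect_identical(anyDuplicated(got$participant_id), 0L)
  # subject-wise separation: each model's centers exclude its test ids
  for (f in unique(folds$fold)) {
    testIds <- folds$participant_id[folds$fold == f]
    expect_length(intersect(names(cv$models[[as.character(f)]]@centers),
                            testIds), 0)
  }
  # per-fold summaries at a cross-section have the mean +- sd shape
  at7 <- cv$traces[round(cv$traces$y) == 7, ]
  summ <- aggregate(e ~ fold, at7, function(x) c(mean(x), sd(x)))
  expect_identical(nrow(summ), 2L)
})

test_that("ablations degrade gracefully and add-noise with sd -> 0 is a no-op", {
  prep <- tinyPreppedCohort(nSpont = 4L, seed = 55L)
  m <- trainLaborModel(prep$days, prep$laborDays, tinyModelConfig(),
                       seed = 2L)
  base <- predictCohort(m, prep$days, prep$laborDays)
  same <- ablate(m, prep$days, prep$laborDays, "add-noise", "all",
                 noiseSd = 0, seed = 1L)
  expect_equal(base$y_hat, same$y_hat, tolerance = 1e-12)
  fl <- ablate(m, prep$days, prep$laborDays, "flatline", "all", seed = 1L)
  finalWeek <- function(tr) mean(abs(tr$e[tr$y >= 0 & tr$y <= 14]))
  expect_gt(finalWeek(fl), finalWeek(base))
  expect_warning(ablate(m, prep$days[1], prep$laborDays, "flatline",
                        "random-10", seed = 1L), NA)
})

test_that("an empty non-spontaneous cohort is skipped with a notice", {
  prep <- tinyPreppedCohort(nSpont = 4L, seed = 55L)
  m <- trainLaborModel(prep$days, prep$laborDays, tinyModelConfig(),
                       seed = 2L)
  expect_message(res <- evaluateNonspontaneous(m, list(), numeric(0)),
                 "skipped")
  expect_null(res)
})

test_that("induced participants evaluated on a spontaneous model skew late with wider dispersion", {
  prep <- tinyPreppedCohort(nSpont = 4L, nInd = 4L, seed = 66L,
                            inducedIntrinsicDelay = 10)
  spontIds <- grep("^S", names(prep$days), value = TRUE)
  indIds <- grep("^I", names(prep$days), value = TRUE)
  m <- trainLaborModel(prep$days[spontIds], prep$laborDays,
                       tinyModelConfig(), seed = 4L)
  spontTr <- predictCohort(m, prep$days[spontIds], prep$laborDays)
  res <- evaluateNonspontaneous(m, prep$days[indIds], prep$laborDays,
                                spontTraces = spontTr)
  # direction: induced predictions fall later than spontaneous ones (the
  # absolute late skew needs a fully trained model; see the validation file)
  expect_lt(res$meanSignedError, mean(spontTr$e))
  sper <- vapply(split(spontTr$e, spontTr$participant_id), sd, numeric(1))
  expect_gt(median(res$perParticipant$sd_e), median(sper))
  expect_s3_class(res$dispersionTest, "htest")
})
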