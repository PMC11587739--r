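mkMinutes <- function(start, n, temp) {
  data.frame(time = as.POSIXct(start, tz = "UTC") + 60 * (seq_len(n) - 1),
             temp_c = temp)
}

test_that("5-min averaging reproduces constants, printed means and a brute-force oracle", {
  m <- mkMinutes("2023-01-01 10:00:00", 60, rep(36.5, 60))
  ep <- aggregate5min(m)
  expect_true(all(ep$temp_c == 36.5))

  m2 <- mkMinutes("2023-01-01 10:00:00", 5, c(36.0, 36.5, 37.0, 36.5, 36.0))
  expect_equal(aggregate5min(m2)$temp_c, 36.4)

  set.seed(10)
  n <- 1000
  temp <- rnorm(n, 36, 1)
  temp[sample(n, 150)] <- NA
  temp[sample(n, 10)] <- 10      # implausible -> treated missing
  m3 <- mkMinutes("2023-01-01 09:57:00", n, temp)
  ep3 <- aggregate5min(m3)
  expect_equal(ep3$temp_c, oracleEpochMeans(m3$time, m3$temp_c))
  expect_error(aggregate5min(m3[0, ]), "empty")
})

test_that("non-wear removal blanks labeled epochs and only those", {
  m <- mkMinutes("2023-01-01 10:00:00", 1440, rnorm(1440, 36, 0.2))
  ep <- aggregate5min(m)
  labAll <- data.frame(epoch_start = ep$epoch, label = "wear")
  expect_identical(removeNonwear(ep, labAll), ep)
  labNone <- transform(labAll, label = "nonwear")
  expect_true(all(is.na(removeNonwear(ep, labNone)$temp_c)))
  set.seed(2)
  lab <- transform(labAll, label = ifelse(runif(nrow(labAll)) < 0.3,
                                          "nonwear", "wear"))
  out <- removeNonwear(ep, lab)
  newMissing <- sum(is.na(out$temp_c)) - sum(is.na(ep$temp_c))
  expect_identical(newMissing, sum(lab$label == "nonwear" & !is.na(ep$temp_c)))
  expect_error(removeNonwear(ep, labAll[-3, ]), "tile")
})

test_that("day segmentation anchors at 10:00 and drops partial days", {
  # 72 h beginning 04:00 -> exactly 2 complete 10:00-anchored days
  m <- mkMinutes("2023-01-01 04:00:00", 72 * 60, rep(36, 72 * 60))
  dm <- segmentDays(aggregate5min(m), gaAtStart = 240)
  expect_identical(ncol(dm), 2L)
  expect_identical(nrow(dm), 288L)

  # exactly 24 h from 10:00 -> one day
  m1 <- mkMinutes("2023-01-01 10:00:00", 1440, rep(36, 1440))
  expect_identical(ncol(segmentDays(aggregate5min(m1), 240)), 1L)

  # a sample at 09:59 belongs to the previous civil day
  m2 <- mkMinutes("2023-01-01 10:00:00", 1440 + 1440, rep(36, 2880))
  ep2 <- aggregate5min(m2)
  prev <- thermolabor:::floorDayStart(as.POSIXct("2023-01-02 09:59:00",
                                                 tz = "UTC"))
  expect_identical(format(prev, "%Y-%m-%d %H:%M", tz = "UTC"),
                   "2023-01-01 10:00")
  opens <- thermolabor:::floorDayStart(as.POSIXct("2023-01-02 10:00:00",
                                                  tz = "UTC"))
  expect_identical(format(opens, "%Y-%m-%d %H:%M", tz = "UTC"),
                   "2023-01-02 10:00")

  # conservation: complete days x 288 never exceeds input epochs
  expect_lte(ncol(dm) * 288L, nrow(aggregate5min(m)))
})

test_that("gap interpolation matches a piecewise-linear oracle and is idempotent", {
  v <- rep(36, 288 * 3)
  set.seed(5)
  v <- v + rnorm(length(v), 0, 0.3)
  v[sample(length(v), 200)] <- NA
  v[1:10] <- NA; v[(length(v) - 4):length(v)] <- NA
  dm <- DayMatrix(matrix(v, 288), 240:242, "p1")
  out <- interpolateGaps(dm)
  expect_equal(as.vector(tempMatrix(out)), oracleInterp(v))
  expect_false(anyNA(tempMatrix(out)))
  # observed values unchanged; midpoint example; idempotence; identity
  obs <- !is.na(v)
  expect_identical(as.vector(tempMatrix(out))[obs], v[obs])
  v2 <- c(36.0, NA, 37.0, rep(36.5, 285))
  dm2 <- DayMatrix(matrix(rep(v2, 1), 288), 240L, "p2")
  expect_equal(tempMatrix(interpolateGaps(dm2))[2, 1], 36.5)
  expect_equal(tempMatrix(interpolateGaps(out)), tempMatrix(out))
  full <- DayMatrix(matrix(36, 288, 1), 240L, "p3")
  expect_equal(tempMatrix(interpolateGaps(full)), tempMatrix(full))
  empty <- DayMatrix(matrix(NA_real_, 288, 1), 240L, "p4")
  expect_error(interpolateGaps(empty), "no observed")
})

test_that("data density counts observed epochs before interpolation", {
  ep <- data.frame(epoch = as.POSIXct("2023-01-01 10:00:00", tz = "UTC") +
                     300 * (0:575), temp_c = 36)
  expect_equal(computeDensity(ep), 1.0)
  ep$temp_c[1:288] <- NA
  expect_equal(computeDensity(ep), 0.5)
  set.seed(6)
  mask <- runif(576) < 0.37
  ep$temp_c <- 36; ep$temp_c[mask] <- NA
  expect_equal(computeDensity(ep), mean(!mask))
  expect_error(computeDensity(ep[1:10, ]), "at least one day")
})

test_that("inclusion filters use strict less-than exclusion semantics", {
  mk <- function(nDays, dayFrac = 1) {
    m <- matrix(36, 288, nDays)
    if (dayFrac < 1) m[seq_len(ceiling(288 * (1 - dayFrac))), ] <- NA
    DayMatrix(m, seq_len(nDays) + 239, "px")
  }
  r1 <- applyInclusionFilters(mk(20), density = 1.0)
  expect_false(r1$included); expect_match(r1$reason, "contiguity")
  r2 <- applyInclusionFilters(mk(30), density = 0.74)
  expect_false(r2$included); expect_match(r2$reason, "density")
  r3 <- applyInclusionFilters(mk(30), density = 0.75)
  expect_true(r3$included)
  r4 <- applyInclusionFilters(mk(21), density = 1.0)
  expect_true(r4$included)
})

test_that("contiguity is the longest run of days above the per-day floor", {
  m <- matrix(36, 288, 10)
  m[, 4] <- NA                      # breaks the run
  m[1:200, 8] <- NA                 # density 0.3 < 0.5 floor -> breaks
  dm <- DayMatrix(m, 240:249, "px")
  expect_identical(contiguousDays(dm), 3L)   # days 5,6,7
})

test_that("the pipeline yields gap-free days for included participants", {
  cfg <- cohortConfig(nSpontaneous = 2L, nInduced = 0L, nCesarean = 0L,
                      gaStart = 250, noiseSd = 0.1, seed = 3L)
  prep <- preprocessCohort(generateCohort(cfg))
  expect_true(all(prep$reports$included))
  for (dm in prep$days) {
    expect_false(anyNA(tempMatrix(dm)))
    expect_identical(nrow(dm), 288L)
    expect_true(all(diff(gestationalDays(dm)) > 0))
  }
})
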