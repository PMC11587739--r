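#' CSV dialects and the pipeline driver
#'
#' Readers/writers for the cohort CSV dialects (minutes, activity, hormones,
#' records, traces, windows, outcomes) and an end-to-end pipeline driver
#' that simulates, preprocesses, analyzes rhythms and hormones, trains and
#' evaluates, writing every artifact with a manifest.
#'
#' @name cli_io
NULL

.SCHEMAS <- list(
  minutes = c("participant_id", "time", "temp_c"),
  activity = c("participant_id", "epoch_start", "label"),
  hormones = c("participant_id", "day_to_labor", "analyte", "value"),
  records = c("participant_id", "group", "labor_ga_days", "edd_ga_days",
              "ga_start"),
  traces = c("participant_id", "k", "y", "y_hat", "e"),
  windows = c("T", "P", "eps1", "eps2", "W1", "W2", "width"),
  outcomes = c("participant_id", "label", "miss_days"))

#' Write a cohort to its CSV dialects
#'
#' Writes minutes.csv, activity.csv, hormones.csv and records.csv with
#' ISO-8601 timestamps (UTC) and temperatures at millidegree precision.
#'
#' @param cohort list of [SynthParticipant-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  minutes <- data.table::rbindlist(lapply(cohort, function(p) {
    m <- p@minutes
    data.table::data.table(participant_id = m$participant_id,
                           time = fmt(m$time),
                           temp_c = round(m$temp_c, 3))
  }))
  activity <- data.table::rbindlist(lapply(cohort, function(p) {
    a <- p@activity
    data.table::data.table(participant_id = a$participant_id,
                           epoch_start = fmt(a$epoch_start), label = a$label)
  }))
  hormones <- data.table::rbindlist(lapply(cohort, function(p) p@hormones))
  records <- data.table::rbindlist(lapply(cohort, function(p) p@record))
  data.table::fwrite(minutes, file.path(dir, "minutes.csv"))
  data.table::fwrite(activity, file.path(dir, "activity.csv"))
  data.table::fwrite(hormones, file.path(dir, "hormones.csv"))
  data.table::fwrite(records, file.path(dir, "records.csv"))
  invisible(dir)
}

#' @noRd
checkSchema <- function(df, what) {
  need <- .SCHEMAS[[what]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @noRd
parseTimes <- function(x, what) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad))
    stop("malformed timestamp in ", what, " at row ", bad[1], ": ", x[bad[1]])
  t
}

#' Read a cohort back from its CSV dialects
#'
#' @param dir directory holding minutes.csv, activity.csv, hormones.csv and
#'   records.csv.
#' @return list of [SynthParticipant-class].
#' @export
readCohortCSV <- function(dir) {
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  rd <- function(f) as.data.frame(data.table::fread(
    file.path(dir, f), colClasses = list(character = "participant_id")))
  minutes <- checkSchema(rd("minutes.csv"), "minutes")
  activity <- checkSchema(rd("activity.csv"), "activity")
  hormones <- checkSchema(rd("hormones.csv"), "hormones")
  records <- checkSchema(rd("records.csv"), "records")
  minutes$time <- parseTimes(minutes$time, "minutes")
  activity$epoch_start <- parseTimes(activity$epoch_start, "activity")
  lapply(records$participant_id, function(id) {
    new("SynthParticipant",
        record = records[records$participant_id == id, , drop = FALSE],
        minutes = minutes[minutes$participant_id == id, ],
        activity = activity[activity$participant_id == id, ],
        hormones = hormones[hormones$participant_id == id, ])
  })
}

#' Run the full pipeline end to end
#'
#' simulate -> preprocess -> rhythms/hormones -> train -> evaluate, writing
#' cohort CSVs, traces, windows and a manifest (config digest, seed,
#' package version) into the run directory.
#'
#' @param config a [CohortConfig-class].
#' @param outDir run directory.
#' @param modelConfig a [laborModelConfig()].
#' @param windowT days-to-labor cross-sections for window reports.
#' @param probs coverage probabilities.
#' @param seed master seed (overrides the config seed when given).
#' @param verbose progress messages.
#' @return list with cohort artifacts, traces, window summaries and the
#'   manifest, invisibly.
#' @export
runPipeline <- function(config, outDir, modelConfig = laborModelConfig(),
                        windowT = c(7, 10), probs = c(0.7, 0.8, 0.9, 0.95),
                        seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) config@seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ", Sys.time())
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  cohort <- stage("simulate", generateCohort(config))
  stage("write-cohort", writeCohortCSV(cohort, file.path(outDir, "cohort")))
  prep <- stage("preprocess", preprocessCohort(cohort))
  data.table::fwrite(prep$reports, file.path(outDir, "inclusion.csv"))
  recs <- prep$records
  spontIds <- recs$participant_id[recs$group == "spontaneous"]
  laborDays <- setNames(recs$labor_ga_days, recs$participant_id)
  model <- stage("train", trainLaborModel(prep$days[spontIds], laborDays,
                                          modelConfig, seed = config@seed))
  traces <- stage("predict", predictCohort(model, prep$days, laborDays))
  data.table::fwrite(traces, file.path(outDir, "traces.csv"))
  spontTraces <- traces[traces$participant_id %in% spontIds, ]
  windows <- stage("evaluate", do.call(rbind, lapply(windowT, function(Tc)
    windowReport(spontTraces, Tc, probs)$summary)))
  data.table::fwrite(windows, file.path(outDir, "windows.csv"))
  manifest <- list(seed = config@seed,
                   package = as.character(utils::packageVersion("thermolabor")),
                   nParticipants = length(cohort),
                   nIncluded = sum(prep$reports$included),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, prep = prep, model = model,
                 traces = traces, windows = windows, manifest = manifest))
}

#' Serialize / read a DayMatrix as CSV
#'
#' One row per day: participant_id, gestational_day, slot_0..slot_287.
#'
#' @param dm a [DayMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDayMatrixCSV <- function(dm, path) {
  m <- t(tempMatrix(dm))
  colnames(m) <- paste0("slot_", seq_len(288) - 1)
  df <- data.frame(participant_id = participantId(dm),
                   gestational_day = gestationalDays(dm), m,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeDayMatrixCSV
#' @return for the reader, a [DayMatrix-class].
#' @export
readDayMatrixCSV <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("participant_id", "gestational_day", paste0("slot_", 0:287))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("day-matrix table is missing column(s): ",
         paste(head(miss, 3), collapse = ", "))
  DayMatrix(t(as.matrix(df[, paste0("slot_", 0:287)])),
            df$gestational_day, df$participant_id[1])
}
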