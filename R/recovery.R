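#' Parameter-recovery validation experiment
#'
#' The package's standing validation run: a 30-participant low-noise
#' synthetic cohort with the embedded pre-labor signatures (0.44 deg C drop
#' over the final 7 days, circadian amplitude damping to near zero across
#' the final 10 days), preprocessed and split subject-wise; the model is
#' trained on 24 participants and evaluated on the 6 held out. Reported
#' metrics are the held-out Spearman correlation between predicted and true
#' days-to-labor over the final 14 days and the held-out mean signed error
#' over the final week.
#'
#' @name recovery
NULL

#' Cohort configuration of the recovery experiment
#'
#' @param seed master seed.
#' @param n number of spontaneous participants (default 30).
#' @return a [CohortConfig-class].
#' @export
recoveryCohortConfig <- function(seed = 101L, n = 30L) {
  cohortConfig(nSpontaneous = as.integer(n), nInduced = 0L, nCesarean = 0L,
               noiseSd = 0.05, nonwearGapRate = 0.2,
               missingMinuteRate = 0.01,
               circadianAmplitude = 0.5, circadianDampingRate = 0.09,
               prelaborDrop = 0.44, seed = as.integer(seed))
}

#' Model configuration of the recovery experiment
#'
#' The architecture is the full default (three conv blocks, 64-d latent,
#' 128-unit LSTM); training is shortened (20 autoencoder epochs on a
#' 400-day subsample, 150 LSTM epochs) to keep a single run around two
#' minutes on one CPU.
#'
#' @return a [laborModelConfig()].
#' @export
recoveryModelConfig <- function() {
  laborModelConfig(ae = aeConfig(epochs = 20L),
                   lstm = lstmConfig(epochs = 150L),
                   aeMaxDays = 400L)
}

#' Run the recovery experiment once
#'
#' @param seed seed for cohort generation, fold split and training.
#' @param config a [CohortConfig-class] (defaults to
#'   [recoveryCohortConfig()] with this seed).
#' @param modelConfig a [laborModelConfig()].
#' @return list with `spearman14` (held-out, final 14 days), `bias7`
#'   (held-out mean signed error, final week, days), `reconMAE` (deg C),
#'   `model`, `traces` (held-out), `days`, `laborDays`, `testIds`.
#' @export
recoveryExperiment <- function(seed = 1L,
                               config = recoveryCohortConfig(mixSeed(seed,
                                                                     400L)),
                               modelConfig = recoveryModelConfig()) {
  cohort <- generateCohort(config)
  prep <- preprocessCohort(cohort)
  laborDays <- setNames(prep$records$labor_ga_days,
                        prep$records$participant_id)
  folds <- kfoldSplit(names(prep$days), k = 5L, seed = mixSeed(seed, 401L))
  testIds <- folds$participant_id[folds$fold == 1L]
  trainIds <- setdiff(names(prep$days), testIds)
  model <- trainLaborModel(prep$days[trainIds], laborDays, modelConfig,
                           seed = mixSeed(seed, 402L))
  traces <- predictCohort(model, prep$days[testIds], laborDays)
  fin14 <- traces[traces$y >= 0 & traces$y <= 14, ]
  fin7 <- traces[traces$y >= 0 & traces$y <= 7, ]
  list(spearman14 = cor(fin14$y, fin14$y_hat, method = "spearman"),
       bias7 = mean(fin7$e), reconMAE = model@reconMAE,
       model = model, traces = traces, days = prep$days,
       laborDays = laborDays, testIds = testIds)
}
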