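#' Cohort-flow arithmetic and printed-table percentages
#'
#' The inclusion pipeline's participant accounting, applied to the
#' enrollment flow of the reference wearable-pregnancy cohort the package
#' emulates, plus recomputation of demographic-table percentages from
#' printed counts.
#'
#' @name cohortflow
NULL

#' Participant flow through the filtering pipeline
#'
#' Applies the exclusion arithmetic of the study design: enrolled minus
#' lost to follow-up, split by labor type, minus the temperature-quality
#' exclusions (contiguity/density filters) per group. Defaults are the
#' reference cohort's printed flow: 127 enrolled, 7 lost, 71 spontaneous /
#' 45 induced / 4 cesarean, 17 spontaneous and 12 non-spontaneous excluded.
#'
#' @param enrolled,lost enrollment counts.
#' @param spontaneous,induced,cesarean group sizes after follow-up.
#' @param excludedSpontaneous,excludedNonspontaneous data-quality
#'   exclusions.
#' @return list with `followed`, `analyzedSpontaneous`,
#'   `analyzedNonspontaneous` and `analyzedTotal`.
#' @export
cohortFlow <- function(enrolled = 127L, lost = 7L,
                       spontaneous = 71L, induced = 45L, cesarean = 4L,
                       excludedSpontaneous = 17L,
                       excludedNonspontaneous = 12L) {
  followed <- enrolled - lost
  if (spontaneous + induced + cesarean != followed)
    stop("group sizes do not sum to the followed count")
  aSp <- spontaneous - excludedSpontaneous
  aNs <- induced + cesarean - excludedNonspontaneous
  list(followed = followed, analyzedSpontaneous = aSp,
       analyzedNonspontaneous = aNs, analyzedTotal = aSp + aNs)
}

#' Recompute table percentages from counts
#'
#' Percentages to one decimal (standard half-up rounding, matching the
#' printed tables' convention).
#'
#' @param counts integer vector of cell counts.
#' @param denominator total (defaults to `sum(counts)`).
#' @return numeric vector of percentages.
#' @export
tablePercentages <- function(counts, denominator = sum(counts)) {
  round(100 * counts / denominator + 1e-9, 1)
}

#' Reference cohort demographic counts
#'
#' Selected cell counts of the analyzed reference cohort (N = 91: 54
#' spontaneous, 37 induced or pre-labor cesarean), used to validate the
#' percentage arithmetic: group sizes, parity, labor progress and mode of
#' birth.
#'
#' @return data.frame (section, cell, group, count, denominator).
#' @export
referenceDemographics <- function() {
  rbind(
    data.frame(section = "labor_group",
               cell = c("spontaneous", "nonspontaneous"),
               group = "total", count = c(54L, 37L), denominator = 91L),
    data.frame(section = "parity", cell = c("nulliparous", "multiparous"),
               group = "total", count = c(48L, 43L), denominator = 91L),
    data.frame(section = "labor_progress",
               cell = c("spont_onset_progress", "spont_onset_augmented",
                        "labor_induction", "cesarean_prelabor"),
               group = "total", count = c(34L, 20L, 34L, 3L),
               denominator = 91L),
    data.frame(section = "mode_of_birth",
               cell = c("vaginal", "vaginal_assisted", "cesarean"),
               group = "total", count = c(72L, 4L, 15L), denominator = 91L),
    data.frame(section = "induction_reason",
               cell = c("post_dates", "medical", "fetal", "convenience"),
               group = "induced_subset", count = c(7L, 5L, 10L, 4L),
               denominator = 33L))
}
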