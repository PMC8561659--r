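#' @include utils.R
NULL

#' Cohort bookkeeping from the bundled demographics table
#'
#' Summarises the study design from the per-group demographics shipped with
#' the package (one row per treatment group: participant counts by sex,
#' group mean/SD age, samples per participant): samples collected, samples
#' processed after missed collections, per-experiment sample counts retained
#' after sequencing quality control, participant total, and the mean of the
#' group mean ages.
#'
#' @param demographics data.frame as in
#'   \code{system.file("extdata", "participant_demographics.tsv",
#'   package = "microload")}; read from there when NULL.
#' @param missingCollections samples never collected, by study (the daily
#'   study had 2 missed collections).
#' @param qcDropped samples dropped by the minimum-depth sequencing filter,
#'   by study (6 in the acute-perturbation study).
#' @return list of bookkeeping quantities.
#' @export
studySummary <- function(demographics = NULL,
                         missingCollections = c(daily_dynamics = 2L,
                                                acute_perturbation = 0L),
                         qcDropped = c(daily_dynamics = 0L,
                                       acute_perturbation = 6L)) {
  if (is.null(demographics)) {
    path <- system.file("extdata", "participant_demographics.tsv",
                        package = "microload")
    demographics <- read.delim(path, stringsAsFactors = FALSE)
  }
  d <- demographics
  d$n_participants <- d$n_females + d$n_males
  collected <- sum(d$total_samples)
  byStudy <- tapply(d$total_samples, d$study, sum)
  processedByStudy <- byStudy - missingCollections[names(byStudy)]
  retainedByStudy <- processedByStudy - qcDropped[names(byStudy)]
  list(samples_collected = collected,
       samples_processed = sum(processedByStudy),
       participants = sum(d$n_participants),
       daily_retained = unname(retainedByStudy["daily_dynamics"]),
       acute_retained = unname(retainedByStudy["acute_perturbation"]),
       mean_group_age = mean(d$avg_age),
       females = sum(d$n_females), males = sum(d$n_males))
}
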