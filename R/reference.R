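# Published summary statistics for Luehdorfia chinensis control (CG) and
# larval-starvation (ST, pooled 3rd/4th/5th-instar treatments) cohorts,
# transcribed from the literature. They parameterize the synthetic cohort
# generator and the reference arithmetic below; no raw individual data are
# publicly deposited for this species.

ref_file <- function(name) {
  system.file("extdata", name, package = "agestage", mustWork = TRUE)
}

#' Published population parameters (bootstrap mean and SD) by group
#'
#' Intrinsic rate r, net reproductive rate R0, finite rate lambda, mean
#' total fecundity per female F, and mean generation time T for the control
#' (CG, n = 30) and pooled larval-starvation (ST, n = 90) cohorts of
#' \emph{Luehdorfia chinensis}.
#'
#' @return Data frame with columns parameter, group, mean, sd.
#' @export
ref_population_parameters <- function() {
  utils::read.csv(ref_file("reference_population_parameters.csv"), stringsAsFactors = FALSE)
}

#' Published immature stage durations (mean, SD, n) by group
#'
#' Egg, larval instar and pupal durations in days for the control (CG) and
#' the three starvation treatments (ST3/ST4/ST5: starved for three days at
#' the 3rd/4th/5th instar). The n column is the number of individuals alive
#' in the stage.
#'
#' @return Data frame with columns stage, group, mean_days, sd_days, n.
#' @export
ref_stage_durations <- function() {
  utils::read.csv(ref_file("reference_stage_durations.csv"), stringsAsFactors = FALSE)
}

#' Published cohort survival counts by group
#'
#' Individuals at the start, pupae formed, and adult females/males emerged.
#'
#' @return Data frame with columns group, n_start, n_pupae, n_adult_female,
#'   n_adult_male.
#' @export
ref_cohort_counts <- function() {
  utils::read.csv(ref_file("reference_cohort_counts.csv"), stringsAsFactors = FALSE)
}

ref_param <- function(parameter, group) {
  d <- ref_population_parameters()
  d$mean[d$parameter == parameter & d$group == group]
}

ref_duration <- function(stage, group) {
  d <- ref_stage_durations()
  d$mean_days[d$stage == stage & d$group == group]
}

#' Percent change helpers
#'
#' \code{percent_decline} is the percent reduction of \code{treated}
#' relative to \code{control}; \code{percent_extension} is the percent
#' increase.
#'
#' @param control,treated Positive reference and comparison values.
#' @return Percent change (100-scale).
#' @export
percent_decline <- function(control, treated) 100 * (control - treated) / control

#' @rdname percent_decline
#' @export
percent_extension <- function(control, treated) 100 * (treated - control) / control

#' Parameter declines between the published CG and ST columns
#'
#' Recomputes, from the packaged published means, the percent declines of
#' the intrinsic rate r, net reproductive rate R0 and mean total fecundity F
#' in the starvation group relative to control.
#'
#' @return Named vector (r, R0, F) of percent declines.
#' @export
published_parameter_declines <- function() {
  c(r = percent_decline(ref_param("r", "CG"), ref_param("r", "ST")),
    R0 = percent_decline(ref_param("R0", "CG"), ref_param("R0", "ST")),
    F = percent_decline(ref_param("F", "CG"), ref_param("F", "ST")))
}

#' Starved-instar duration extensions from the published stage means
#'
#' Percent extension of the starved instar's developmental duration relative
#' to control: the 3rd instar under 3rd-instar starvation and the 5th instar
#' under 5th-instar starvation bracket the published range.
#'
#' @return Named vector (L3, L5) of percent extensions.
#' @export
published_duration_extensions <- function() {
  c(L3 = percent_extension(ref_duration("L3", "CG"), ref_duration("L3", "ST3")),
    L5 = percent_extension(ref_duration("L5", "CG"), ref_duration("L5", "ST5")))
}

#' Finite rate of increase implied by the published intrinsic rates
#'
#' Applies the identity \eqn{\lambda = e^r} to the published r of each
#' group; agreement with the published lambda to four decimals is a
#' consistency check of the transcribed table.
#'
#' @return Named vector (CG, ST) of \eqn{e^r}.
#' @export
published_lambda_from_r <- function() {
  c(CG = exp(ref_param("r", "CG")), ST = exp(ref_param("r", "ST")))
}
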