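#' Default obstetric principal-procedure codes
#'
#' A small set of delivery/curettage procedure codes in the national
#' procedure-table style, shipped as a one-column CSV and user-replaceable.
#'
#' @param path Optional CSV with a `procedure_code` column.
#' @return Character vector of procedure codes.
#' @export
default_obstetric_procedures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "obstetric_procedures.csv",
                        package = "morbrules", mustWork = TRUE)
  }
  utils::read.csv(path, colClasses = "character")$procedure_code
}

#' Is an episode obstetric?
#'
#' True when any claim of the episode carries a chapter-XV diagnosis (ICD-10
#' code starting with "O") in the principal or any secondary field, or an
#' obstetric principal procedure.
#'
#' @param episodes Episode tibble from [episodes()].
#' @param obstetric_procedures Character vector of procedure codes.
#' @return Logical vector, one element per episode.
#' @export
is_obstetric <- function(episodes, obstetric_procedures = default_obstetric_procedures()) {
  has_o <- vapply(episodes$diagnoses,
                  function(d) any(startsWith(d, "O")), logical(1))
  has_proc <- vapply(episodes$procedures,
                     function(p) any(p %in% obstetric_procedures), logical(1))
  has_o | has_proc
}

#' Select the obstetric study cohort
#'
#' Keeps obstetric episodes of women aged 10-49 completed years at
#' admission whose episode outcome is discharged alive or in-hospital
#' death. The three criteria commute; selection is idempotent.
#'
#' @inheritParams is_obstetric
#' @return Filtered episode tibble; attribute `selection_log` holds the
#'   number of episodes failing each criterion and the total removed.
#' @export
select_cohort <- function(episodes, obstetric_procedures = default_obstetric_procedures()) {
  obst <- is_obstetric(episodes, obstetric_procedures)
  age_ok <- episodes$age_years >= 10L & episodes$age_years <= 49L
  outcome_ok <- episodes$outcome %in% c("alive", "in_hospital_death")
  keep <- obst & age_ok & outcome_ok
  out <- episodes[keep, , drop = FALSE]
  attr(out, "selection_log") <- list(
    n_in = nrow(episodes),
    removed_not_obstetric = sum(!obst),
    removed_age = sum(!age_ok),
    removed_outcome = sum(!outcome_ok),
    n_kept = nrow(out)
  )
  out
}

#' Confirm in-hospital deaths against a death registry
#'
#' Removes death-outcome episodes that cannot be matched in the registry
#' by patient date of birth and municipality with a death date within the
#' episode's stay (extended `grace_days` past discharge to tolerate
#' date-entry lag). Alive episodes pass through. Optional stage: without a
#' registry no confirmation is attempted.
#'
#' @param episodes Cohort episode tibble.
#' @param registry Death-registry tibble (`birth_date, municipality,
#'   death_date`).
#' @param grace_days Days past discharge still accepted; default 1.
#' @return Filtered episode tibble with attribute `confirm_log`
#'   (`removed_unconfirmed`).
#' @export
confirm_deaths <- function(episodes, registry, grace_days = 1L) {
  deaths <- episodes[episodes$outcome == "in_hospital_death", , drop = FALSE]
  if (nrow(deaths) == 0L || is.null(registry)) {
    attr(episodes, "confirm_log") <- list(removed_unconfirmed = 0L)
    return(episodes)
  }
  reg <- dplyr::distinct(tibble::as_tibble(registry))
  cand <- dplyr::inner_join(
    deaths[, c("episode_id", "birth_date", "municipality",
               "admission_date", "discharge_date")],
    reg, by = c("birth_date", "municipality"),
    relationship = "many-to-many")
  confirmed <- unique(cand$episode_id[
    cand$death_date >= cand$admission_date &
    cand$death_date <= cand$discharge_date + grace_days])
  drop <- setdiff(deaths$episode_id, confirmed)
  out <- episodes[!(episodes$episode_id %in% drop), , drop = FALSE]
  attr(out, "confirm_log") <- list(removed_unconfirmed = length(drop))
  out
}
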