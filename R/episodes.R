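#' Can a claim continue the episode of the previous claim?
#'
#' Two claims of the same patient block (same municipality and date of
#' birth) chain when the earlier claim was discharged as a hospital stay or
#' an interhospital transfer and the later admission follows within at most
#' one day of the earlier discharge. A stay continuation must be in the
#' same hospital; a transfer may change hospital. Negative gaps
#' (overlapping stays) never chain.
#'
#' @param prev,next_ Claims (one-row data frames or equal-length claim
#'   tables, compared row-wise).
#' @return Logical vector.
#' @export
chainable <- function(prev, next_) {
  gap <- as.integer(next_$admission_date - prev$discharge_date)
  ok_reason <- prev$discharge_reason %in% c("stay", "transfer")
  ok_hospital <- prev$discharge_reason == "transfer" |
    prev$hospital_code == next_$hospital_code
  ok_reason & !is.na(gap) & gap >= 0L & gap <= 1L & ok_hospital
}

diag_cols <- function() c("diag_principal", paste0("diag_sec_", 1:11))

validate_claims <- function(claims) {
  stopifnot(is.data.frame(claims))
  missing <- setdiff(claims_columns(), names(claims))
  if (length(missing)) {
    stop("claims table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(claims$claim_id)) {
    stop("duplicate claim_id in input claims", call. = FALSE)
  }
  if (any(claims$discharge_date < claims$admission_date)) {
    stop("claim(s) with discharge_date before admission_date", call. = FALSE)
  }
  if (any(claims$birth_date >= claims$admission_date)) {
    stop("claim(s) with birth_date on or after admission_date", call. = FALSE)
  }
  if (any(is.na(claims$diag_principal))) {
    stop("claim(s) with no principal diagnosis", call. = FALSE)
  }
  invisible(claims)
}

#' Link claims into hospital episodes
#'
#' Deterministic record linkage: claims are blocked by municipality of
#' residence and patient date of birth, sorted by admission date (ties by
#' discharge date, then claim id), and chained greedily left to right under
#' [chainable()]. Every claim ends up in exactly one episode; shuffling the
#' input leaves the partition unchanged.
#'
#' @param claims Claims tibble (see [read_claims()] for the dialect).
#' @return The claims sorted in linkage order with an added `episode_id`
#'   column. A `linkage_log` attribute records block/claim/episode counts
#'   and the number of overlapping-stay (negative gap) adjacencies, which
#'   never chain and are flagged as data-quality findings.
#' @export
link_episodes <- function(claims) {
  validate_claims(claims)
  claims <- dplyr::arrange(claims, .data$municipality, .data$birth_date,
                           .data$admission_date, .data$discharge_date,
                           .data$claim_id)
  same_block <- c(FALSE,
                  claims$municipality[-1L] == claims$municipality[-nrow(claims)] &
                  claims$birth_date[-1L] == claims$birth_date[-nrow(claims)])
  prev <- claims[c(NA_integer_, seq_len(nrow(claims) - 1L)), ]
  chain <- same_block & chainable(prev, claims)
  chain[is.na(chain)] <- FALSE
  episode_idx <- cumsum(!chain)
  claims$episode_id <- sprintf("E%07d", episode_idx)
  neg_gap <- sum(same_block &
                   prev$discharge_reason %in% c("stay", "transfer") &
                   as.integer(claims$admission_date - prev$discharge_date) < 0L,
                 na.rm = TRUE)
  attr(claims, "linkage_log") <- list(
    n_claims = nrow(claims),
    n_blocks = nrow(dplyr::distinct(claims, .data$municipality, .data$birth_date)),
    n_episodes = max(episode_idx, 0L),
    negative_gap_pairs = neg_gap
  )
  claims
}

completed_years <- function(birth, at) {
  b <- as.POSIXlt(birth); a <- as.POSIXlt(at)
  (a$year - b$year) - as.integer(a$mon < b$mon | (a$mon == b$mon & a$mday < b$mday))
}

#' Summarise linked claims into episodes
#'
#' One row per episode: admission is the first claim's admission, discharge
#' the last claim's discharge, the outcome is the discharge-reason class of
#' the last claim (`alive`, `in_hospital_death`, anything else `other`),
#' and age is in completed years at episode admission. The `diagnoses` and
#' `procedures` list-columns collect every diagnosis/procedure code across
#' the episode's claims.
#'
#' @param linked_claims Output of [link_episodes()].
#' @return Episode tibble.
#' @export
episodes <- function(linked_claims) {
  stopifnot("episode_id" %in% names(linked_claims))
  cl <- linked_claims
  # claims arrive in linkage order, episodes contiguous
  eid <- cl$episode_id
  first <- !duplicated(eid)
  last <- !duplicated(eid, fromLast = TRUE)
  f <- factor(eid, levels = eid[first])
  dmat <- as.matrix(cl[, diag_cols()])
  keep <- !is.na(dmat)
  diagnoses <- unname(split(dmat[keep], f[row(dmat)[keep]]))
  procedures <- lapply(unname(split(cl$procedure_code, f)), unique)
  last_reason <- cl$discharge_reason[last]
  ep <- tibble::tibble(
    episode_id = eid[first],
    municipality = cl$municipality[first],
    birth_date = cl$birth_date[first],
    admission_date = cl$admission_date[first],
    discharge_date = cl$discharge_date[last],
    n_claims = tabulate(f),
    diagnoses = diagnoses,
    procedures = procedures,
    outcome = ifelse(last_reason %in% c("alive", "in_hospital_death"),
                     last_reason, "other")
  )
  ep$age_years <- completed_years(ep$birth_date, ep$admission_date)
  ep
}
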