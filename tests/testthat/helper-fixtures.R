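# hand-built fixtures

make_claim <- function(claim_id = "C1", hospital_code = "H1",
                       municipality = "350001",
                       birth_date = as.Date("1990-05-10"),
                       admission_date = as.Date("2016-03-01"),
                       discharge_date = admission_date + 2,
                       discharge_reason = "alive",
                       diag_principal = "O80", diag_sec = character(0),
                       procedure_code = "0310010039") {
  sec <- rep(NA_character_, 11L)
  sec[seq_along(diag_sec)] <- diag_sec
  tibble::tibble(
    claim_id = claim_id, hospital_code = hospital_code,
    municipality = municipality, birth_date = birth_date,
    admission_date = admission_date, discharge_date = discharge_date,
    discharge_reason = discharge_reason, diag_principal = diag_principal,
    !!!stats::setNames(as.list(sec), paste0("diag_sec_", 1:11)),
    procedure_code = procedure_code
  )
}

make_episode <- function(episode_id = "E1", diagnoses = "O80",
                         outcome = "alive", age_years = 25L,
                         municipality = "350001",
                         birth_date = as.Date("1990-05-10"),
                         admission_date = as.Date("2016-03-01"),
                         discharge_date = admission_date + 2,
                         procedures = "0310010039", n_claims = 1L) {
  tibble::tibble(
    episode_id = episode_id, municipality = municipality,
    birth_date = birth_date, admission_date = admission_date,
    discharge_date = discharge_date, n_claims = n_claims,
    diagnoses = list(diagnoses), procedures = list(procedures),
    outcome = outcome, age_years = age_years
  )
}

make_rules <- function(antecedents, confidences, consequent = "DEATH",
                       counts = 10, lifts = 2, n = 1000) {
  k <- length(antecedents)
  tibble::tibble(
    antecedent = antecedents,
    consequent = rep_len(consequent, k),
    count = rep_len(counts, k),
    support = rep_len(counts, k) / n,
    confidence = confidences,
    lift = rep_len(lifts, k)
  )
}

# weighted database realizing stated profile counts in a database of n
# records with n_deaths deaths overall
profile_db <- function(profiles, n = 2742467, n_deaths = 831) {
  sets <- lapply(profiles, `[[`, "items")
  w <- vapply(profiles, `[[`, numeric(1), "w")
  deaths_in <- sum(w[vapply(sets, function(s) "DEATH" %in% s, logical(1))])
  sets <- c(sets, list("DEATH", "ALIVE"))
  w <- c(w, n_deaths - deaths_in, n - sum(w) - (n_deaths - deaths_in))
  morbrules::transaction_db(sets, w)
}
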