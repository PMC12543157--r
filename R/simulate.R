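#' Default per-episode prevalence of each morbidity item
#'
#' Emulates an obstetric claims stream: childbirth (group 10) dominates,
#' direct obstetric complications are at the percent level, non-obstetric
#' complications are rarer. Values are the generator's fixed study
#' conditions, not tuning knobs.
#'
#' @return Named numeric vector over [item_catalogue()].
#' @export
default_group_prevalences <- function() {
  c("1a" = 0.004, "1b" = 0.006, "2a" = 0.020, "2b" = 0.004,
    "3"  = 0.012, "4a" = 0.010, "4b" = 0.0015, "5" = 0.006,
    "7a" = 0.008, "7b" = 0.0015, "8a" = 0.0010, "8b" = 0.0005,
    "8c" = 0.0010, "8d" = 0.0008, "8e" = 0.003, "9" = 0.00002,
    "10" = 0.90, "11" = 0.010, "12" = 0.0005, "13" = 0.005)
}

#' Configuration for the synthetic claims generator
#'
#' One synthetic patient yields one hospital episode. Diagnosis items are
#' drawn per episode from `group_prevalences` (with optional pairwise
#' odds tilts), the in-hospital death probability is
#' `baseline_death_prob` times the product of `death_relative_risks` over
#' the episode's items (capped at 1), and with probability `transfer_prob`
#' the episode is split into chained claims whose intermediate discharge
#' codes are stay/transfer with admission gaps drawn from
#' `gap_days_distribution`.
#'
#' @param n_patients Number of synthetic patients (= episodes).
#' @param baseline_death_prob Per-episode death probability with no risk
#'   items; default 3e-4, the order of magnitude of in-hospital death in
#'   obstetric admissions.
#' @param group_prevalences Named probabilities per item label.
#' @param death_relative_risks Named multiplicative risk factors (>= 0);
#'   items not named have risk 1.
#' @param cooccurrence_pairs Optional data frame `item_a,item_b,odds_multiplier`:
#'   for episodes carrying `item_a`, the odds of `item_b` are multiplied.
#' @param transfer_prob Probability an episode is split into 2+ claims;
#'   default 0.011 (so roughly 98.9% of episodes are single-claim).
#' @param gap_days_distribution Named probabilities over gap days `"0"`/`"1"`
#'   between a claim's discharge and the next claim's admission.
#' @param seed Integer RNG seed; identical seed and config give identical
#'   output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients,
                              baseline_death_prob = 3e-4,
                              group_prevalences = default_group_prevalences(),
                              death_relative_risks = NULL,
                              cooccurrence_pairs = NULL,
                              transfer_prob = 0.011,
                              gap_days_distribution = c("0" = 0.5, "1" = 0.5),
                              seed = 1L) {
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
      stop("invalid probability for ", what, call. = FALSE)
    }
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  chk_prob(baseline_death_prob, "baseline_death_prob")
  chk_prob(group_prevalences, "group_prevalences")
  chk_prob(transfer_prob, "transfer_prob")
  chk_prob(gap_days_distribution, "gap_days_distribution")
  chk_items <- function(labs, what) {
    bad <- setdiff(labs, item_catalogue())
    if (length(bad)) {
      stop("unknown item label(s) in ", what, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  chk_items(names(group_prevalences), "group_prevalences")
  if (!is.null(death_relative_risks)) {
    if (!is.numeric(death_relative_risks) || any(death_relative_risks < 0)) {
      stop("death_relative_risks must be numeric and >= 0", call. = FALSE)
    }
    chk_items(names(death_relative_risks), "death_relative_risks")
  }
  if (!is.null(cooccurrence_pairs)) {
    cooccurrence_pairs <- as.data.frame(cooccurrence_pairs)
    stopifnot(all(c("item_a", "item_b", "odds_multiplier") %in%
                    names(cooccurrence_pairs)))
    chk_items(c(cooccurrence_pairs$item_a, cooccurrence_pairs$item_b),
              "cooccurrence_pairs")
    if (any(cooccurrence_pairs$odds_multiplier < 0)) {
      stop("odds_multiplier must be >= 0", call. = FALSE)
    }
  }
  if (!all(names(gap_days_distribution) %in% c("0", "1")) ||
      abs(sum(gap_days_distribution) - 1) > 1e-8) {
    stop("gap_days_distribution must be probabilities over gaps 0 and 1",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    baseline_death_prob = baseline_death_prob,
    group_prevalences = group_prevalences,
    death_relative_risks = death_relative_risks,
    cooccurrence_pairs = cooccurrence_pairs,
    transfer_prob = transfer_prob,
    gap_days_distribution = gap_days_distribution,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# column order of the claims CSV dialect
claims_columns <- function() {
  c("claim_id", "hospital_code", "municipality", "birth_date",
    "admission_date", "discharge_date", "discharge_reason",
    "diag_principal", paste0("diag_sec_", 1:11), "procedure_code")
}

#' Generate synthetic hospital claims
#'
#' Emits one episode's worth of claims per patient under `config` (see
#' [simulation_config()]). Every diagnosis is written as an ICD-10-shaped
#' code that the shipped default mapping resolves to the intended item, and
#' every episode carries an obstetric principal procedure so the whole
#' stream is an obstetric hospitalization stream. Claims are returned in
#' shuffled order so downstream linkage cannot rely on input order.
#'
#' @param config A [simulation_config()].
#' @return Tibble of claims, one row per claim, columns as in the claims
#'   CSV dialect (see [write_claims()]).
#' @export
generate_claims <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_patients
  prev <- config$group_prevalences
  labs <- names(prev)

  # item indicator matrix, then sequential pairwise odds tilts
  M <- matrix(runif(n * length(labs)) < rep(prev, each = n),
              nrow = n, dimnames = list(NULL, labs))
  cp <- config$cooccurrence_pairs
  if (!is.null(cp)) {
    for (i in seq_len(nrow(cp))) {
      a <- cp$item_a[i]; b <- cp$item_b[i]; m <- cp$odds_multiplier[i]
      rows <- which(M[, a])
      if (length(rows)) {
        odds <- prev[b] / (1 - prev[b]) * m
        M[rows, b] <- runif(length(rows)) < odds / (1 + odds)
      }
    }
  }
  # ensure every episode has an admission reason
  none <- rowSums(M) == 0L
  if (any(none)) {
    if (!"10" %in% labs) stop("no items drawn and item '10' not configured",
                              call. = FALSE)
    M[none, "10"] <- TRUE
  }

  # multiplicative death model, capped at 1; risk-0 items force survival
  rr <- setNames(rep(1, length(labs)), labs)
  if (!is.null(config$death_relative_risks)) {
    rr[names(config$death_relative_risks)] <- config$death_relative_risks
  }
  zero <- M[, rr == 0, drop = FALSE]
  lp <- as.vector(M[, rr > 0, drop = FALSE] %*% log(rr[rr > 0]))
  p_death <- pmin(1, config$baseline_death_prob * exp(lp))
  p_death[rowSums(zero) > 0L] <- 0
  dead <- runif(n) < p_death

  # demographics and stay
  municipality <- sprintf("%06d", 350000L + sample.int(600L, n, replace = TRUE))
  hospital <- sprintf("%07d", 2000000L + sample.int(200L, n, replace = TRUE))
  admission <- as.Date("2014-01-01") +
    sample.int(as.integer(as.Date("2019-12-31") - as.Date("2014-01-01")) + 1L,
               n, replace = TRUE) - 1L
  age <- sample(10:49, n, replace = TRUE)
  # d in [30, 320] keeps the completed age exactly `age` at any age <= 49
  birth <- admission - (age * 365L + sample(30:320, n, replace = TRUE))
  los <- pmin(rpois(n, 3), 30L)
  procedures <- default_obstetric_procedures()
  procedure <- sample(procedures, n, replace = TRUE)

  # diagnosis codes per episode: childbirth code is principal when present,
  # otherwise the first drawn item in catalogue order; the principal is
  # repeated on every claim of the episode
  codes <- representative_codes()[labs]
  first_item <- labs[max.col(M, ties.method = "first")]
  principal_item <- if ("10" %in% labs) ifelse(M[, "10"], "10", first_item) else first_item
  principal <- unname(codes[principal_item])
  sec_items <- vector("list", n)
  sec_items[] <- list(character(0))
  multi <- which(rowSums(M) > 1L)
  if (length(multi)) {
    ww <- which(M[multi, , drop = FALSE], arr.ind = TRUE)
    by_row <- split(labs[ww[, "col"]], ww[, "row"])
    rows <- multi[as.integer(names(by_row))]
    sec_items[rows] <- Map(function(ls, pi) unname(codes[setdiff(ls, pi)]),
                           by_row, principal_item[rows])
  }

  split <- runif(n) < config$transfer_prob
  n_claims <- ifelse(split, 2L + (runif(n) < 0.15), 1L)
  gap_p <- config$gap_days_distribution
  gap_levels <- as.integer(names(gap_p))
  final_reason <- ifelse(dead, "in_hospital_death", "alive")

  sec_matrix <- function(si, k) {
    # distribute an episode's secondary codes over its k claims (11 slots each)
    sec <- matrix(NA_character_, k, 11L)
    if (length(si)) {
      at <- if (k == 1L) rep(1L, length(si)) else
        sample.int(k, length(si), replace = TRUE)
      for (j in unique(at)) {
        mine <- si[at == j]
        sec[j, seq_len(min(length(mine), 11L))] <- head(mine, 11L)
      }
    }
    sec
  }

  # single-claim episodes: fully vectorised
  s1 <- which(!split)
  len1 <- lengths(sec_items[s1])
  sec1 <- matrix(NA_character_, length(s1), 11L)
  if (any(len1 > 0L)) {
    ri <- rep(seq_along(s1), pmin(len1, 11L))
    ci <- unlist(lapply(pmin(len1, 11L), seq_len), use.names = FALSE)
    sec1[cbind(ri, ci)] <- unlist(lapply(sec_items[s1], head, 11L),
                                  use.names = FALSE)
  }
  single <- tibble::tibble(
    hospital_code = hospital[s1], municipality = municipality[s1],
    birth_date = birth[s1], admission_date = admission[s1],
    discharge_date = admission[s1] + los[s1],
    discharge_reason = final_reason[s1], diag_principal = principal[s1],
    !!!setNames(lapply(1:11, function(cc) sec1[, cc]), paste0("diag_sec_", 1:11)),
    procedure_code = procedure[s1]
  )

  # split episodes: small loop (transfer_prob is low)
  split_rows <- lapply(which(split), function(i) {
    k <- n_claims[i]
    cuts <- sort(sample.int(los[i] + 1L, k - 1L, replace = TRUE) - 1L)
    d <- diff(c(0L, cuts, los[i]))
    adm <- disc <- rep(admission[i], k)
    hosp <- rep(hospital[i], k)
    reason <- rep(final_reason[i], k)
    for (j in seq_len(k - 1L)) {
      disc[j] <- adm[j] + d[j]
      reason[j] <- sample(c("stay", "transfer"), 1L)
      if (reason[j] == "transfer") {
        hosp[(j + 1L):k] <- sprintf("%07d", 2000000L + sample.int(200L, 1L))
      }
      adm[j + 1L] <- disc[j] + sample(gap_levels, 1L, prob = gap_p)
    }
    disc[k] <- adm[k] + d[k]
    sec <- sec_matrix(sec_items[[i]], k)
    tibble::tibble(
      hospital_code = hosp, municipality = municipality[i],
      birth_date = birth[i], admission_date = adm, discharge_date = disc,
      discharge_reason = reason, diag_principal = principal[i],
      !!!setNames(lapply(1:11, function(cc) sec[, cc]), paste0("diag_sec_", 1:11)),
      procedure_code = procedure[i]
    )
  })
  claims <- dplyr::bind_rows(c(list(single), split_rows))
  claims$claim_id <- sprintf("C%07d", seq_len(nrow(claims)))
  claims <- claims[sample.int(nrow(claims)), claims_columns()]
  claims
}

#' Generate a synthetic death registry
#'
#' Emulates a mortality information system: each death-discharged claim is
#' represented with probability `coverage`, carrying the patient's date of
#' birth and municipality and a death date inside the final claim's stay.
#'
#' @param claims Claims tibble from [generate_claims()].
#' @param coverage Probability in `[0,1]` that a death appears in the
#'   registry.
#' @param seed Integer RNG seed.
#' @return Tibble `birth_date, municipality, death_date`.
#' @export
generate_death_registry <- function(claims, coverage = 1, seed = 1L) {
  if (!is.numeric(coverage) || coverage < 0 || coverage > 1) {
    stop("invalid probability for coverage", call. = FALSE)
  }
  set.seed(as.integer(seed))
  d <- claims[claims$discharge_reason == "in_hospital_death", , drop = FALSE]
  keep <- runif(nrow(d)) < coverage
  d <- d[keep, , drop = FALSE]
  span <- as.integer(d$discharge_date - d$admission_date)
  death_date <- d$admission_date +
    floor(runif(nrow(d)) * (span + 1L))
  tibble::tibble(birth_date = d$birth_date,
                 municipality = d$municipality,
                 death_date = death_date)
}

#' Write / read the claims CSV dialect
#'
#' Columns: `claim_id, hospital_code, municipality, birth_date,
#' admission_date, discharge_date, discharge_reason, diag_principal,
#' diag_sec_1..diag_sec_11, procedure_code`; all dates ISO-8601. When
#' adapting real claims extracts, map the native column names onto this
#' layout (hospital identifier, municipality of residence, patient date of
#' birth, admission/discharge dates, discharge reason recoded to
#' `alive | in_hospital_death | transfer | stay | other`, principal plus up
#' to 11 secondary ICD-10 diagnoses, principal procedure code).
#'
#' @param claims Claims tibble.
#' @param path CSV path.
#' @return `write_claims` returns `path` invisibly; `read_claims` returns a
#'   claims tibble.
#' @export
write_claims <- function(claims, path) {
  readr::write_csv(claims[, claims_columns()], path, na = "")
  invisible(path)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  col_spec <- readr::cols(.default = readr::col_character(),
                      birth_date = readr::col_date(),
                      admission_date = readr::col_date(),
                      discharge_date = readr::col_date())
  claims <- readr::read_csv(path, col_types = col_spec, na = c("", "NA"))
  if (!"claim_id" %in% names(claims)) {
    claims$claim_id <- sprintf("C%07d", seq_len(nrow(claims)))
  }
  claims[, claims_columns()]
}

#' Write / read a death registry CSV
#'
#' Columns `birth_date, municipality, death_date`, dates ISO-8601.
#'
#' @param registry Registry tibble.
#' @param path CSV path.
#' @export
write_death_registry <- function(registry, path) {
  readr::write_csv(registry, path, na = "")
  invisible(path)
}

#' @rdname write_death_registry
#' @export
read_death_registry <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    birth_date = readr::col_date(),
    municipality = readr::col_character(),
    death_date = readr::col_date()
  ))
}
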