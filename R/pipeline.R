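#' Run the full surveillance pipeline
#'
#' Claims (synthetic or supplied) -> episode linkage -> obstetric cohort
#' selection -> optional death confirmation against a registry ->
#' morbidity transactions -> rule mining and filtering -> report tables.
#' Artifacts written to `out_dir`: `rules.csv` (filtered rules),
#' `death_profile.csv`, `combinations.csv` and `run_metadata.json` (stage
#' counts, thresholds, seed, package version). With a fixed seed the
#' artifact set is byte-identical across runs.
#'
#' @param config Named list or path to a JSON config. Recognised fields:
#'   `n_patients`, `seed`, `baseline_death_prob`, `group_prevalences`
#'   (partial overrides of the defaults), `death_relative_risks`,
#'   `cooccurrence_pairs`, `transfer_prob`, `claims_csv` (use supplied
#'   claims instead of simulating), `confirm_deaths` (logical),
#'   `registry_csv`, `registry_coverage`, `min_support`, `min_confidence`,
#'   `min_lift`, `min_count`, `excluded_items`, `out_dir`.
#' @param out_dir Output directory; overrides the config field. Pass `NULL`
#'   explicitly to skip writing artifacts.
#' @return Invisibly, a list with every intermediate object
#'   (`claims`, `linked`, `episodes`, `cohort`, `transactions`, `db`,
#'   `rules_all`, `rules`, `death_profile`, `combinations`, `metadata`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  get <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  seed <- as.integer(get("seed", 1L))
  if (missing(out_dir)) out_dir <- get("out_dir", "results")

  if (!is.null(config$claims_csv)) {
    if (!file.exists(config$claims_csv)) {
      stop("claims file not found: ", config$claims_csv, call. = FALSE)
    }
    claims <- read_claims(config$claims_csv)
  } else {
    prev <- default_group_prevalences()
    if (!is.null(config$group_prevalences)) {
      ov <- unlist(config$group_prevalences)
      prev[names(ov)] <- ov
    }
    sim <- simulation_config(
      n_patients = get("n_patients", 100000L),
      baseline_death_prob = get("baseline_death_prob", 3e-4),
      group_prevalences = prev,
      death_relative_risks = if (!is.null(config$death_relative_risks))
        unlist(config$death_relative_risks) else NULL,
      cooccurrence_pairs = config$cooccurrence_pairs,
      transfer_prob = get("transfer_prob", 0.011),
      seed = seed
    )
    claims <- generate_claims(sim)
  }

  linked <- link_episodes(claims)
  eps <- episodes(linked)
  cohort <- select_cohort(eps)
  if (nrow(cohort) == 0L) stop("empty cohort after selection", call. = FALSE)

  confirm_log <- list(removed_unconfirmed = 0L)
  if (isTRUE(get("confirm_deaths", FALSE))) {
    registry <- if (!is.null(config$registry_csv)) {
      if (!file.exists(config$registry_csv)) {
        stop("registry file not found: ", config$registry_csv, call. = FALSE)
      }
      read_death_registry(config$registry_csv)
    } else {
      generate_death_registry(claims, coverage = get("registry_coverage", 1),
                              seed = seed + 1L)
    }
    cohort <- confirm_deaths(cohort, registry)
    confirm_log <- attr(cohort, "confirm_log")
  }

  tx <- episodes_to_transactions(cohort)
  db <- transaction_db(tx)
  mcfg <- mining_config(
    min_support = get("min_support", 1e-10),
    min_confidence = get("min_confidence", 1e-10),
    min_lift = get("min_lift", 1.1),
    min_count = get("min_count", 4L),
    excluded_items = get("excluded_items", "10")
  )
  fi <- frequent_itemsets(db, mcfg$min_support)
  rules_all <- generate_rules(fi, db, mcfg)
  rules <- filter_rules(rules_all, mcfg)
  profile <- death_profile_table(rules, db)
  combos <- combination_table(rules)

  metadata <- list(
    package_version = as.character(utils::packageVersion("morbrules")),
    seed = seed,
    thresholds = mcfg[c("min_support", "min_confidence", "min_lift",
                        "min_count", "excluded_items")],
    stages = list(
      claims = nrow(claims),
      episodes = nrow(eps),
      cohort = attr(cohort, "selection_log") %||% list(n_kept = nrow(cohort)),
      deaths_unconfirmed_removed = confirm_log$removed_unconfirmed,
      transactions = db$n,
      frequent_itemsets = nrow(fi),
      rules_generated = nrow(rules_all),
      rules_filtered = attr(rules, "filter_log"),
      rules_kept = nrow(rules)
    ),
    summary = attr(profile, "summary")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rules(rules, file.path(out_dir, "rules.csv"))
    readr::write_csv(format_profile(profile), file.path(out_dir, "death_profile.csv"),
                     na = "")
    readr::write_csv(format_combinations(combos), file.path(out_dir, "combinations.csv"),
                     na = "")
    jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(claims = claims, linked = linked, episodes = eps,
                 cohort = cohort, transactions = tx, db = db,
                 rules_all = rules_all, rules = rules,
                 death_profile = profile, combinations = combos,
                 metadata = metadata))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# printed precision: support 3 significant figures, confidence/lift 3
# decimals, death shares 1 decimal
format_profile <- function(profile) {
  if (nrow(profile) == 0L) return(profile)
  profile$support <- sprintf("%.2E", profile$support)
  profile$confidence <- round(profile$confidence, 3)
  profile$lift <- round(profile$lift, 3)
  profile
}

format_combinations <- function(combos) {
  if (nrow(combos) == 0L) return(combos)
  combos$confidence <- round(combos$confidence, 3)
  combos$lift <- round(combos$lift, 3)
  combos
}
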