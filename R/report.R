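db_item_count <- function(db, item) {
  sum(db$weights[vapply(db$itemsets, function(s) item %in% s, logical(1))])
}

group_of <- function(labels) sub("[a-e]$", "", labels)

#' Morbidity profile of episodes ending in death
#'
#' One row per single-antecedent death rule: the morbidity group and
#' subgroup, support, confidence, lift, the number of death cases carrying
#' the item, its share of all deaths (1 decimal), and per numbered group
#' the total of its subgroup case counts with the group share of deaths.
#' A `summary` attribute carries total episodes, total deaths and the death
#' percentage of episodes (2 decimals).
#'
#' @param rules Filtered rule tibble (see [filter_rules()]).
#' @param db The [transaction_db()] the rules were mined from.
#' @return Tibble, one row per single-antecedent death rule, sorted by
#'   group then subgroup.
#' @export
death_profile_table <- function(rules, db) {
  n_deaths <- db_item_count(db, "DEATH")
  summary <- list(
    n_episodes = db$n,
    n_deaths = n_deaths,
    death_pct = round(100 * n_deaths / db$n, 2)
  )
  single <- rules[rules$consequent == "DEATH" & lengths(rules$antecedent) == 1L, ,
                  drop = FALSE]
  if (nrow(single) == 0L) {
    out <- tibble::tibble(group = character(), subgroup = character(),
                          subgroup_name = character(), support = numeric(),
                          confidence = numeric(), lift = numeric(),
                          n_cases = numeric(), pct_of_deaths = numeric(),
                          group_total = numeric(),
                          group_pct_of_deaths = numeric())
    attr(out, "summary") <- summary
    return(out)
  }
  lab <- vapply(single$antecedent, `[[`, character(1), 1L)
  names_map <- item_display_names()
  out <- tibble::tibble(
    group = group_of(lab),
    subgroup = lab,
    subgroup_name = unname(names_map[lab]),
    support = single$support,
    confidence = single$confidence,
    lift = single$lift,
    n_cases = single$count,
    pct_of_deaths = round(100 * single$count / n_deaths, 1)
  )
  totals <- tapply(out$n_cases, out$group, sum)
  out$group_total <- as.vector(totals[out$group])
  out$group_pct_of_deaths <- round(100 * out$group_total / n_deaths, 1)
  out <- out[order(as.integer(out$group), out$subgroup, method = "radix"), ,
             drop = FALSE]
  attr(out, "summary") <- summary
  out
}

#' Combinations of morbidity groups in death rules
#'
#' Rows for filtered death rules with two or more antecedent items; columns
#' give the antecedent groups in canonical label order plus confidence,
#' lift and count. The `size_counts` attribute tallies how many rules
#' combine 2, 3, 4, ... groups.
#'
#' @param rules Filtered rule tibble.
#' @return Tibble sorted by antecedent labels.
#' @export
combination_table <- function(rules) {
  multi <- rules[rules$consequent == "DEATH" & lengths(rules$antecedent) >= 2L, ,
                 drop = FALSE]
  sizes <- lengths(multi$antecedent)
  kmax <- max(c(sizes, 2L))
  cols <- lapply(seq_len(kmax), function(k)
    vapply(multi$antecedent, function(a)
      if (length(a) >= k) a[k] else NA_character_, character(1)))
  out <- tibble::as_tibble(setNames(cols, paste0("group_", seq_len(kmax))))
  out$confidence <- multi$confidence
  out$lift <- multi$lift
  out$count <- multi$count
  key <- vapply(multi$antecedent, paste, character(1), collapse = "\x1f")
  out <- out[order(key, method = "radix"), , drop = FALSE]
  attr(out, "size_counts") <- table(factor(sizes, levels = 2:max(c(sizes, 4L))))
  out
}
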