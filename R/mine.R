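#' Transaction database for rule mining
#'
#' Collapses transactions to unique itemsets with multiplicity weights;
#' `n` is the total number of records (the denominator of the support
#' metric). Accepts either the transaction tibble produced by
#' [episodes_to_transactions()] (the outcome item is appended to the
#' diagnosis items) or a plain list of character itemsets, optionally
#' weighted, which allows large databases stated as profile counts to be
#' represented without materialising every record.
#'
#' @param transactions Transaction tibble or list of character vectors.
#' @param weights Optional positive integer multiplicities, one per
#'   transaction.
#' @return A `transaction_db` with elements `itemsets`, `weights`, `n`,
#'   `items` (the sorted item universe).
#' @export
transaction_db <- function(transactions, weights = NULL) {
  if (is.data.frame(transactions)) {
    stopifnot(all(c("items", "outcome_item") %in% names(transactions)))
    if (nrow(transactions) == 0L) stop("empty transaction database", call. = FALSE)
    # hash profiles first; only the unique ones are materialised as itemsets
    key <- paste(vapply(transactions$items, paste, character(1),
                        collapse = "\x1f"),
                 transactions$outcome_item, sep = "\x1f")
    if (is.null(weights)) weights <- rep(1, nrow(transactions))
    stopifnot(length(weights) == nrow(transactions), all(weights >= 1))
    u <- !duplicated(key)
    grp <- match(key, key[u])
    itemsets <- Map(function(it, oc) sort(unique(c(it, oc)), method = "radix"),
                    transactions$items[u], transactions$outcome_item[u])
  } else if (is.list(transactions)) {
    itemsets <- transactions
    if (length(itemsets) == 0L) stop("empty transaction database", call. = FALSE)
    if (is.null(weights)) weights <- rep(1, length(itemsets))
    stopifnot(length(weights) == length(itemsets), all(weights >= 1))
    itemsets <- lapply(itemsets, function(x) sort(unique(as.character(x)),
                                                  method = "radix"))
    key <- vapply(itemsets, paste, character(1), collapse = "\x1f")
    u <- !duplicated(key)
    grp <- match(key, key[u])
    itemsets <- itemsets[u]
  } else {
    stop("transactions must be a transaction tibble or a list of itemsets",
         call. = FALSE)
  }
  w <- as.vector(rowsum(as.numeric(weights), grp))
  uni <- unname(itemsets)
  structure(list(
    itemsets = uni,
    weights = as.numeric(w),
    n = sum(weights),
    items = sort(unique(unlist(uni, use.names = FALSE)), method = "radix")
  ), class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("<transaction_db> ", x$n, " transactions (", length(x$itemsets),
      " unique profiles), ", length(x$items), " items\n", sep = "")
  invisible(x)
}

itemset_key <- function(x) paste(x, collapse = "\x1f")

#' Frequent itemsets by level-wise Apriori
#'
#' Returns every itemset whose weighted occurrence count reaches the
#' integer floor `max(1, ceiling(min_support * n))`; with the conventional
#' minimum support of 1e-10 this means "observed at least once" at any
#' realistic database size, which is what mining rules for a rare outcome
#' requires. Candidates of size k are generated by joining frequent
#' (k-1)-itemsets and pruned unless every (k-1)-subset is frequent
#' (anti-monotonicity); counting is done against the unique weighted
#' profiles.
#'
#' @param db A [transaction_db()].
#' @param min_support Minimum support as a fraction of `n`.
#' @return Tibble with `items` (list of canonically sorted labels) and
#'   `count`, ordered by itemset size then labels.
#' @export
frequent_itemsets <- function(db, min_support = 1e-10) {
  stopifnot(inherits(db, "transaction_db"))
  floor_count <- max(1, ceiling(min_support * db$n))
  items <- db$items
  U <- length(db$itemsets)
  M <- matrix(FALSE, U, length(items), dimnames = list(NULL, items))
  for (u in seq_len(U)) M[u, db$itemsets[[u]]] <- TRUE
  w <- db$weights

  counts1 <- as.vector(crossprod(M, w))
  L <- which(counts1 >= floor_count)
  out_sets <- lapply(L, function(i) i)
  out_counts <- counts1[L]

  level <- lapply(L, function(i) i)
  level_counts <- counts1[L]
  k <- 1L
  while (length(level) >= 2L) {
    k <- k + 1L
    prev_keys <- vapply(level, paste, character(1), collapse = ",")
    # join step: pairs sharing the first k-2 items
    prefix <- vapply(level, function(v) paste(v[-length(v)], collapse = ","),
                     character(1))
    cands <- list()
    for (g in split(seq_along(level), prefix)) {
      if (length(g) < 2L) next
      lasts <- vapply(level[g], function(v) v[length(v)], integer(1))
      o <- order(lasts)
      g <- g[o]; lasts <- lasts[o]
      for (a in seq_len(length(g) - 1L)) {
        base <- level[[g[a]]]
        for (b in (a + 1L):length(g)) {
          cands[[length(cands) + 1L]] <- c(base, lasts[b])
        }
      }
    }
    if (!length(cands)) break
    # prune step: every (k-1)-subset must be frequent
    keep <- vapply(cands, function(cs) {
      all(vapply(seq_along(cs), function(d)
        paste(cs[-d], collapse = ",") %in% prev_keys, logical(1)))
    }, logical(1))
    cands <- cands[keep]
    if (!length(cands)) break
    cnt <- vapply(cands, function(cs)
      sum(w[rowSums(M[, cs, drop = FALSE]) == length(cs)]), numeric(1))
    ok <- cnt >= floor_count
    level <- cands[ok]
    level_counts <- cnt[ok]
    out_sets <- c(out_sets, level)
    out_counts <- c(out_counts, level_counts)
    if (!length(level)) break
  }
  labels <- lapply(out_sets, function(v) items[v])
  ord <- order(lengths(labels),
               vapply(labels, paste, character(1), collapse = "\x1f"),
               method = "radix")
  tibble::tibble(items = labels[ord], count = out_counts[ord])
}

#' Mining thresholds and consequent configuration
#'
#' Defaults reproduce the published analysis surface: minimum support and
#' confidence of 1e-10 (so rare-death rules are generated), lift at least
#' 1.1, rule observed at least 4 times, childbirth (group 10) excluded from
#' antecedents, and both discharge outcomes allowed as consequents (rules
#' concluding on live discharge are then removed by the lift filter).
#'
#' @param min_support,min_confidence Metric floors; default 1e-10.
#' @param min_lift Minimum lift kept by [filter_rules()]; default 1.1.
#' @param min_count Minimum rule occurrences kept; default 4.
#' @param excluded_items Antecedent items whose rules are dropped;
#'   default `"10"`.
#' @param consequents Outcome items allowed as rule consequents.
#' @return A `mining_config` list.
#' @export
mining_config <- function(min_support = 1e-10, min_confidence = 1e-10,
                          min_lift = 1.1, min_count = 4L,
                          excluded_items = "10",
                          consequents = c("DEATH", "ALIVE")) {
  stopifnot(min_support >= 0, min_confidence >= 0, min_lift >= 0,
            min_count >= 1)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 min_lift = min_lift, min_count = as.integer(min_count),
                 excluded_items = excluded_items, consequents = consequents),
            class = "mining_config")
}

#' Association rules from frequent itemsets
#'
#' For every frequent itemset containing exactly one outcome item Y and at
#' least one diagnosis item, emits the rule X -> Y (X the itemset minus Y)
#' with support `count(X u Y)/n`, confidence `count(X u Y)/count(X)` and
#' lift `confidence / (count(Y)/n)`. Rules whose consequent never occurs
#' in the database are undefined (division by zero support) and are
#' skipped with a warning. The empty-antecedent rule `{} -> Y` is not
#' emitted (its lift is identically 1).
#'
#' @param itemsets Result of [frequent_itemsets()] on `db`.
#' @param db The same [transaction_db()].
#' @param config A [mining_config()].
#' @return Rule tibble: `antecedent` (list of labels), `consequent`,
#'   `count`, `support`, `confidence`, `lift`.
#' @export
generate_rules <- function(itemsets, db, config = mining_config()) {
  stopifnot(inherits(db, "transaction_db"))
  keys <- vapply(itemsets$items, itemset_key, character(1))
  count_of <- setNames(itemsets$count, keys)
  outcomes <- config$consequents
  absent <- setdiff(outcomes, db$items)
  if (length(absent)) {
    warning("consequent item(s) absent from all transactions, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", nrow(itemsets))
  ri <- 0L
  for (i in seq_len(nrow(itemsets))) {
    set <- itemsets$items[[i]]
    y <- set[set %in% outcomes]
    if (length(y) != 1L || length(set) < 2L) next
    if (!y %in% db$items) next
    x <- setdiff(set, y)
    cx <- count_of[[itemset_key(x)]]
    cy <- count_of[[itemset_key(y)]]
    cxy <- itemsets$count[i]
    conf <- cxy / cx
    if (conf < config$min_confidence) next
    ri <- ri + 1L
    rows[[ri]] <- list(antecedent = x, consequent = y, count = cxy,
                       support = cxy / db$n, confidence = conf,
                       lift = conf / (cy / db$n))
  }
  rows <- rows[seq_len(ri)]
  tibble::tibble(
    antecedent = lapply(rows, `[[`, "antecedent"),
    consequent = vapply(rows, `[[`, character(1), "consequent"),
    count = vapply(rows, `[[`, numeric(1), "count"),
    support = vapply(rows, `[[`, numeric(1), "support"),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    lift = vapply(rows, `[[`, numeric(1), "lift")
  )
}

#' Remove redundant rules
#'
#' A rule is redundant when another rule with the same consequent and a
#' proper subset of its antecedent reaches at least the same confidence
#' (the extra items buy no predictive improvement). Idempotent.
#'
#' @param rules Rule tibble from [generate_rules()].
#' @return Rule tibble with redundant rules removed.
#' @export
prune_redundant <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  sizes <- lengths(rules$antecedent)
  drop <- logical(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    cand <- which(rules$consequent == rules$consequent[i] & sizes < sizes[i])
    for (j in cand) {
      if (all(rules$antecedent[[j]] %in% rules$antecedent[[i]]) &&
          rules$confidence[j] >= rules$confidence[i]) {
        drop[i] <- TRUE
        break
      }
    }
  }
  rules[!drop, , drop = FALSE]
}

#' Apply the rule selection filters
#'
#' In order: (1) lift at least `min_lift`; (2) redundancy pruning via
#' [prune_redundant()]; (3) rule count at least `min_count`; (4) removal of
#' rules whose antecedent contains an excluded item (childbirth by
#' default). The per-step removal counts are recorded in the `filter_log`
#' attribute.
#'
#' @param rules Rule tibble.
#' @param config A [mining_config()].
#' @return Filtered rule tibble.
#' @export
filter_rules <- function(rules, config = mining_config()) {
  log <- list()
  n0 <- nrow(rules)
  rules <- rules[rules$lift >= config$min_lift, , drop = FALSE]
  log$removed_lift <- n0 - nrow(rules)
  n0 <- nrow(rules)
  rules <- prune_redundant(rules)
  log$removed_redundant <- n0 - nrow(rules)
  n0 <- nrow(rules)
  rules <- rules[rules$count >= config$min_count, , drop = FALSE]
  log$removed_count <- n0 - nrow(rules)
  n0 <- nrow(rules)
  excl <- vapply(rules$antecedent,
                 function(a) any(a %in% config$excluded_items), logical(1))
  rules <- rules[!excl, , drop = FALSE]
  log$removed_excluded <- n0 - nrow(rules)
  attr(rules, "filter_log") <- log
  rules
}

#' Write rules as CSV
#'
#' Antecedent labels are semicolon-joined; metrics are written at the
#' conventional reporting precision (support to 3 significant figures in
#' scientific notation, confidence and lift to 3 decimals) unless
#' `formatted = FALSE`, which writes full precision.
#'
#' @param rules Rule tibble.
#' @param path CSV path.
#' @param formatted Apply display rounding; default TRUE.
#' @export
write_rules <- function(rules, path, formatted = TRUE) {
  out <- tibble::tibble(
    antecedent = vapply(rules$antecedent, paste, character(1), collapse = ";"),
    consequent = rules$consequent,
    count = rules$count,
    support = if (formatted) sprintf("%.2E", rules$support) else rules$support,
    confidence = if (formatted) round(rules$confidence, 3) else rules$confidence,
    lift = if (formatted) round(rules$lift, 3) else rules$lift
  )
  readr::write_csv(out, path)
  invisible(path)
}
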