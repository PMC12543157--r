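# Independent oracles used to validate the shipped implementations.
# Deliberately naive: enumeration and plain loops, no shared code paths.

# every itemset (over the full power set of the universe) with weighted
# count >= floor
oracle_itemsets <- function(itemsets, weights = rep(1, length(itemsets)),
                            floor_count = 1) {
  universe <- sort(unique(unlist(itemsets)), method = "radix")
  out_items <- list()
  out_counts <- numeric()
  for (k in seq_along(universe)) {
    combs <- utils::combn(universe, k, simplify = FALSE)
    for (cs in combs) {
      cnt <- 0
      for (i in seq_along(itemsets)) {
        if (all(cs %in% itemsets[[i]])) cnt <- cnt + weights[i]
      }
      if (cnt >= floor_count) {
        out_items[[length(out_items) + 1L]] <- cs
        out_counts <- c(out_counts, cnt)
      }
    }
  }
  list(items = out_items, count = out_counts)
}

# canonical key table for comparing itemset collections
itemset_table <- function(items, counts) {
  keys <- vapply(items, paste, character(1), collapse = "|")
  ord <- order(keys)
  data.frame(key = keys[ord], count = counts[ord])
}

# all-pairs quadratic scan for redundant rules
oracle_prune <- function(rules) {
  keep <- rep(TRUE, nrow(rules))
  for (i in seq_len(nrow(rules))) {
    for (j in seq_len(nrow(rules))) {
      if (i == j) next
      ai <- rules$antecedent[[i]]; aj <- rules$antecedent[[j]]
      if (rules$consequent[j] == rules$consequent[i] &&
          length(aj) < length(ai) && all(aj %in% ai) &&
          rules$confidence[j] >= rules$confidence[i]) {
        keep[i] <- FALSE
      }
    }
  }
  rules[keep, , drop = FALSE]
}

# plain-loop greedy chaining, written independently of link_episodes()
oracle_link <- function(claims) {
  blocks <- split(seq_len(nrow(claims)),
                  paste(claims$municipality, claims$birth_date))
  assignment <- character(nrow(claims))
  eid <- 0L
  for (b in blocks) {
    o <- b[order(claims$admission_date[b], claims$discharge_date[b],
                 claims$claim_id[b])]
    prev <- NULL
    for (i in o) {
      ok <- FALSE
      if (!is.null(prev)) {
        gap <- as.integer(claims$admission_date[i] - claims$discharge_date[prev])
        if (claims$discharge_reason[prev] %in% c("stay", "transfer") &&
            gap >= 0L && gap <= 1L &&
            (claims$discharge_reason[prev] == "transfer" ||
             claims$hospital_code[i] == claims$hospital_code[prev])) {
          ok <- TRUE
        }
      }
      if (!ok) eid <- eid + 1L
      assignment[i] <- sprintf("E%04d", eid)
      prev <- i
    }
  }
  assignment
}

# partition of claim_ids implied by an episode assignment, order-free
partition_of <- function(claim_ids, episode_ids) {
  p <- lapply(split(claim_ids, episode_ids), sort)
  unname(p[order(vapply(p, `[[`, character(1), 1L))])
}

random_transaction_list <- function(n, items, max_size = 4, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample.int(max_size, 1L)
    c(sample(items, min(k, length(items))),
      sample(c("DEATH", "ALIVE"), 1L, prob = c(0.2, 0.8)))
  })
}
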