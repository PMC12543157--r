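test_that("a one-transaction database yields its power set of itemsets", {
  db <- transaction_db(list(c("a", "DEATH")))
  fi <- frequent_itemsets(db)
  tab <- itemset_table(fi$items, fi$count)
  expect_identical(tab$key, c("DEATH", "DEATH|a", "a"))
  expect_identical(tab$count, c(1, 1, 1))
})

test_that("the support floor drops itemsets below the integer count", {
  db <- transaction_db(list(c("a", "ALIVE"), c("b", "ALIVE"), c("c", "DEATH")))
  fi <- frequent_itemsets(db, min_support = 0.5)  # floor = 2 of 3
  tab <- itemset_table(fi$items, fi$count)
  expect_identical(tab$key, "ALIVE")
  expect_identical(tab$count, 2)
  expect_identical(nrow(frequent_itemsets(db, min_support = 0.9)), 0L)
  expect_error(transaction_db(list()), "empty")
})

test_that("level-wise mining equals brute-force enumeration", {
  items <- c("1a", "2a", "3", "4a", "5", "8a", "8e", "11", "13", "10")
  for (s in 1:5) {
    trans <- random_transaction_list(sample(50:200, 1), sample(items, 8),
                                     max_size = 5, seed = s)
    db <- transaction_db(trans)
    fi <- frequent_itemsets(db)
    oracle <- oracle_itemsets(db$itemsets, db$weights, 1)
    expect_identical(itemset_table(fi$items, fi$count),
                     itemset_table(oracle$items, oracle$count))
  }
  # a higher floor and explicit weights
  trans <- random_transaction_list(120, items[1:6], max_size = 4, seed = 9)
  w <- sample(1:5, 120, replace = TRUE)
  db <- transaction_db(trans, weights = w)
  floor_count <- ceiling(0.05 * db$n)
  fi <- frequent_itemsets(db, min_support = 0.05)
  oracle <- oracle_itemsets(db$itemsets, db$weights, floor_count)
  expect_identical(itemset_table(fi$items, fi$count),
                   itemset_table(oracle$items, oracle$count))
})

test_that("itemset counts are anti-monotone", {
  trans <- random_transaction_list(150, c("a", "b", "c", "d", "e"), seed = 2)
  fi <- frequent_itemsets(transaction_db(trans))
  key <- vapply(fi$items, paste, character(1), collapse = "|")
  cnt <- stats::setNames(fi$count, key)
  for (i in which(lengths(fi$items) > 1)) {
    s <- fi$items[[i]]
    for (d in seq_along(s)) {
      expect_gte(cnt[[paste(s[-d], collapse = "|")]], fi$count[i])
    }
  }
})

test_that("rule metrics reproduce the printed worked examples", {
  # 113 deaths with obstetric haemorrhage in 2,742,467 episodes
  db <- profile_db(list(list(items = c("3", "DEATH"), w = 113),
                        list(items = c("3", "ALIVE"), w = 26500)))
  rules <- generate_rules(frequent_itemsets(db), db)
  r <- rules[vapply(rules$antecedent, identical, logical(1), "3") &
               rules$consequent == "DEATH", ]
  expect_identical(signif(r$support, 3), 4.12e-5)
  expect_identical(r$count, 113)

  # antecedent profile seen 8 times, 6 of them deaths
  db2 <- profile_db(list(list(items = c("1a", "8a", "DEATH"), w = 6),
                         list(items = c("1a", "8a", "ALIVE"), w = 2)))
  rules2 <- generate_rules(frequent_itemsets(db2), db2)
  r2 <- rules2[vapply(rules2$antecedent, identical, logical(1),
                      c("1a", "8a")) & rules2$consequent == "DEATH", ]
  expect_identical(round(r2$confidence, 3), 0.750)
  expect_identical(round(r2$lift, 3), 2475.151)
})

test_that("independent antecedent and consequent give lift exactly 1", {
  db <- transaction_db(list(c("A", "DEATH"), c("A", "ALIVE"),
                            c("B", "DEATH"), c("B", "ALIVE")))
  rules <- generate_rules(frequent_itemsets(db), db)
  a_death <- rules[vapply(rules$antecedent, identical, logical(1), "A") &
                     rules$consequent == "DEATH", ]
  expect_identical(a_death$lift, 1)
})

test_that("metric identities hold to 1e-12 on mined rules", {
  trans <- random_transaction_list(200, c("1a", "2a", "3", "8a", "8e", "11"),
                                   max_size = 5, seed = 7)
  db <- transaction_db(trans)
  fi <- frequent_itemsets(db)
  rules <- generate_rules(fi, db)
  expect_gt(nrow(rules), 10)
  key <- vapply(fi$items, paste, character(1), collapse = "|")
  cnt <- stats::setNames(fi$count, key)
  for (i in seq_len(nrow(rules))) {
    supp_x <- cnt[[paste(rules$antecedent[[i]], collapse = "|")]] / db$n
    supp_y <- cnt[[rules$consequent[i]]] / db$n
    expect_lt(abs(rules$support[i] - rules$count[i] / db$n), 1e-12)
    expect_lt(abs(rules$confidence[i] - rules$support[i] / supp_x), 1e-12)
    expect_lt(abs(rules$lift[i] * supp_y - rules$confidence[i]), 1e-12)
    expect_lte(rules$support[i], supp_x + 1e-12)
    expect_lte(rules$support[i], supp_y + 1e-12)
  }
})

test_that("a consequent absent from the database is skipped with a warning", {
  db <- transaction_db(list(c("a", "ALIVE"), c("b", "ALIVE")))
  fi <- frequent_itemsets(db)
  expect_warning(rules <- generate_rules(fi, db), "absent")
  expect_false("DEATH" %in% rules$consequent)
  expect_true(all(rules$consequent == "ALIVE"))
})

test_that("redundant rules are removed exactly as defined", {
  r <- make_rules(list("A", c("A", "B")), c(0.5, 0.5))
  expect_identical(prune_redundant(r)$antecedent, list("A"))
  r2 <- make_rules(list("A", c("A", "B")), c(0.5, 0.6))
  expect_identical(nrow(prune_redundant(r2)), 2L)
  # different consequents never shadow each other
  r3 <- make_rules(list("A", c("A", "B")), c(0.5, 0.4),
                   consequent = c("DEATH", "ALIVE"))
  expect_identical(nrow(prune_redundant(r3)), 2L)
})

test_that("pruning matches the quadratic-scan oracle and is idempotent", {
  items <- c("1a", "2a", "3", "4a", "8a")
  for (s in 1:5) {
    set.seed(s)
    k <- sample(20:100, 1)
    ants <- lapply(seq_len(k), function(i)
      sort(sample(items, sample(1:3, 1))))
    rules <- make_rules(ants, round(runif(k), 2),
                        consequent = sample(c("DEATH", "ALIVE"), k,
                                            replace = TRUE))
    got <- prune_redundant(rules)
    want <- oracle_prune(rules)
    expect_identical(as.data.frame(got), as.data.frame(want))
    expect_identical(as.data.frame(prune_redundant(got)), as.data.frame(got))
  }
})

test_that("selection filters drop low-lift, rare, and childbirth rules", {
  rules <- make_rules(
    list("2a", "3", "8a", c("10", "2a"), "5"),
    c(0.5, 0.5, 0.5, 0.5, 0.5))
  rules$lift <- c(1.05, 2, 2, 2, 2)
  rules$count <- c(10, 3, 10, 10, 10)
  kept <- filter_rules(rules, mining_config())
  expect_identical(unlist(kept$antecedent), c("8a", "5"))
  log <- attr(kept, "filter_log")
  expect_identical(log$removed_lift, 1L)
  expect_identical(log$removed_count, 1L)
  expect_identical(log$removed_excluded, 1L)
})
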