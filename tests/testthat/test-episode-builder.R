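test_that("chaining predicate follows the stay/transfer one-day rule", {
  prev_transfer <- make_claim(claim_id = "A", hospital_code = "H1",
                              discharge_reason = "transfer")
  nxt <- make_claim(claim_id = "B", hospital_code = "H2",
                    admission_date = prev_transfer$discharge_date + 1)
  expect_true(chainable(prev_transfer, nxt))

  prev_alive <- make_claim(discharge_reason = "alive")
  nxt0 <- make_claim(admission_date = prev_alive$discharge_date)
  expect_false(chainable(prev_alive, nxt0))

  prev_stay <- make_claim(discharge_reason = "stay")
  late <- make_claim(admission_date = prev_stay$discharge_date + 2)
  expect_false(chainable(prev_stay, late))

  same_day <- make_claim(hospital_code = "H1",
                         admission_date = prev_stay$discharge_date)
  expect_true(chainable(prev_stay, same_day))
  other_hospital <- make_claim(hospital_code = "H9",
                               admission_date = prev_stay$discharge_date)
  expect_false(chainable(prev_stay, other_hospital))

  overlapping <- make_claim(admission_date = prev_stay$discharge_date - 1)
  expect_false(chainable(prev_stay, overlapping))
})

test_that("a single claim forms a single episode", {
  linked <- link_episodes(make_claim())
  expect_identical(length(unique(linked$episode_id)), 1L)
  ep <- episodes(linked)
  expect_identical(nrow(ep), 1L)
  expect_identical(ep$n_claims, 1L)
})

test_that("stay-linked claims merge into one episode with the last claim's outcome", {
  c1 <- make_claim(claim_id = "A", discharge_reason = "stay",
                   admission_date = as.Date("2016-03-01"),
                   discharge_date = as.Date("2016-03-04"))
  c2 <- make_claim(claim_id = "B", admission_date = as.Date("2016-03-05"),
                   discharge_date = as.Date("2016-03-09"),
                   discharge_reason = "in_hospital_death")
  ep <- episodes(link_episodes(dplyr::bind_rows(c1, c2)))
  expect_identical(nrow(ep), 1L)
  expect_identical(ep$n_claims, 2L)
  expect_identical(ep$outcome, "in_hospital_death")
  expect_identical(ep$admission_date, as.Date("2016-03-01"))
  expect_identical(ep$discharge_date, as.Date("2016-03-09"))
})

test_that("invalid inputs are rejected", {
  dup <- dplyr::bind_rows(make_claim(claim_id = "X"),
                          make_claim(claim_id = "X"))
  expect_error(link_episodes(dup), "duplicate claim_id")
  bad <- make_claim(discharge_date = as.Date("2016-02-01"))
  expect_error(link_episodes(bad), "discharge_date before")
  old <- make_claim(birth_date = as.Date("2017-01-01"))
  expect_error(link_episodes(old), "birth_date")
})

test_that("linkage partitions the claims and ignores input order", {
  cl <- generate_claims(simulation_config(1500, transfer_prob = 0.5, seed = 31))
  linked <- link_episodes(cl)
  expect_setequal(linked$claim_id, cl$claim_id)
  expect_identical(sum(table(linked$episode_id)), nrow(cl))

  set.seed(1)
  shuffled <- cl[sample.int(nrow(cl)), ]
  linked2 <- link_episodes(shuffled)
  expect_identical(partition_of(linked$claim_id, linked$episode_id),
                   partition_of(linked2$claim_id, linked2$episode_id))
})

test_that("greedy linkage matches the plain-loop oracle on random blocks", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(5:20, 1)
    base <- as.Date("2016-01-01")
    claims <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      adm <- base + sample(0:12, 1)
      make_claim(
        claim_id = sprintf("C%02d", i),
        hospital_code = sample(c("H1", "H2"), 1),
        municipality = sample(c("350001", "350002"), 1),
        birth_date = as.Date(sample(c("1990-05-10", "1985-02-20"), 1)),
        admission_date = adm,
        discharge_date = adm + sample(0:4, 1),
        discharge_reason = sample(c("alive", "stay", "transfer",
                                    "in_hospital_death"), 1))
    }))
    linked <- link_episodes(claims)
    oracle <- oracle_link(claims)
    expect_identical(partition_of(linked$claim_id, linked$episode_id),
                     partition_of(claims$claim_id, oracle))
  }
})

test_that("single-claim episode share tracks the transfer probability", {
  p <- 0.3
  cl <- generate_claims(simulation_config(5000, transfer_prob = p, seed = 17))
  ep <- episodes(link_episodes(cl))
  share <- mean(ep$n_claims == 1L)
  sd3 <- 3 * sqrt(p * (1 - p) / 5000)
  expect_gt(share, 1 - p - sd3)
  expect_lt(share, 1 - p + sd3)
})

test_that("age is counted in completed years at episode admission", {
  adm <- as.Date("2016-03-01")
  on_birthday <- make_claim(birth_date = as.Date("2006-03-01"),
                            admission_date = adm)
  day_before <- make_claim(birth_date = as.Date("2006-03-02"),
                           admission_date = adm)
  expect_identical(episodes(link_episodes(on_birthday))$age_years, 10L)
  expect_identical(episodes(link_episodes(day_before))$age_years, 9L)
})
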