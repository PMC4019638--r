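test_that("sequence generation rule maps each method correctly", {
  cases <- list(
    computer_rng = "low", random_number_table = "low",
    coin_toss_or_equivalent = "low", quasi_random = "high",
    not_described = "unclear"
  )
  f <- adequate_record()[rep(1, length(cases)), ]
  f$sequence_method <- names(cases)
  expect_equal(as.character(assess_sequence_generation(f)),
               unname(unlist(cases)))
})

test_that("allocation concealment needs central allocation or all three envelope safeguards", {
  env <- function(s1, s2, s3) {
    adequate_record(allocation_method = "envelopes",
                    sequentially_numbered = s1, opaque = s2, sealed = s3)
  }
  expect_equal(as.character(assess_allocation_concealment(env(TRUE, TRUE, TRUE))), "low")
  # any safeguard false or undescribed drops to unclear
  for (bad in list(c(TRUE, TRUE, FALSE), c(TRUE, NA, TRUE), c(FALSE, FALSE, FALSE))) {
    expect_equal(as.character(assess_allocation_concealment(
      env(bad[1], bad[2], bad[3]))), "unclear")
  }
  expect_equal(as.character(assess_allocation_concealment(
    adequate_record(allocation_method = "central_allocation"))), "low")
  expect_equal(as.character(assess_allocation_concealment(
    adequate_record(allocation_method = "open_or_predictable"))), "high")
  expect_equal(as.character(assess_allocation_concealment(
    adequate_record(allocation_method = "not_described"))), "unclear")
  expect_equal(as.character(assess_allocation_concealment(
    adequate_record(allocation_method = "other_concealed_claim"))), "unclear")
})

test_that("blinding items follow blinded/unblinded/undescribed with the objective-outcome override", {
  rec <- function(...) adequate_record(...)
  expect_equal(as.character(assess_blinding(rec(), "participants_personnel")), "low")
  expect_equal(as.character(assess_blinding(
    rec(personnel_blinded = "no"), "participants_personnel")), "high")
  expect_equal(as.character(assess_blinding(
    rec(personnel_blinded = "no", outcome_objective = TRUE),
    "participants_personnel")), "low")
  expect_equal(as.character(assess_blinding(
    rec(personnel_blinded = "not_described"), "participants_personnel")), "unclear")
  expect_equal(as.character(assess_blinding(
    rec(assessor_blinded = "no"), "outcome_assessment")), "high")
  expect_equal(as.character(assess_blinding(
    rec(assessor_blinded = "not_described"), "outcome_assessment")), "unclear")
  # override can be disabled in the rule config
  off <- rob_rules(objective_outcome_override = FALSE)
  expect_equal(as.character(assess_blinding(
    rec(assessor_blinded = "no", outcome_objective = TRUE),
    "outcome_assessment", rules = off)), "high")
})

test_that("incomplete-data rule: ITT plus <=20% dropout is low, >20% is high, gap is unclear", {
  expect_equal(as.character(assess_incomplete_data(
    adequate_record(dropout_rate = 0.15, itt_performed = TRUE))), "low")
  expect_equal(as.character(assess_incomplete_data(
    adequate_record(dropout_rate = 0.20, itt_performed = TRUE))), "low")
  for (itt in c(TRUE, FALSE)) {
    expect_equal(as.character(assess_incomplete_data(
      adequate_record(dropout_rate = 0.25, itt_performed = itt))), "high")
  }
  expect_equal(as.character(assess_incomplete_data(
    adequate_record(dropout_rate = 0.10, itt_performed = FALSE))), "unclear")
  # severity is non-decreasing in dropout, holding the rest fixed
  sev <- vapply(seq(0, 1, by = 0.05), function(d) {
    as.integer(assess_incomplete_data(adequate_record(dropout_rate = d)))
  }, integer(1))
  expect_true(all(diff(sev) >= 0))
  # threshold is configurable
  loose <- rob_rules(dropout_max_low = 0.30)
  expect_equal(as.character(assess_incomplete_data(
    adequate_record(dropout_rate = 0.25), rules = loose)), "low")
})

test_that("selective reporting distinguishes complete, incomplete and suppressed reporting", {
  rec <- function(p, s, r) {
    adequate_record(primary_outcomes_declared = p,
                    secondary_outcomes_declared = s,
                    outcomes_reported = r)
  }
  expect_equal(as.character(assess_selective_reporting(
    rec("P1", c("S1", "S2"), c("P1", "S1", "S2")))), "low")
  # missing primary outcome is always high
  expect_equal(as.character(assess_selective_reporting(
    rec("P1", character(0), "S1"))), "high")
  # 8 of 10 secondaries missing (80% > 70%) is high
  expect_equal(as.character(assess_selective_reporting(
    rec("P1", sprintf("S%d", 1:10), c("P1", "S1", "S2")))), "high")
  # exactly 70% missing is NOT high (strict threshold), but not complete
  expect_equal(as.character(assess_selective_reporting(
    rec("P1", sprintf("S%d", 1:10), c("P1", "S1", "S2", "S3")))), "unclear")
  # a new outcome added in the results blocks a low rating
  expect_equal(as.character(assess_selective_reporting(
    rec("P1", "S1", c("P1", "S1", "SURPRISE")))), "unclear")
  # no declared primary outcome violates the precondition
  expect_error(assess_selective_reporting(rec(character(0), "S1", "S1")),
               class = "robagree_precondition_error")
  # removing a reported outcome never decreases severity
  full <- c("P1", sprintf("S%d", 1:5))
  sev <- vapply(length(full):0, function(k) {
    as.integer(assess_selective_reporting(
      rec("P1", sprintf("S%d", 1:5), full[seq_len(k)])))
  }, integer(1))
  expect_true(all(diff(sev) >= 0))
})

test_that("other-bias rule over the full tri-state grid: all-yes low, any-no high, else unclear", {
  tri <- c("yes", "no", "not_described")
  grid <- expand.grid(b = tri, c = tri, k = tri, stringsAsFactors = FALSE)
  f <- adequate_record()[rep(1, nrow(grid)), ]
  f$baseline_comparable <- grid$b
  f$cointervention_controlled <- grid$c
  f$compliance_acceptable <- grid$k
  got <- as.character(assess_other_bias(f))
  want <- apply(grid, 1, function(x) {
    if (any(x == "no")) "high" else if (all(x == "yes")) "low" else "unclear"
  })
  expect_equal(got, unname(want))
  expect_false(any(is.na(got)))
})

test_that("assess_rob is deterministic, exhaustive and composes the domain rules", {
  f <- dplyr::bind_rows(
    adequate_record("T1"),
    adequate_record("T2", sequence_method = "not_described",
                    allocation_method = "not_described",
                    participants_blinded = "not_described",
                    personnel_blinded = "not_described",
                    assessor_blinded = "not_described",
                    itt_performed = FALSE, dropout_rate = NA_real_,
                    baseline_comparable = "not_described"),
    adequate_record("T3", dropout_rate = 0.30)
  )
  out <- assess_rob(f)
  expect_equal(nrow(out), 21L)
  expect_equal(unname(table(out$trial_id)), rep(7L, 3), ignore_attr = TRUE)
  expect_identical(out, assess_rob(f))
  # best case: all seven low
  expect_true(all(out$rating[out$trial_id == "T1"] == "low"))
  # fully undescribed: no domain can be rated low or high on enumerables
  t2 <- out[out$trial_id == "T2", ]
  enum <- c("sequence_generation", "allocation_concealment",
            "blinding_participants_personnel", "blinding_outcome_assessment",
            "other_bias")
  expect_true(all(t2$rating[t2$domain %in% enum] == "unclear"))
  # a single dropout defect flags only incomplete outcome data
  t3 <- out[out$trial_id == "T3", ]
  expect_equal(as.character(t3$rating[t3$domain == "incomplete_outcome_data"]), "high")
  expect_true(all(t3$rating[t3$domain != "incomplete_outcome_data"] == "low"))
})

test_that("every enumerated feature combination yields a rating", {
  # discretized grid over the enumerable rule inputs
  tri <- c("yes", "no", "not_described")
  grid <- expand.grid(
    sequence_method = c("computer_rng", "random_number_table",
                        "coin_toss_or_equivalent", "quasi_random", "not_described"),
    allocation_method = c("central_allocation", "envelopes", "other_concealed_claim",
                          "open_or_predictable", "not_described"),
    participants_blinded = tri, assessor_blinded = tri,
    dropout_rate = c(0, 0.2, 0.5), itt_performed = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  f <- adequate_record()[rep(1, nrow(grid)), ]
  for (col in names(grid)) f[[col]] <- grid[[col]]
  f$personnel_blinded <- f$participants_blinded
  f$trial_id <- sprintf("G%04d", seq_len(nrow(f)))
  out <- assess_rob(f)
  expect_false(any(is.na(out$rating)))
  expect_equal(nrow(out), 7L * nrow(grid))
})

test_that("feature CSVs parse list columns, tri-states and booleans", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("trial_id,sequence_method,allocation_method,sequentially_numbered,",
          "opaque,sealed,participants_blinded,personnel_blinded,assessor_blinded,",
          "outcome_objective,dropout_rate,itt_performed,primary_outcomes_declared,",
          "secondary_outcomes_declared,outcomes_reported,baseline_comparable,",
          "cointervention_controlled,compliance_acceptable", sep = ""),
    "T1,computer_rng,envelopes,true,true,true,yes,yes,,false,0.1,true,P1,S1;S2,P1;S1;S2,yes,,yes"
  ), tmp)
  f <- read_trial_features(tmp)
  expect_equal(f$assessor_blinded, "not_described")
  expect_equal(f$cointervention_controlled, "not_described")
  expect_equal(f$secondary_outcomes_declared[[1]], c("S1", "S2"))
  expect_true(f$sealed)
  out <- assess_rob(f)
  expect_equal(as.character(out$rating[out$domain == "allocation_concealment"]), "low")
  writeLines(c("trial_id,sequence_method,allocation_method,dropout_rate",
               "T1,telepathy,envelopes,0.1"), tmp)
  expect_error(read_trial_features(tmp), class = "robagree_parse_error")
})
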