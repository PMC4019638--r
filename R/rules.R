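#' Decision-rule configuration
#'
#' The numeric thresholds in the incomplete-data and selective-reporting
#' rules, and the blinding override for objective outcomes, are configurable;
#' the defaults are the pre-specified rules the package implements.
#'
#' @param dropout_max_low Maximum drop-out fraction compatible with a low
#'   rating for incomplete outcome data (default 0.20). Drop-out strictly
#'   above this is high risk.
#' @param secondary_missing_high Fraction of declared secondary outcomes that
#'   must be missing from the results, *strictly exceeded*, before selective
#'   reporting is rated high (default 0.70).
#' @param objective_outcome_override If `TRUE` (default) a trial whose
#'   outcome is judged insensitive to lack of blinding (`outcome_objective`)
#'   is rated low on the blinding items even when unblinded — the standard
#'   Cochrane convention. `outcome_objective` itself defaults to `FALSE` per
#'   record, so the override only acts when a record explicitly claims it.
#' @return A list of class `rob_rules`.
#' @export
rob_rules <- function(dropout_max_low = 0.20, secondary_missing_high = 0.70,
                      objective_outcome_override = TRUE) {
  stopifnot(is.numeric(dropout_max_low), dropout_max_low >= 0, dropout_max_low <= 1,
            is.numeric(secondary_missing_high), secondary_missing_high >= 0,
            secondary_missing_high <= 1, is.logical(objective_outcome_override))
  structure(
    list(dropout_max_low = dropout_max_low,
         secondary_missing_high = secondary_missing_high,
         objective_outcome_override = objective_outcome_override),
    class = "rob_rules"
  )
}

#' Domain decision rules
#'
#' Each `assess_*()` function maps structured trial features to one domain's
#' low/unclear/high rating, vectorised over the rows of a feature tibble
#' (one row per trial; see [read_trial_features()] for the column schema).
#' [assess_rob()] applies all of them and returns a long ratings tibble with
#' exactly seven item ratings per trial. The rules are deterministic:
#' identical records always yield identical ratings.
#'
#' The rules, in brief:
#' * **Sequence generation** — computer random-number generation, random
#'   number tables and coin tossing (or equivalent) are adequate (low);
#'   quasi-random assignment is high; an undescribed method is unclear.
#' * **Allocation concealment** — low only for central allocation (telephone,
#'   web-based or centre-controlled randomisation) or envelopes with all
#'   three safeguards described: sequentially numbered, opaque and sealed.
#'   Envelopes missing any safeguard, other unverifiable concealment claims
#'   and undescribed methods are unclear; an open or predictable schedule is
#'   high.
#' * **Blinding (two items)** — low when the relevant parties are blinded
#'   (both participants and personnel for the first item; the outcome
#'   assessor for the second); high when any relevant party is unblinded,
#'   unless the outcome is objective and the override is enabled; unclear
#'   when blinding status is not described.
#' * **Incomplete outcome data** — low when an intention-to-treat analysis
#'   was conducted and the drop-out rate was at most 20%; high whenever the
#'   drop-out rate exceeds 20%; the remaining case (acceptable drop-out but
#'   no ITT) is unclear.
#' * **Selective reporting** — low only when every declared primary and
#'   secondary outcome appears in the results and no undeclared outcome was
#'   added; high when any declared primary outcome is missing, or when more
#'   than 70% of declared secondary outcomes are missing; otherwise unclear.
#' * **Other bias** — baseline comparability, control of co-interventions
#'   and acceptable compliance: all three met is low, any explicit failure is
#'   high, otherwise unclear.
#'
#' @param features Tibble of trial-feature records.
#' @param item Which blinding item to assess.
#' @param rules A [rob_rules()] configuration.
#' @return `assess_*()`: an ordered rating factor of length `nrow(features)`.
#'   `assess_rob()`: a long tibble `trial_id`, `domain`, `rating`.
#' @examples
#' f <- tibble::tibble(
#'   trial_id = "T1", sequence_method = "computer_rng",
#'   allocation_method = "central_allocation",
#'   sequentially_numbered = NA, opaque = NA, sealed = NA,
#'   participants_blinded = "yes", personnel_blinded = "yes",
#'   assessor_blinded = "yes", outcome_objective = FALSE,
#'   dropout_rate = 0.1, itt_performed = TRUE,
#'   primary_outcomes_declared = list("pain"),
#'   secondary_outcomes_declared = list("function"),
#'   outcomes_reported = list(c("pain", "function")),
#'   baseline_comparable = "yes", cointervention_controlled = "yes",
#'   compliance_acceptable = "yes"
#' )
#' assess_rob(f)
#' @export
assess_sequence_generation <- function(features) {
  map <- c(computer_rng = "low", random_number_table = "low",
           coin_toss_or_equivalent = "low", quasi_random = "high",
           not_described = "unclear")
  v <- as.character(features$sequence_method)
  bad <- !v %in% names(map)
  if (any(bad)) {
    abort(paste0("Unknown sequence_method: ", unique(v[bad])[1]),
          class = "robagree_parse_error")
  }
  rob_factor(unname(map[v]))
}

#' @rdname assess_sequence_generation
#' @export
assess_allocation_concealment <- function(features) {
  v <- as.character(features$allocation_method)
  ok <- c("central_allocation", "envelopes", "other_concealed_claim",
          "open_or_predictable", "not_described")
  bad <- !v %in% ok
  if (any(bad)) {
    abort(paste0("Unknown allocation_method: ", unique(v[bad])[1]),
          class = "robagree_parse_error")
  }
  safeguards_ok <- mapply(function(a, b, c) isTRUE(a) && isTRUE(b) && isTRUE(c),
                          features$sequentially_numbered, features$opaque,
                          features$sealed)
  out <- dplyr::case_when(
    v == "central_allocation" ~ "low",
    v == "envelopes" & safeguards_ok ~ "low",
    v == "envelopes" ~ "unclear",
    v == "open_or_predictable" ~ "high",
    TRUE ~ "unclear"   # not_described, other_concealed_claim
  )
  rob_factor(out)
}

#' @rdname assess_sequence_generation
#' @export
assess_blinding <- function(features,
                            item = c("participants_personnel", "outcome_assessment"),
                            rules = rob_rules()) {
  item <- match.arg(item)
  objective <- !is.na(features$outcome_objective) & features$outcome_objective &
    rules$objective_outcome_override
  if (item == "participants_personnel") {
    p <- features$participants_blinded
    s <- features$personnel_blinded
    out <- dplyr::case_when(
      (p == "no" | s == "no") & objective ~ "low",
      p == "no" | s == "no" ~ "high",
      p == "yes" & s == "yes" ~ "low",
      TRUE ~ "unclear"
    )
  } else {
    a <- features$assessor_blinded
    out <- dplyr::case_when(
      a == "no" & objective ~ "low",
      a == "no" ~ "high",
      a == "yes" ~ "low",
      TRUE ~ "unclear"
    )
  }
  rob_factor(out)
}

#' @rdname assess_sequence_generation
#' @export
assess_incomplete_data <- function(features, rules = rob_rules()) {
  d <- features$dropout_rate
  if (any(!is.na(d) & (d < 0 | d > 1))) {
    abort("dropout_rate must lie in [0, 1]", class = "robagree_parse_error")
  }
  itt <- !is.na(features$itt_performed) & features$itt_performed
  out <- dplyr::case_when(
    !is.na(d) & d > rules$dropout_max_low ~ "high",
    !is.na(d) & itt ~ "low",
    TRUE ~ "unclear"   # dropout acceptable but no ITT, or dropout unknown
  )
  rob_factor(out)
}

#' @rdname assess_sequence_generation
#' @export
assess_selective_reporting <- function(features, rules = rob_rules()) {
  prim <- features$primary_outcomes_declared
  sec <- features$secondary_outcomes_declared
  rep_ <- features$outcomes_reported
  if (any(lengths(prim) == 0)) {
    abort("Every trial must declare at least one primary outcome",
          class = "robagree_precondition_error")
  }
  out <- mapply(function(p, s, r) {
    prim_missing <- length(setdiff(p, r)) > 0
    sec_missing_frac <- if (length(s) == 0) 0 else length(setdiff(s, r)) / length(s)
    new_outcomes <- length(setdiff(r, union(p, s))) > 0
    if (prim_missing || sec_missing_frac > rules$secondary_missing_high) {
      "high"
    } else if (sec_missing_frac == 0 && !new_outcomes) {
      "low"
    } else {
      "unclear"
    }
  }, prim, sec, rep_)
  rob_factor(out)
}

#' @rdname assess_sequence_generation
#' @export
assess_other_bias <- function(features) {
  crit <- cbind(features$baseline_comparable,
                features$cointervention_controlled,
                features$compliance_acceptable)
  out <- apply(crit, 1, function(x) {
    if (any(x == "no")) "high"
    else if (all(x == "yes")) "low"
    else "unclear"
  })
  rob_factor(out)
}

#' @rdname assess_sequence_generation
#' @export
assess_rob <- function(features, rules = rob_rules()) {
  if (!"trial_id" %in% names(features)) {
    abort("Feature records need a trial_id column", class = "robagree_parse_error")
  }
  ratings <- list(
    sequence_generation = assess_sequence_generation(features),
    allocation_concealment = assess_allocation_concealment(features),
    blinding_participants_personnel =
      assess_blinding(features, "participants_personnel", rules),
    blinding_outcome_assessment =
      assess_blinding(features, "outcome_assessment", rules),
    incomplete_outcome_data = assess_incomplete_data(features, rules),
    selective_reporting = assess_selective_reporting(features, rules),
    other_bias = assess_other_bias(features)
  )
  out <- purrr::map2_dfr(ratings, names(ratings), function(r, d) {
    tibble(trial_id = features$trial_id, domain = d, rating = r)
  })
  out$domain <- factor(out$domain, levels = rob_domains())
  dplyr::arrange(out, .data$trial_id, .data$domain) %>%
    dplyr::mutate(domain = as.character(.data$domain))
}
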