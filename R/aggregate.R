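#' Derive a trial's overall risk-of-bias rating
#'
#' The overall rating is the worst domain rating: a trial is low risk only if
#' every item is low, high if any item is high, and unclear in between —
#' i.e. the maximum under the order `low < unclear < high`.
#'
#' With `require_all_domains_for_low = TRUE` (the default) a trial whose
#' present ratings are all low but which is missing items cannot be rated
#' low overall (it falls back to unclear): absent information must not
#' certify the absence of bias.
#'
#' @param ratings A vector of domain ratings for one trial (at least one
#'   present rating required; `NA`s are dropped).
#' @param require_all_domains_for_low See above.
#' @param n_domains Number of items expected for a complete assessment
#'   (default 7).
#' @return A length-1 ordered rating factor.
#' @examples
#' derive_overall_rob(rep("low", 7))                     # low
#' derive_overall_rob(c(rep("low", 6), "unclear"))       # unclear
#' derive_overall_rob(c(rep("low", 6), "high"))          # high
#' @export
derive_overall_rob <- function(ratings, require_all_domains_for_low = TRUE,
                               n_domains = 7L) {
  r <- rob_factor(ratings)
  r <- r[!is.na(r)]
  if (length(r) == 0) {
    abort("Cannot derive an overall rating from zero domain ratings",
          class = "robagree_precondition_error")
  }
  out <- max(r)
  if (require_all_domains_for_low && out == "low" && length(r) < n_domains) {
    out <- rob_factor("unclear")
  }
  out
}

#' Append overall ratings to a ratings table
#'
#' Computes [derive_overall_rob()] for every `(trial_id, rater_id)` group in
#' a long ratings tibble and returns the input with the derived `"overall"`
#' rows appended. Pre-existing `"overall"` rows are left untouched and their
#' groups are skipped.
#'
#' @param ratings Long ratings tibble (see [read_rob_ratings()]).
#' @inheritParams derive_overall_rob
#' @return The input tibble with one `overall` row appended per group.
#' @export
overall_rob <- function(ratings, require_all_domains_for_low = TRUE) {
  has_overall <- ratings %>%
    dplyr::filter(.data$domain == "overall") %>%
    dplyr::distinct(.data$trial_id, .data$rater_id)
  derived <- ratings %>%
    dplyr::filter(.data$domain != "overall") %>%
    dplyr::anti_join(has_overall, by = c("trial_id", "rater_id")) %>%
    dplyr::group_by(.data$trial_id, .data$review_id, .data$rater_id) %>%
    dplyr::summarise(
      domain = "overall",
      rating = derive_overall_rob(.data$rating, require_all_domains_for_low),
      .groups = "drop"
    )
  dplyr::bind_rows(ratings, derived)
}

#' Rate a body of evidence at the meta-analysis level
#'
#' A meta-analysis inherits the rating held by the "majority of studies":
#' the category whose share of trial overall ratings reaches the majority
#' cutoff (default 60%). Because the cutoff exceeds 50%, at most one
#' category can qualify. When no category reaches the cutoff the
#' meta-analysis is rated unclear and a warning is emitted, since the
#' majority rule itself is silent on split panels.
#'
#' @param overalls Vector of trial overall ratings for one meta-analysis
#'   (non-empty; `NA`s dropped).
#' @param cutoff Majority cutoff as a fraction in (0.5, 1]; default 0.60.
#' @param inclusive If `TRUE` (default) a share exactly equal to the cutoff
#'   qualifies.
#' @return A length-1 ordered rating factor.
#' @examples
#' derive_meta_analysis_rob(c("high", "high", "high", "low", "unclear")) # high (3/5)
#' @export
derive_meta_analysis_rob <- function(overalls, cutoff = 0.60, inclusive = TRUE) {
  if (!is.numeric(cutoff) || cutoff <= 0.5 || cutoff > 1) {
    abort("Majority cutoff must lie in (0.5, 1]", class = "robagree_config_error")
  }
  r <- rob_factor(overalls)
  r <- r[!is.na(r)]
  if (length(r) == 0) {
    abort("Cannot rate a meta-analysis from zero trial ratings",
          class = "robagree_precondition_error")
  }
  share <- table(r) / length(r)
  hit <- if (inclusive) share >= cutoff else share > cutoff
  if (any(hit)) {
    rob_factor(names(share)[hit][1])
  } else {
    warn(paste0("No rating category reaches the ", round(100 * cutoff),
                "% majority cutoff; falling back to 'unclear'"),
         class = "robagree_no_majority")
    rob_factor("unclear")
  }
}

#' Meta-analysis ratings for grouped trials
#'
#' Applies [derive_meta_analysis_rob()] per meta-analysis group: trials are
#' assigned to groups by a grouping table (see [read_meta_groups()]), and
#' each trial contributes its `"overall"` rating.
#'
#' @param ratings Long ratings tibble containing `"overall"` rows (run
#'   [overall_rob()] first if needed).
#' @param groups Grouping tibble with `review_id`, `trial_id` and optionally
#'   `outcome_label`.
#' @inheritParams derive_meta_analysis_rob
#' @return Tibble with one row per `review_id`: `n_trials`, `rating`.
#' @export
meta_analysis_rob <- function(ratings, groups, cutoff = 0.60, inclusive = TRUE) {
  ov <- ratings %>%
    dplyr::filter(.data$domain == "overall", !is.na(.data$rating)) %>%
    dplyr::select("trial_id", "rating")
  joined <- dplyr::inner_join(groups, ov, by = "trial_id")
  joined %>%
    dplyr::group_by(.data$review_id) %>%
    dplyr::summarise(
      n_trials = dplyr::n(),
      rating = derive_meta_analysis_rob(.data$rating, cutoff, inclusive),
      .groups = "drop"
    )
}
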