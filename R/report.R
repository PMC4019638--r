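#' Bundled published rating tables
#'
#' Two small reference tables ship with the package:
#'
#' * `published_meta_ratings()` — the overall risk-of-bias ratings of 17
#'   physiotherapy meta-analyses as judged by a blinded external review
#'   panel and by the original Cochrane review authors, together with the
#'   published agreement/disagreement partition. One published pair (Puhan
#'   2010) sits in the disagreement section although both its printed
#'   ratings are "high"; the transcription keeps both the values and the
#'   partition verbatim, so partition-based and value-based agreement counts
#'   differ by one.
#' * `published_domain_kappas()` — the published per-item weighted kappas
#'   (with 95% CIs and interpretation labels) for the same study corpus,
#'   external panel vs Cochrane and within the external panel.
#'
#' @return A tibble (see above).
#' @export
published_meta_ratings <- function() {
  path <- system.file("extdata", "meta_rob_published.csv", package = "robagree",
                      mustWork = TRUE)
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  d$external <- rob_factor(d$external)
  d$cochrane <- rob_factor(d$cochrane)
  as_tibble(d)
}

#' @rdname published_meta_ratings
#' @export
published_domain_kappas <- function() {
  path <- system.file("extdata", "domain_kappas_published.csv", package = "robagree",
                      mustWork = TRUE)
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    domain = readr::col_character(),
                    n = readr::col_integer(),
                    label_vs_cochrane = readr::col_character(),
                    label_within_panel = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Recompute the meta-analysis-level agreement result
#'
#' Runs the agreement analysis on the bundled 17 meta-analysis rating pairs
#' ([published_meta_ratings()]): cross-tabulates external-panel vs Cochrane
#' overall ratings, computes the linearly weighted kappa, and summarises the
#' agreement structure (the published partition counts, the value-equal
#' count, and the dominant disagreement cell).
#'
#' @param weights Weight scheme, default `"linear"`.
#' @param verbose Print the report (default `TRUE`).
#' @return Invisibly, a list with `pairs`, `crosstab`, `kappa`,
#'   `kappa_2dp`, `agreements_printed`, `disagreements_printed`,
#'   `value_equal`, `top_disagreements`.
#' @export
meta_agreement_report <- function(weights = "linear", verbose = TRUE) {
  d <- published_meta_ratings()
  ct <- rob_crosstab(d$external, d$cochrane)
  k <- weighted_kappa(ct, weights = weights)
  res <- list(
    pairs = d,
    crosstab = ct,
    kappa = k,
    kappa_2dp = round(k, 2),
    agreements_printed = sum(d$printed_section == "agreement"),
    disagreements_printed = sum(d$printed_section == "disagreement"),
    value_equal = sum(diag(ct$counts)),
    top_disagreements = disagreement_cells(ct)
  )
  if (verbose) {
    cat("Overall risk of bias at the meta-analysis level:",
        "external panel vs Cochrane reviewers\n\n")
    print(ct)
    cat(sprintf("\nWeighted kappa (%s weights): %.2f\n",
                attr(kappa_weights(weights), "scheme"), res$kappa_2dp))
    cat(sprintf("Published partition: %d agreements, %d disagreements",
                res$agreements_printed, res$disagreements_printed))
    if (res$value_equal != res$agreements_printed) {
      cat(sprintf(" (note: %d pairs have identical ratings)", res$value_equal))
    }
    cat("\nLargest disagreement cell: external",
        res$top_disagreements$rater_a[1], "/ Cochrane",
        res$top_disagreements$rater_b[1], "=",
        res$top_disagreements$count[1], "meta-analyses\n")
  }
  invisible(res)
}

#' Assess a trial-feature file and write ratings
#'
#' File-level wrapper over [read_trial_features()] and [assess_rob()]:
#' reads one feature record per trial, applies the decision rules, and
#' writes the seven item ratings per trial in the canonical long ratings
#' CSV.
#'
#' @param features_csv Input feature CSV path.
#' @param out_csv Output ratings CSV path.
#' @param rules A [rob_rules()] configuration.
#' @param rater_id Rater label recorded in the output (default
#'   `"rules_engine"`).
#' @return The ratings tibble, invisibly.
#' @export
assess_rob_file <- function(features_csv, out_csv, rules = rob_rules(),
                            rater_id = "rules_engine") {
  feats <- read_trial_features(features_csv)
  ratings <- assess_rob(feats, rules = rules)
  ratings$review_id <- NA_character_
  ratings$rater_id <- rater_id
  write_rob_ratings(ratings, out_csv)
  invisible(ratings)
}

#' Run configuration files
#'
#' Reads (and writes back next to outputs) a YAML or JSON run
#' configuration. Recognised keys mirror the function arguments:
#' `weights`, `ci`, `conf_level`, `B`, `seed`, `dropout_max_low`,
#' `secondary_missing_high`, `objective_outcome_override`,
#' `majority_cutoff`, `majority_inclusive`,
#' `require_all_domains_for_low`, `split_blinding`. Unknown keys are an
#' error so typos cannot silently change an analysis.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config path.
#' @return Named list of configuration values merged over the defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(
    weights = "linear", ci = "bootstrap", conf_level = 0.95, B = 2000L,
    seed = 1L, dropout_max_low = 0.20, secondary_missing_high = 0.70,
    objective_outcome_override = TRUE, majority_cutoff = 0.60,
    majority_inclusive = TRUE, require_all_domains_for_low = TRUE,
    split_blinding = FALSE
  )
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "robagree_config_error")
  }
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @param cfg Configuration list.
#' @param path Output path (`.json` or `.yaml` by extension).
#' @export
write_run_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(cfg, path)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
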