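#' Read a ratings table
#'
#' Reads per-trial, per-domain risk-of-bias ratings from CSV. The canonical
#' layout is long — one row per `(trial_id, rater_id, domain)` with columns
#' `trial_id`, `review_id` (optional), `rater_id`, `domain`, `rating` — which
#' represents per-domain missingness cleanly (an absent row, or an empty
#' rating cell, is simply a missing rating). A wide layout with one column per
#' domain (plus optionally `overall`) is accepted on read and pivoted.
#'
#' @param path Path to a CSV file (UTF-8, header required). Lines starting
#'   with `#` are treated as comments.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @param synonyms Rating synonym table, see [rob_synonyms()].
#' @param split_blinding Some published assessments carry a single combined
#'   `blinding` judgement. If `TRUE`, such rows are duplicated into both
#'   blinding items; if `FALSE` (default) a `blinding` domain is an error.
#' @return A tibble with columns `trial_id`, `review_id`, `rater_id`,
#'   `domain`, `rating` (ordered factor). Rows with empty rating cells are
#'   dropped: missingness is represented by absence, never by a fourth
#'   category.
#' @section Errors: An unknown rating token or domain raises a parse error
#'   naming the row; a duplicated `(trial_id, rater_id, domain)` key raises an
#'   integrity error.
#' @export
read_rob_ratings <- function(path, format = c("auto", "long", "wide"),
                             synonyms = rob_synonyms(), split_blinding = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "robagree_parse_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE, show_col_types = FALSE)
  if (format == "auto") {
    format <- if (all(c("domain", "rating") %in% names(raw))) "long" else "wide"
  }
  if (format == "long") {
    need <- c("trial_id", "rater_id", "domain", "rating")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(paste0("Long ratings CSV is missing column(s): ", paste(miss, collapse = ", ")),
            class = "robagree_parse_error")
    }
    if (!"review_id" %in% names(raw)) raw$review_id <- NA_character_
    long <- raw[, c("trial_id", "review_id", "rater_id", "domain", "rating")]
  } else {
    id_cols <- intersect(c("trial_id", "review_id", "rater_id"), names(raw))
    if (!all(c("trial_id", "rater_id") %in% id_cols)) {
      abort("Wide ratings CSV needs trial_id and rater_id columns",
            class = "robagree_parse_error")
    }
    dom_cols <- intersect(c(rob_domains(), "overall", "blinding"), names(raw))
    if (length(dom_cols) == 0) {
      abort("Wide ratings CSV has no recognised domain columns",
            class = "robagree_parse_error")
    }
    if (!"review_id" %in% names(raw)) raw$review_id <- NA_character_
    long <- tidyr::pivot_longer(raw[, c("trial_id", "review_id", "rater_id", dom_cols)],
                                cols = dplyr::all_of(dom_cols),
                                names_to = "domain", values_to = "rating")
  }
  long$.row <- seq_len(nrow(long))

  if (split_blinding && any(long$domain == "blinding", na.rm = TRUE)) {
    comb <- long[long$domain %in% "blinding", ]
    rest <- long[!long$domain %in% "blinding", ]
    long <- dplyr::bind_rows(
      rest,
      dplyr::mutate(comb, domain = "blinding_participants_personnel"),
      dplyr::mutate(comb, domain = "blinding_outcome_assessment")
    )
  }
  bad_dom <- !long$domain %in% c(rob_domains(), "overall")
  if (any(bad_dom)) {
    show <- head(long$.row[bad_dom], 5L)
    abort(paste0("Unknown domain(s) at data row(s) ", paste(show, collapse = ", "),
                 ": ", paste(unique(long$domain[bad_dom]), collapse = ", "),
                 if (!split_blinding && "blinding" %in% long$domain)
                   " (use split_blinding = TRUE for combined blinding judgements)" else ""),
          class = "robagree_parse_error")
  }

  parsed <- rob_factor(long$rating, synonyms = synonyms, strict = FALSE)
  bad <- !is.na(long$rating) & trimws(long$rating) != "" & is.na(parsed)
  if (any(bad)) {
    show <- head(which(bad), 5L)
    abort(paste0("Unknown rating token(s): ",
                 paste0("'", long$rating[show], "' (data row ", long$.row[show], ")",
                        collapse = ", ")),
          class = "robagree_parse_error")
  }
  long$rating <- parsed
  long <- long[!is.na(long$rating), ]

  dup <- duplicated(long[, c("trial_id", "rater_id", "domain")])
  if (any(dup)) {
    d <- long[dup, ]
    abort(paste0("Duplicate (trial_id, rater_id, domain) key(s): ",
                 paste0(head(paste(d$trial_id, d$rater_id, d$domain, sep = "/"), 5L),
                        collapse = ", ")),
          class = "robagree_integrity_error")
  }
  long$.row <- NULL
  as_tibble(long)
}

#' Write a ratings table
#'
#' Writes a ratings tibble in the canonical long CSV layout, the inverse of
#' [read_rob_ratings()]: `write_rob_ratings()` then `read_rob_ratings()` is
#' the identity on any valid ratings collection.
#'
#' @param ratings Tibble as returned by [read_rob_ratings()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rob_ratings <- function(ratings, path) {
  out <- dplyr::mutate(ratings, rating = as.character(.data$rating))
  readr::write_csv(out[, c("trial_id", "review_id", "rater_id", "domain", "rating")], path)
  invisible(path)
}

#' Read a meta-analysis grouping table
#'
#' A grouping table assigns trials to the meta-analysis (review/outcome) they
#' contribute to; columns `review_id`, `trial_id` and optionally
#' `outcome_label`.
#'
#' @param path CSV path.
#' @return Tibble with columns `review_id`, `trial_id`, `outcome_label`.
#' @export
read_meta_groups <- function(path) {
  g <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       comment = "#", progress = FALSE, show_col_types = FALSE)
  miss <- setdiff(c("review_id", "trial_id"), names(g))
  if (length(miss) > 0) {
    abort(paste0("Grouping CSV is missing column(s): ", paste(miss, collapse = ", ")),
          class = "robagree_parse_error")
  }
  if (!"outcome_label" %in% names(g)) g$outcome_label <- NA_character_
  dup <- duplicated(g[, c("review_id", "trial_id")])
  if (any(dup)) {
    abort("Duplicate trial within a meta-analysis group", class = "robagree_integrity_error")
  }
  as_tibble(g[, c("review_id", "trial_id", "outcome_label")])
}

# split a semicolon-delimited cell into a unique character vector
split_labels <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || trimws(cell) == "") return(character(0))
    out <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    unique(out[out != ""])
  })
}

parse_tristate <- function(x, col) {
  chr <- tolower(trimws(as.character(x)))
  chr[is.na(chr) | chr == ""] <- "not_described"
  bad <- !chr %in% c("yes", "no", "not_described")
  if (any(bad)) {
    abort(paste0("Column '", col, "' must be yes/no/not_described; got '",
                 unique(chr[bad])[1], "'"),
          class = "robagree_parse_error")
  }
  chr
}

parse_bool <- function(x, col) {
  chr <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(chr))
  out[chr %in% c("true", "yes", "1", "t")] <- TRUE
  out[chr %in% c("false", "no", "0", "f")] <- FALSE
  bad <- !is.na(chr) & chr != "" & is.na(out)
  if (any(bad)) {
    abort(paste0("Column '", col, "' must be boolean; got '", unique(chr[bad])[1], "'"),
          class = "robagree_parse_error")
  }
  out
}

#' Read structured trial-feature records
#'
#' Reads the methodological facts about each trial that the decision rules
#' consume: one row per trial, columns named as in the feature schema (see
#' [assess_rob()]). List-valued outcome columns
#' (`primary_outcomes_declared`, `secondary_outcomes_declared`,
#' `outcomes_reported`) are semicolon-delimited within a cell and become
#' list-columns. Empty tri-state cells read as `not_described`.
#'
#' @param path CSV path.
#' @return Tibble of trial-feature records, one row per `trial_id`.
#' @export
read_trial_features <- function(path) {
  f <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       comment = "#", progress = FALSE, show_col_types = FALSE)
  if (!"trial_id" %in% names(f)) {
    abort("Feature CSV needs a trial_id column", class = "robagree_parse_error")
  }
  if (anyDuplicated(f$trial_id)) {
    abort("Duplicate trial_id in feature CSV", class = "robagree_integrity_error")
  }
  enum_ok <- list(
    sequence_method = c("computer_rng", "random_number_table",
                        "coin_toss_or_equivalent", "quasi_random", "not_described"),
    allocation_method = c("central_allocation", "envelopes", "other_concealed_claim",
                          "open_or_predictable", "not_described")
  )
  for (col in names(enum_ok)) {
    if (!col %in% names(f)) {
      abort(paste0("Feature CSV is missing column ", col), class = "robagree_parse_error")
    }
    v <- tolower(trimws(f[[col]]))
    v[is.na(v) | v == ""] <- "not_described"
    bad <- !v %in% enum_ok[[col]]
    if (any(bad)) {
      abort(paste0("Column '", col, "': unknown value '", unique(v[bad])[1], "'"),
            class = "robagree_parse_error")
    }
    f[[col]] <- v
  }
  for (col in c("participants_blinded", "personnel_blinded", "assessor_blinded",
                "baseline_comparable", "cointervention_controlled",
                "compliance_acceptable")) {
    f[[col]] <- parse_tristate(if (col %in% names(f)) f[[col]] else NA, col)
  }
  for (col in c("sequentially_numbered", "opaque", "sealed", "outcome_objective",
                "itt_performed")) {
    f[[col]] <- parse_bool(if (col %in% names(f)) f[[col]] else NA, col)
  }
  f$dropout_rate <- suppressWarnings(as.numeric(f$dropout_rate))
  bad_dr <- !is.na(f$dropout_rate) & (f$dropout_rate < 0 | f$dropout_rate > 1)
  if (any(bad_dr)) {
    abort("dropout_rate must lie in [0, 1]", class = "robagree_parse_error")
  }
  for (col in c("primary_outcomes_declared", "secondary_outcomes_declared",
                "outcomes_reported")) {
    f[[col]] <- split_labels(if (col %in% names(f)) f[[col]] else rep(NA_character_, nrow(f)))
  }
  as_tibble(f)
}
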