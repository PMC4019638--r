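#' The risk-of-bias rating scale
#'
#' Every assessment in this package is one of three ordered categories:
#' `low < unclear < high` risk of bias. `rob_levels()` returns the category
#' names in that fixed order; `rob_factor()` parses arbitrary rating strings
#' (case-insensitively, through a configurable synonym table) into an ordered
#' factor on that scale; `rob_code()` returns the ordinal codes 0/1/2 used by
#' the weighting schemes.
#'
#' @param x A character (or factor) vector of rating strings. Empty strings
#'   and `NA` become missing ratings.
#' @param synonyms Named list mapping each canonical level to the strings
#'   accepted for it; see [rob_synonyms()].
#' @param strict If `TRUE` (default) an unrecognised non-missing token is an
#'   error naming the offending positions and tokens; if `FALSE` it becomes
#'   `NA` silently.
#' @return `rob_levels()`: character vector `c("low", "unclear", "high")`.
#'   `rob_factor()`: an ordered factor with those levels. `rob_code()`: an
#'   integer vector with values 0, 1, 2 (or `NA`).
#' @examples
#' rob_factor(c("Low risk", "UNCLEAR", "high"))
#' rob_code(rob_factor("high"))
#' @export
rob_levels <- function() c("low", "unclear", "high")

#' @rdname rob_levels
#' @export
rob_factor <- function(x, synonyms = rob_synonyms(), strict = TRUE) {
  chr <- tolower(trimws(as.character(x)))
  chr[!is.na(chr) & chr == ""] <- NA_character_
  lut <- unlist(lapply(names(synonyms), function(canon) {
    setNames(rep(canon, length(synonyms[[canon]])), tolower(trimws(synonyms[[canon]])))
  }))
  out <- unname(lut[chr])
  bad <- !is.na(chr) & is.na(out)
  if (any(bad)) {
    if (strict) {
      show <- head(which(bad), 5L)
      abort(
        paste0(
          "Unknown rating token(s): ",
          paste0("'", chr[show], "' (position ", show, ")", collapse = ", "),
          if (sum(bad) > 5L) paste0(" and ", sum(bad) - 5L, " more") else ""
        ),
        class = "robagree_parse_error"
      )
    }
  }
  factor(out, levels = rob_levels(), ordered = TRUE)
}

#' @rdname rob_levels
#' @param r An ordered rating factor as returned by [rob_factor()].
#' @export
rob_code <- function(r) as.integer(rob_factor(r)) - 1L

#' Default rating synonym table
#'
#' Cochrane exports have used several vocabularies for the same three
#' judgements ("Yes/No/Unclear" in older reviews, "Low/High/Unclear risk"
#' later). The synonym table maps any of them onto the canonical scale and can
#' be extended per call.
#'
#' @param ... Additional synonyms, e.g. `low = "L"`, appended to the defaults.
#' @return Named list with elements `low`, `unclear`, `high`.
#' @export
rob_synonyms <- function(...) {
  base <- list(
    low     = c("low", "low risk", "low risk of bias", "yes", "l"),
    unclear = c("unclear", "unclear risk", "unclear risk of bias", "?", "u"),
    high    = c("high", "high risk", "high risk of bias", "no", "h")
  )
  extra <- list(...)
  for (nm in names(extra)) {
    if (!nm %in% names(base)) {
      abort(paste0("Synonym target must be one of low/unclear/high, got '", nm, "'"),
            class = "robagree_config_error")
    }
    base[[nm]] <- c(base[[nm]], as.character(extra[[nm]]))
  }
  base
}

#' The seven items of the Cochrane risk-of-bias tool
#'
#' Six bias domains are assessed, with blinding contributing two separate
#' items (participants/personnel and outcome assessment), giving seven items
#' in total. The special label `"overall"` denotes the derived trial-level
#' summary rating and is accepted wherever a domain is requested.
#'
#' @return Character vector of the 7 item names.
#' @export
rob_domains <- function() {
  c(
    "sequence_generation",
    "allocation_concealment",
    "blinding_participants_personnel",
    "blinding_outcome_assessment",
    "incomplete_outcome_data",
    "selective_reporting",
    "other_bias"
  )
}

# internal: validate a domain label (optionally allowing "overall")
check_domain <- function(domain, allow_overall = TRUE) {
  ok <- c(rob_domains(), if (allow_overall) "overall")
  bad <- setdiff(unique(as.character(domain)), ok)
  if (length(bad) > 0) {
    abort(paste0("Unknown domain(s): ", paste(bad, collapse = ", ")),
          class = "robagree_parse_error")
  }
  invisible(domain)
}
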