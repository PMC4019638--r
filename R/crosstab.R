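#' Cross-tabulate paired ratings
#'
#' A `rob_crosstab` is the k-by-k contingency table of paired ordinal ratings
#' that every agreement statistic consumes: rows are rater A, columns rater B,
#' categories in the fixed order `low < unclear < high`.
#'
#' `rob_crosstab()` builds one from two aligned rating vectors (pairs where
#' either side is missing are dropped); `as_rob_crosstab()` wraps an existing
#' count matrix; [pair_ratings()] builds one from two ratings tibbles.
#'
#' @param a,b Rating vectors (anything [rob_factor()] accepts) of equal
#'   length, one element per paired unit.
#' @param categories Category labels in order; defaults to [rob_levels()].
#' @return An object of class `rob_crosstab`: a list with `counts` (k-by-k
#'   integer matrix), `categories` and `n`.
#' @examples
#' rob_crosstab(c("low", "high", "high"), c("low", "unclear", "high"))
#' @export
rob_crosstab <- function(a, b, categories = rob_levels()) {
  if (length(a) != length(b)) {
    abort("Paired rating vectors must have equal length", class = "robagree_config_error")
  }
  fa <- factor(as.character(rob_factor(a, strict = TRUE)), levels = categories)
  fb <- factor(as.character(rob_factor(b, strict = TRUE)), levels = categories)
  keep <- !is.na(fa) & !is.na(fb)
  counts <- unclass(table(fa[keep], fb[keep]))
  dimnames(counts) <- list(rater_a = categories, rater_b = categories)
  new_rob_crosstab(counts, categories)
}

new_rob_crosstab <- function(counts, categories) {
  dimnames(counts) <- list(rater_a = categories, rater_b = categories)
  structure(
    list(counts = counts, categories = categories, n = sum(counts)),
    class = "rob_crosstab"
  )
}

#' @rdname rob_crosstab
#' @param x A square non-negative integer matrix (for `as_rob_crosstab`), or
#'   a `rob_crosstab` (for the methods).
#' @export
as_rob_crosstab <- function(x, categories = rob_levels()) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || nrow(x) != length(categories)) {
    abort("Count matrix must be square with one row per category",
          class = "robagree_config_error")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be non-negative integers", class = "robagree_config_error")
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(rater_a = categories, rater_b = categories)
  new_rob_crosstab(x, categories)
}

#' @export
as.matrix.rob_crosstab <- function(x, ...) x$counts

#' @export
t.rob_crosstab <- function(x) new_rob_crosstab(t(x$counts), x$categories)

#' @export
print.rob_crosstab <- function(x, ...) {
  cat("Paired ratings cross-tabulation (rows = rater A, cols = rater B), n =",
      x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.rob_crosstab <- function(x, ...) {
  g <- expand.grid(rater_a = x$categories, rater_b = x$categories,
                   stringsAsFactors = FALSE)
  g$count <- as.integer(x$counts[cbind(g$rater_a, g$rater_b)])
  as_tibble(g)
}

#' Pair two rating collections on a domain
#'
#' Aligns two ratings tibbles by `trial_id` and cross-tabulates their ratings
#' for one domain (or the derived `"overall"` rating). Only trials with a
#' present rating on **both** sides contribute — pairwise deletion — so the
#' resulting `n` varies by domain when reporting is incomplete.
#'
#' @param a,b Ratings tibbles (see [read_rob_ratings()]); each must contain at
#'   most one rating per trial for the requested domain.
#' @param domain One of [rob_domains()] or `"overall"` (default).
#' @return A [rob_crosstab] with rows from `a` and columns from `b`.
#' @section Errors: Zero overlapping trials raises an empty-overlap error;
#'   duplicated trial ratings within one side raise an integrity error.
#' @export
pair_ratings <- function(a, b, domain = "overall") {
  stopifnot(length(domain) == 1)
  check_domain(domain)
  pick <- function(df, side) {
    sub <- df[as.character(df$domain) == domain & !is.na(df$rating), ]
    if (anyDuplicated(sub$trial_id)) {
      abort(paste0("Side ", side, " has multiple '", domain,
                   "' ratings for one trial; filter to a single rater first"),
            class = "robagree_integrity_error")
    }
    sub[, c("trial_id", "rating")]
  }
  sa <- pick(a, "A")
  sb <- pick(b, "B")
  joined <- dplyr::inner_join(sa, sb, by = "trial_id", suffix = c("_a", "_b"))
  if (nrow(joined) == 0) {
    abort(paste0("No overlapping trials with a '", domain, "' rating on both sides"),
          class = "robagree_empty_overlap")
  }
  rob_crosstab(joined$rating_a, joined$rating_b)
}

#' Export a cross-tabulation as JSON
#'
#' @param x A [rob_crosstab].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
crosstab_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(
    list(categories = x$categories,
         counts = unname(apply(x$counts, 1, as.integer, simplify = FALSE)),
         n = x$n),
    auto_unbox = TRUE
  )
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
autoplot.rob_crosstab <- function(object, ...) {
  d <- tidy(object)
  d$rater_a <- factor(d$rater_a, levels = object$categories)
  d$rater_b <- factor(d$rater_b, levels = object$categories)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rater_b, y = .data$rater_a,
                                  fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Rater B", y = "Rater A", fill = "Trials") +
    ggplot2::theme_minimal()
}
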