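#' Per-domain agreement between two rating collections
#'
#' Runs the full agreement analysis between two panels: for each requested
#' domain (and the overall rating) the paired cross-tabulation is built with
#' pairwise deletion, weighted kappa and its confidence interval are
#' computed, and the Byrt label attached — one row per domain, mirroring the
#' usual reliability-table layout (domain, n, kappa, 95% CI, classification).
#'
#' Domains on which kappa is undefined (degenerate marginals) are kept as
#' rows with `NA` statistics and a note, rather than failing the whole
#' analysis.
#'
#' @param a,b Long ratings tibbles (see [read_rob_ratings()]).
#' @param domains Character vector of domains to compare; default: every
#'   domain (or `"overall"`) present in both collections, in canonical order.
#' @inheritParams kappa_test
#' @return A tibble of class `rob_agreement` with columns `domain`, `n`,
#'   `kappa`, `ci_low`, `ci_high`, `ci_method`, `scheme`, `byrt_label`,
#'   `note`.
#' @export
rob_agreement <- function(a, b, domains = NULL, weights = "linear",
                          ci = c("bootstrap", "analytic"), conf_level = 0.95,
                          B = 2000L, seed = NULL) {
  ci <- match.arg(ci)
  if (is.null(domains)) {
    present <- intersect(unique(as.character(a$domain)),
                         unique(as.character(b$domain)))
    domains <- intersect(c(rob_domains(), "overall"), present)
  }
  check_domain(domains)
  rows <- purrr::map(domains, function(d) {
    ct <- tryCatch(pair_ratings(a, b, domain = d),
                   robagree_empty_overlap = function(e) NULL)
    if (is.null(ct)) {
      return(tibble(domain = d, n = 0L, kappa = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, ci_method = ci, scheme = NA_character_,
                    byrt_label = NA_character_, note = "no overlapping trials"))
    }
    kt <- tryCatch(
      kappa_test(ct, weights = weights, ci = ci, conf_level = conf_level,
                 B = B, seed = seed),
      robagree_degenerate_kappa = function(e) NULL
    )
    if (is.null(kt)) {
      return(tibble(domain = d, n = ct$n, kappa = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, ci_method = ci, scheme = NA_character_,
                    byrt_label = NA_character_, note = "kappa undefined"))
    }
    tibble(domain = d, n = kt$n, kappa = kt$kappa, ci_low = kt$ci_low,
           ci_high = kt$ci_high, ci_method = kt$ci_method, scheme = kt$scheme,
           byrt_label = kt$byrt_label, note = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rob_agreement", class(out))
  out
}

#' Largest disagreement cells of a cross-tabulation
#'
#' Ranks the off-diagonal cells by count, identifying where two panels part
#' company (e.g. trials one panel calls high and the other unclear).
#'
#' @param x A [rob_crosstab].
#' @param top How many cells to return (default 3).
#' @return Tibble `rater_a`, `rater_b`, `count`, sorted decreasing.
#' @export
disagreement_cells <- function(x, top = 3L) {
  d <- tidy(x)
  d <- d[d$rater_a != d$rater_b, ]
  d <- d[order(-d$count), ]
  as_tibble(head(d, top))
}

#' @export
autoplot.rob_agreement <- function(object, ...) {
  d <- object[!is.na(object$kappa), ]
  d$domain <- factor(d$domain, levels = rev(c(rob_domains(), "overall")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kappa, y = .data$domain)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Weighted kappa", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write an agreement table to CSV or JSON
#'
#' @param x A `rob_agreement` tibble.
#' @param path Output path; `.json` writes one JSON record per comparison,
#'   anything else writes CSV.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    readr::write_csv(as_tibble(x), path, na = "")
  }
  invisible(path)
}
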