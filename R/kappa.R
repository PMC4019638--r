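#' Weighting schemes for ordinal agreement
#'
#' For k ordered categories with codes `0..k-1`, the weight matrix gives the
#' partial credit awarded to each pair of ratings: `identity` scores only
#' exact matches (classic unweighted kappa); `linear` decreases the credit
#' proportionally to the ordinal distance, `w_ij = 1 - |i - j| / (k - 1)`;
#' `quadratic` uses `w_ij = 1 - (i - j)^2 / (k - 1)^2`.
#'
#' @param scheme `"linear"` (default), `"quadratic"` or `"identity"`, or a
#'   user-supplied symmetric k-by-k matrix with unit diagonal and entries in
#'   `[0, 1]`.
#' @param k Number of categories (default 3).
#' @return A k-by-k numeric weight matrix with attribute `"scheme"`.
#' @export
kappa_weights <- function(scheme = c("linear", "quadratic", "identity"), k = 3L) {
  if (is.matrix(scheme)) {
    w <- scheme
    if (nrow(w) != ncol(w) || any(diag(w) != 1) || any(w < 0) || any(w > 1) ||
        !isTRUE(all.equal(w, t(w)))) {
      abort("A custom weight matrix must be symmetric with unit diagonal and entries in [0,1]",
            class = "robagree_config_error")
    }
    attr(w, "scheme") <- "custom"
    return(w)
  }
  scheme <- match.arg(scheme)
  i <- matrix(0:(k - 1), k, k)
  j <- t(i)
  w <- switch(scheme,
    identity  = (i == j) * 1,
    linear    = 1 - abs(i - j) / (k - 1),
    quadratic = 1 - (i - j)^2 / (k - 1)^2
  )
  attr(w, "scheme") <- scheme
  w
}

# kappa from a matrix of joint proportions; NULL when chance agreement is 1
kappa_from_props <- function(p, w) {
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (1 - pe < 1e-12) return(NULL)
  (po - pe) / (1 - pe)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters on an ordered scale,
#' `kappa = (Po_w - Pe_w) / (1 - Pe_w)`, where `Po_w` is the weighted
#' observed agreement `sum(w_ij * p_ij)` over the joint rating proportions
#' and `Pe_w` the weighted agreement expected under independent raters with
#' the same marginals, `sum(w_ij * p_i. * p_.j)`.
#'
#' @param x A [rob_crosstab] (or square count matrix).
#' @param weights A scheme name or matrix for [kappa_weights()].
#' @return The kappa point estimate, a number in `[-1, 1]`.
#' @section Errors: When the expected weighted agreement equals 1 (e.g. both
#'   raters constant on the same category) kappa is undefined; a
#'   degenerate-kappa error is raised with the marginals in the message.
#' @examples
#' ct <- as_rob_crosstab(diag(c(4, 3, 2)))
#' weighted_kappa(ct)                       # 1: perfect agreement
#' @export
weighted_kappa <- function(x, weights = "linear") {
  if (!inherits(x, "rob_crosstab")) x <- as_rob_crosstab(x, categories = rownames(x) %||% rob_levels())
  if (x$n < 1) abort("Cross-tabulation is empty", class = "robagree_precondition_error")
  w <- kappa_weights(weights, k = length(x$categories))
  k <- kappa_from_props(x$counts / x$n, w)
  if (is.null(k)) {
    abort(paste0("Weighted kappa is undefined: expected weighted agreement is 1 ",
                 "(row marginals ", paste(rowSums(x$counts), collapse = "/"),
                 ", column marginals ", paste(colSums(x$counts), collapse = "/"), ")"),
          class = "robagree_degenerate_kappa")
  }
  k
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Large-sample (delta-method) variance of weighted kappa,
# Fleiss, Cohen & Everitt (1969).
kappa_se_analytic <- function(counts, w) {
  n <- sum(counts)
  p <- counts / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  k <- (po - pe) / (1 - pe)
  wbar_i <- as.vector(w %*% pj_)      # row-wise expected weight
  wbar_j <- as.vector(t(w) %*% pi_)   # column-wise expected weight
  term <- (w - outer(wbar_i, wbar_j, "+") * (1 - k))^2
  v <- (sum(p * term) - (k - pe * (1 - k))^2) / (n * (1 - pe)^2)
  sqrt(max(v, 0))
}

# expand a crosstab into per-unit (i, j) index pairs
crosstab_units <- function(x) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  data.frame(
    i = rep(idx[, 1], x$counts[idx]),
    j = rep(idx[, 2], x$counts[idx])
  )
}

#' Weighted kappa with a confidence interval
#'
#' Fits the full agreement summary for one cross-tabulation: the weighted
#' kappa point estimate, a confidence interval, and the Byrt interpretation
#' label. Two interval methods are available:
#'
#' * `"bootstrap"` (default) — percentile interval from `B` resamples of the
#'   `n` paired ratings with replacement. Resamples on which kappa is
#'   undefined (degenerate marginals) are dropped and counted; more than 10%
#'   dropped triggers a warning. Asymmetric intervals near the boundary are
#'   represented faithfully.
#' * `"analytic"` — large-sample delta-method standard error
#'   (Fleiss–Cohen–Everitt), interval `kappa +/- z * SE` truncated to
#'   `[-1, 1]`.
#'
#' @inheritParams weighted_kappa
#' @param ci `"bootstrap"` or `"analytic"`.
#' @param conf_level Coverage, default 0.95.
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap; required for reproducible
#'   intervals. The global RNG state is restored afterwards.
#' @return An object of class `rob_kappa` with fields `kappa`, `ci_low`,
#'   `ci_high`, `ci_method`, `conf_level`, `n`, `scheme`, `byrt_label`, and
#'   (bootstrap only) `B` and `dropped_resamples`. Supports `print()`,
#'   [tidy()] and [glance()].
#' @examples
#' ct <- rob_crosstab(c("low", "low", "unclear", "high"),
#'                    c("low", "unclear", "unclear", "high"))
#' kappa_test(ct, ci = "analytic")
#' @export
kappa_test <- function(x, weights = "linear", ci = c("bootstrap", "analytic"),
                       conf_level = 0.95, B = 2000L, seed = NULL) {
  ci <- match.arg(ci)
  if (!inherits(x, "rob_crosstab")) x <- as_rob_crosstab(x)
  w <- kappa_weights(weights, k = length(x$categories))
  k <- weighted_kappa(x, weights = w)
  alpha <- 1 - conf_level
  dropped <- 0L
  if (ci == "analytic") {
    se <- kappa_se_analytic(x$counts, w)
    z <- qnorm(1 - alpha / 2)
    lo <- max(-1, k - z * se)
    hi <- min(1, k + z * se)
  } else {
    if (B < 1) abort("B must be >= 1", class = "robagree_config_error")
    units <- crosstab_units(x)
    n <- nrow(units)
    ks <- with_preserved_seed(seed, {
      vapply(seq_len(B), function(b) {
        take <- sample.int(n, n, replace = TRUE)
        counts <- matrix(0, nrow(w), ncol(w))
        tab <- table(factor(units$i[take], levels = seq_len(nrow(w))),
                     factor(units$j[take], levels = seq_len(ncol(w))))
        counts[] <- tab
        kb <- kappa_from_props(counts / n, w)
        if (is.null(kb)) NA_real_ else kb
      }, numeric(1))
    })
    dropped <- sum(is.na(ks))
    if (dropped > 0.10 * B) {
      warn(paste0(dropped, " of ", B, " bootstrap resamples had undefined kappa ",
                  "and were dropped; the interval may be unreliable"),
           class = "robagree_degenerate_resamples")
    }
    ks <- ks[!is.na(ks)]
    if (length(ks) == 0) {
      abort("All bootstrap resamples had undefined kappa",
            class = "robagree_degenerate_kappa")
    }
    qs <- quantile(ks, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- qs[1]
    hi <- qs[2]
  }
  structure(
    list(kappa = k, ci_low = lo, ci_high = hi, ci_method = ci,
         conf_level = conf_level, n = x$n,
         scheme = attr(w, "scheme"), byrt_label = byrt_classify(k),
         B = if (ci == "bootstrap") as.integer(B) else NA_integer_,
         dropped_resamples = dropped, crosstab = x),
    class = "rob_kappa"
  )
}

# run code with a seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.rob_kappa <- function(x, ...) {
  cat(sprintf("Weighted kappa (%s weights): %.3f  [%s %.0f%% CI: %.3f, %.3f], n = %d\n",
              x$scheme, x$kappa, x$ci_method, 100 * x$conf_level,
              x$ci_low, x$ci_high, x$n))
  cat("Interpretation (Byrt):", x$byrt_label, "\n")
  if (identical(x$ci_method, "bootstrap") && x$dropped_resamples > 0) {
    cat("Note:", x$dropped_resamples, "degenerate resamples dropped\n")
  }
  invisible(x)
}

#' @export
tidy.rob_kappa <- function(x, ...) {
  tibble(
    estimate = x$kappa,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    conf.level = x$conf_level,
    method = paste0("weighted kappa (", x$scheme, ")"),
    ci.method = x$ci_method,
    n = x$n,
    byrt_label = x$byrt_label
  )
}

#' @export
glance.rob_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, n = x$n, scheme = x$scheme,
         byrt_label = x$byrt_label, dropped_resamples = x$dropped_resamples)
}

#' Interpret a kappa value on the Byrt scale
#'
#' Maps a kappa value onto the seven interpretation bands of Byrt (1996):
#' 0.93–1.00 excellent, 0.81–0.92 very good, 0.61–0.80 good, 0.41–0.60 fair,
#' 0.21–0.40 slight, 0.01–0.20 poor, and 0.00 or less no agreement. The
#' bands are stated at two-decimal resolution, so the value is rounded to
#' two decimals first; every value in `[-1, 1]` then receives exactly one
#' label.
#'
#' @param kappa Numeric vector of kappa values in `[-1, 1]`.
#' @return Character vector of interpretation labels.
#' @examples
#' byrt_classify(c(0.62, 0.55, 0.00, -0.29))
#' @export
byrt_classify <- function(kappa) {
  if (any(!is.na(kappa) & (kappa < -1 - 1e-9 | kappa > 1 + 1e-9))) {
    abort("kappa must lie in [-1, 1]", class = "robagree_precondition_error")
  }
  k2 <- round(kappa, 2)
  dplyr::case_when(
    is.na(k2)  ~ NA_character_,
    k2 <= 0.00 ~ "no agreement",
    k2 <= 0.20 ~ "poor agreement",
    k2 <= 0.40 ~ "slight agreement",
    k2 <= 0.60 ~ "fair agreement",
    k2 <= 0.80 ~ "good agreement",
    k2 <= 0.92 ~ "very good agreement",
    TRUE       ~ "excellent agreement"
  )
}

#' Median of a set of kappa values
#'
#' Convenience summary for a panel of per-domain kappas (the standard median;
#' mean of the middle two for even length), with a non-empty precondition.
#'
#' @param values Non-empty numeric vector of kappa values.
#' @return The median.
#' @export
median_kappa <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("median_kappa needs at least one value", class = "robagree_precondition_error")
  }
  median(values)
}
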