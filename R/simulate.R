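#' Simulator configuration
#'
#' The paired-ratings simulator emulates the statistical structure the
#' agreement analysis assumes: for every trial and domain a latent true
#' rating is drawn from `truth`, and each of two panels independently emits
#' a rating through its own 3-by-3 row-stochastic confusion matrix (row =
#' true category, column = emitted rating); emitted ratings are then deleted
#' completely at random. Output is a pure function of the configuration,
#' seed included.
#'
#' Defaults reflect a corpus of physiotherapy trials with mostly incomplete
#' reporting: truth mass (0.2, 0.5, 0.3) over low/unclear/high, panels with
#' 70% per-category accuracy, 109 trials, and 10% missingness.
#'
#' @param n_trials Number of trials (default 109).
#' @param n_domains Number of items per trial, up to 7 (default 7).
#' @param seed Integer seed; mandatory.
#' @param truth Probability vector over (low, unclear, high).
#' @param confusion_a,confusion_b Row-stochastic 3-by-3 confusion matrices,
#'   e.g. from [rob_confusion()].
#' @param missingness Per-rating deletion probability in `[0, 1)`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 109L, n_domains = 7L, seed,
                       truth = c(low = 0.2, unclear = 0.5, high = 0.3),
                       confusion_a = rob_confusion(0.7),
                       confusion_b = rob_confusion(0.7),
                       missingness = 0.1) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("sim_config requires an integer seed", class = "robagree_config_error")
  }
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      abort(paste0(what, " must be non-negative and sum to 1"),
            class = "robagree_config_error")
    }
  }
  check_probs(truth, "truth distribution")
  for (m in list(confusion_a, confusion_b)) {
    if (!is.matrix(m) || any(dim(m) != 3)) {
      abort("Confusion matrices must be 3x3", class = "robagree_config_error")
    }
    apply(m, 1, check_probs, what = "each confusion row")
  }
  stopifnot(n_trials >= 1, n_domains >= 1, n_domains <= 7,
            missingness >= 0, missingness < 1)
  structure(
    list(n_trials = as.integer(n_trials), n_domains = as.integer(n_domains),
         seed = as.integer(seed), truth = unname(truth),
         confusion_a = unname(confusion_a), confusion_b = unname(confusion_b),
         missingness = missingness),
    class = "sim_config"
  )
}

#' Build a simple symmetric confusion matrix
#'
#' Diagonal mass `accuracy`, remainder split evenly over the other two
#' categories — a one-parameter rater error model.
#'
#' @param accuracy Probability of emitting the true category, in `(0, 1]`.
#' @return A 3-by-3 row-stochastic matrix.
#' @export
rob_confusion <- function(accuracy = 0.7) {
  stopifnot(accuracy > 0, accuracy <= 1)
  off <- (1 - accuracy) / 2
  m <- matrix(off, 3, 3)
  diag(m) <- accuracy
  m
}

#' Simulate paired panel ratings
#'
#' Draws ratings for two panels under [sim_config()]'s latent-truth model
#' and returns them in the canonical long ratings schema, so simulated data
#' flow through the identical pipeline as real data. Identical
#' configurations produce identical output.
#'
#' @param cfg A [sim_config()].
#' @return List with ratings tibbles `panel_a`, `panel_b` (rater_id
#'   `"panel_a"`/`"panel_b"`, review_id `"SIM"`) and `truth` (the latent
#'   ratings before noise and deletion).
#' @export
simulate_paired_ratings <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  doms <- rob_domains()[seq_len(cfg$n_domains)]
  with_preserved_seed(cfg$seed, {
    grid <- expand.grid(trial_id = sprintf("T%04d", seq_len(cfg$n_trials)),
                        domain = doms, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    m <- nrow(grid)
    truth_idx <- sample.int(3, m, replace = TRUE, prob = cfg$truth)
    emit <- function(conf) {
      out <- integer(m)
      for (t in 1:3) {
        sel <- truth_idx == t
        if (any(sel)) out[sel] <- sample.int(3, sum(sel), replace = TRUE,
                                             prob = conf[t, ])
      }
      out
    }
    a_idx <- emit(cfg$confusion_a)
    b_idx <- emit(cfg$confusion_b)
    drop_a <- stats::runif(m) < cfg$missingness
    drop_b <- stats::runif(m) < cfg$missingness
    mk <- function(idx, rater, keep) {
      tibble(trial_id = grid$trial_id[keep], review_id = "SIM",
             rater_id = rater, domain = grid$domain[keep],
             rating = rob_factor(rob_levels()[idx[keep]]))
    }
    list(
      panel_a = mk(a_idx, "panel_a", !drop_a),
      panel_b = mk(b_idx, "panel_b", !drop_b),
      truth = mk(truth_idx, "truth", rep(TRUE, m))
    )
  })
}

#' Population weighted kappa of a rater model
#'
#' Closed-form oracle for the simulator: two panels rating conditionally
#' independently given a latent truth induce the exact joint rating
#' distribution `p_ij = sum_t truth_t * A[t, i] * B[t, j]`; this returns the
#' weighted kappa of that distribution, the value the sample kappa converges
#' to as the number of trials grows.
#'
#' @param truth Probability vector over (low, unclear, high).
#' @param confusion_a,confusion_b Row-stochastic confusion matrices.
#' @param weights Scheme for [kappa_weights()].
#' @return The population kappa.
#' @export
population_kappa <- function(truth, confusion_a, confusion_b, weights = "linear") {
  p <- t(confusion_a) %*% diag(as.vector(truth)) %*% confusion_b
  w <- kappa_weights(weights, k = nrow(p))
  k <- kappa_from_props(p, w)
  if (is.null(k)) {
    abort("Population kappa is undefined: expected weighted agreement is 1",
          class = "robagree_degenerate_kappa")
  }
  k
}

#' Simulate trial-feature records with known true ratings
#'
#' Generates structured trial-feature records field by field. With all
#' defect rates zero every record is fully adequate (all ratings low); each
#' rate is the probability that the corresponding feature group is drawn
#' from its inadequate/undescribed alternatives instead. The paired "true"
#' ratings are computed by an independent, join-table implementation of the
#' documented decision rules ([rules_reference()]), enabling equivalence
#' testing against [assess_rob()].
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param defect_rates Named numeric vector of per-field defect
#'   probabilities with names `sequence`, `allocation`, `blinding`,
#'   `incomplete`, `reporting`, `other` (default 0.5 each, giving a diverse
#'   mix of adequate and deficient trials).
#' @return List with `features` (tibble, one row per trial) and `truth`
#'   (long tibble `trial_id`, `domain`, `rating` from [rules_reference()]).
#' @export
simulate_feature_records <- function(n, seed,
                                     defect_rates = c(sequence = 0.5,
                                                      allocation = 0.5,
                                                      blinding = 0.5,
                                                      incomplete = 0.5,
                                                      reporting = 0.5,
                                                      other = 0.5)) {
  need <- c("sequence", "allocation", "blinding", "incomplete", "reporting", "other")
  if (!all(need %in% names(defect_rates)) ||
      any(defect_rates < 0) || any(defect_rates > 1)) {
    abort("defect_rates must name all six rule groups with probabilities in [0,1]",
          class = "robagree_config_error")
  }
  features <- with_preserved_seed(seed, {
    defect <- function(rate) stats::runif(n) < rate
    pick <- function(cond, bad_opts, good_opts) {
      out <- sample(good_opts, n, replace = TRUE)
      out[cond] <- sample(bad_opts, sum(cond), replace = TRUE)
      out
    }
    d_seq <- defect(defect_rates[["sequence"]])
    d_all <- defect(defect_rates[["allocation"]])
    d_bli <- defect(defect_rates[["blinding"]])
    d_inc <- defect(defect_rates[["incomplete"]])
    d_rep <- defect(defect_rates[["reporting"]])
    d_oth <- defect(defect_rates[["other"]])

    alloc <- pick(d_all,
                  c("envelopes", "open_or_predictable", "not_described",
                    "other_concealed_claim"),
                  c("central_allocation", "envelopes"))
    # envelope safeguards: complete when the allocation group is adequate,
    # otherwise each safeguard independently described/true
    sg <- function() {
      out <- rep(TRUE, n)
      out[d_all] <- sample(c(TRUE, FALSE, NA), sum(d_all), replace = TRUE)
      out
    }
    tri <- function(cond) {
      out <- rep("yes", n)
      out[cond] <- sample(c("no", "not_described"), sum(cond), replace = TRUE)
      out
    }
    dropout <- round(stats::runif(n, 0, 0.20), 3)
    dropout[d_inc] <- round(stats::runif(sum(d_inc), 0, 0.60), 3)
    itt <- rep(TRUE, n)
    itt[d_inc] <- sample(c(TRUE, FALSE), sum(d_inc), replace = TRUE)

    prim <- replicate(n, "P1", simplify = FALSE)
    sec <- replicate(n, sprintf("S%d", seq_len(sample(0:4, 1))), simplify = FALSE)
    reported <- mapply(function(p, s, bad) {
      if (!bad) return(c(p, s))
      keep_p <- if (stats::runif(1) < 0.3) character(0) else p
      keep_s <- s[stats::runif(length(s)) < 0.4]
      extra <- if (stats::runif(1) < 0.3) "NEW1" else character(0)
      c(keep_p, keep_s, extra)
    }, prim, sec, d_rep, SIMPLIFY = FALSE)

    tibble(
      trial_id = sprintf("F%04d", seq_len(n)),
      sequence_method = pick(d_seq, c("quasi_random", "not_described"),
                             c("computer_rng", "random_number_table",
                               "coin_toss_or_equivalent")),
      allocation_method = alloc,
      sequentially_numbered = sg(), opaque = sg(), sealed = sg(),
      participants_blinded = tri(d_bli), personnel_blinded = tri(d_bli),
      assessor_blinded = tri(d_bli),
      outcome_objective = FALSE,
      dropout_rate = dropout, itt_performed = itt,
      primary_outcomes_declared = prim,
      secondary_outcomes_declared = sec,
      outcomes_reported = reported,
      baseline_comparable = tri(d_oth),
      cointervention_controlled = tri(d_oth),
      compliance_acceptable = tri(d_oth)
    )
  })
  list(features = features, truth = rules_reference(features))
}

#' Reference implementation of the decision rules
#'
#' A second, deliberately different implementation of the documented domain
#' rules: each enumerable rule is materialised as an exhaustive decision
#' table (every combination of its inputs with its rating) and records are
#' joined against it; the numeric rules use interval lookup. It exists so
#' the production rules in [assess_rob()] can be checked against an
#' independent code path; the two must agree on every record.
#'
#' @param features Tibble of trial-feature records.
#' @param rules A [rob_rules()] configuration.
#' @return Long tibble `trial_id`, `domain`, `rating`.
#' @export
rules_reference <- function(features, rules = rob_rules()) {
  tri <- c("yes", "no", "not_described")

  # sequence generation: 5-row table
  seq_tab <- data.frame(
    sequence_method = c("computer_rng", "random_number_table",
                        "coin_toss_or_equivalent", "quasi_random", "not_described"),
    rating = c("low", "low", "low", "high", "unclear")
  )
  r_seq <- seq_tab$rating[match(features$sequence_method, seq_tab$sequence_method)]

  # allocation concealment: method x complete-safeguards table
  all_tab <- expand.grid(
    allocation_method = c("central_allocation", "envelopes", "other_concealed_claim",
                          "open_or_predictable", "not_described"),
    safeguards_complete = c(TRUE, FALSE), stringsAsFactors = FALSE)
  all_tab$rating <- ifelse(all_tab$allocation_method == "central_allocation", "low",
                    ifelse(all_tab$allocation_method == "envelopes" &
                             all_tab$safeguards_complete, "low",
                    ifelse(all_tab$allocation_method == "open_or_predictable",
                           "high", "unclear")))
  sgc <- mapply(function(a, b, c) isTRUE(a) && isTRUE(b) && isTRUE(c),
                features$sequentially_numbered, features$opaque, features$sealed)
  key <- paste(features$allocation_method, sgc)
  r_all <- all_tab$rating[match(key, paste(all_tab$allocation_method,
                                           all_tab$safeguards_complete))]

  # blinding items: full tri-state x objective tables
  bl_tab <- expand.grid(p = tri, s = tri, obj = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  bl_tab$rating <- apply(bl_tab, 1, function(x) {
    obj <- as.logical(x[["obj"]]) && rules$objective_outcome_override
    if (x[["p"]] == "no" || x[["s"]] == "no") {
      if (obj) "low" else "high"
    } else if (x[["p"]] == "yes" && x[["s"]] == "yes") "low" else "unclear"
  })
  obj <- !is.na(features$outcome_objective) & features$outcome_objective
  r_bpp <- bl_tab$rating[match(paste(features$participants_blinded,
                                     features$personnel_blinded, obj),
                               paste(bl_tab$p, bl_tab$s, bl_tab$obj))]
  oa_tab <- expand.grid(a = tri, obj = c(TRUE, FALSE), stringsAsFactors = FALSE)
  oa_tab$rating <- apply(oa_tab, 1, function(x) {
    o <- as.logical(x[["obj"]]) && rules$objective_outcome_override
    if (x[["a"]] == "no") { if (o) "low" else "high" }
    else if (x[["a"]] == "yes") "low" else "unclear"
  })
  r_boa <- oa_tab$rating[match(paste(features$assessor_blinded, obj),
                               paste(oa_tab$a, oa_tab$obj))]

  # incomplete outcome data: interval lookup on dropout crossed with ITT
  dr_bin <- findInterval(features$dropout_rate,
                         c(-Inf, rules$dropout_max_low + 1e-15))  # 1: <=max, 2: >max
  dr_bin[is.na(features$dropout_rate)] <- 0L
  inc_tab <- expand.grid(bin = 0:2, itt = c(TRUE, FALSE), stringsAsFactors = FALSE)
  inc_tab$rating <- ifelse(inc_tab$bin == 2, "high",
                    ifelse(inc_tab$bin == 1 & inc_tab$itt, "low", "unclear"))
  itt <- !is.na(features$itt_performed) & features$itt_performed
  r_inc <- inc_tab$rating[match(paste(dr_bin, itt), paste(inc_tab$bin, inc_tab$itt))]

  # selective reporting: boolean-profile table over (primary missing,
  # secondary fraction above threshold, reporting complete and closed)
  if (any(lengths(features$primary_outcomes_declared) == 0)) {
    abort("Every trial must declare at least one primary outcome",
          class = "robagree_precondition_error")
  }
  profile <- mapply(function(p, s, r) {
    pm <- !all(p %in% r)
    smf <- if (length(s) == 0) 0 else mean(!(s %in% r))
    closed <- all(r %in% c(p, s))
    c(pm = pm, over = smf > rules$secondary_missing_high,
      complete = (smf == 0) && !pm && closed)
  }, features$primary_outcomes_declared, features$secondary_outcomes_declared,
     features$outcomes_reported)
  rep_tab <- expand.grid(pm = c(TRUE, FALSE), over = c(TRUE, FALSE),
                         complete = c(TRUE, FALSE))
  rep_tab$rating <- ifelse(rep_tab$pm | rep_tab$over, "high",
                           ifelse(rep_tab$complete, "low", "unclear"))
  r_rep <- rep_tab$rating[match(paste(profile["pm", ], profile["over", ],
                                      profile["complete", ]),
                                paste(rep_tab$pm, rep_tab$over, rep_tab$complete))]

  # other bias: exhaustive 27-row table
  oth_tab <- expand.grid(b = tri, c = tri, k = tri, stringsAsFactors = FALSE)
  oth_tab$rating <- apply(oth_tab[, c("b", "c", "k")], 1, function(x) {
    if ("no" %in% x) "high" else if (all(x == "yes")) "low" else "unclear"
  })
  r_oth <- oth_tab$rating[match(paste(features$baseline_comparable,
                                      features$cointervention_controlled,
                                      features$compliance_acceptable),
                                paste(oth_tab$b, oth_tab$c, oth_tab$k))]

  long <- tibble(
    trial_id = rep(features$trial_id, times = 7),
    domain = rep(rob_domains(), each = nrow(features)),
    rating = rob_factor(c(r_seq, r_all, r_bpp, r_boa, r_inc, r_rep, r_oth))
  )
  dplyr::arrange(long, .data$trial_id, factor(.data$domain, levels = rob_domains())) %>%
    dplyr::mutate(domain = as.character(.data$domain))
}
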