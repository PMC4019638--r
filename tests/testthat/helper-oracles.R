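# Independent oracles used across the suite. These deliberately avoid the
# package's matrix formulas: agreement statistics are recomputed from the
# individual paired units.

# Brute-force weighted kappa: observed agreement as the mean weight over the
# n observed unit pairs; chance agreement as the mean weight over all n^2
# cross-pairings of rater A's units with rater B's units.
brute_force_weighted_kappa <- function(counts, w) {
  idx <- which(counts > 0, arr.ind = TRUE)
  i <- rep(idx[, 1], counts[idx])
  j <- rep(idx[, 2], counts[idx])
  n <- length(i)
  po <- 0
  for (u in seq_len(n)) po <- po + w[i[u], j[u]]
  po <- po / n
  pe <- 0
  for (u in seq_len(n)) {
    for (v in seq_len(n)) pe <- pe + w[i[u], j[v]]
  }
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# Classic unweighted Cohen's kappa straight from Po and Pe.
cohen_kappa_direct <- function(counts) {
  n <- sum(counts)
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  (po - pe) / (1 - pe)
}

# Random non-degenerate 3x3 cross-tab with n <= max_n units.
random_crosstab <- function(max_n = 30) {
  repeat {
    n <- sample(2:max_n, 1)
    counts <- matrix(0L, 3, 3)
    cells <- sample.int(9, n, replace = TRUE)
    for (c in cells) counts[c] <- counts[c] + 1L
    p <- counts / n
    pe <- sum(kappa_weights("linear") * outer(rowSums(p), colSums(p)))
    if (1 - pe > 1e-6) return(as_rob_crosstab(counts))
  }
}

# A fully adequate trial-feature record as a one-row tibble; fields can be
# overridden to create specific defects.
adequate_record <- function(trial_id = "T1", ...) {
  base <- tibble::tibble(
    trial_id = trial_id,
    sequence_method = "computer_rng",
    allocation_method = "central_allocation",
    sequentially_numbered = NA, opaque = NA, sealed = NA,
    participants_blinded = "yes", personnel_blinded = "yes",
    assessor_blinded = "yes", outcome_objective = FALSE,
    dropout_rate = 0.10, itt_performed = TRUE,
    primary_outcomes_declared = list("P1"),
    secondary_outcomes_declared = list(c("S1", "S2")),
    outcomes_reported = list(c("P1", "S1", "S2")),
    baseline_comparable = "yes", cointervention_controlled = "yes",
    compliance_acceptable = "yes"
  )
  mods <- list(...)
  for (nm in names(mods)) {
    base[[nm]] <- if (nm %in% c("primary_outcomes_declared",
                                "secondary_outcomes_declared",
                                "outcomes_reported")) list(mods[[nm]]) else mods[[nm]]
  }
  base
}

# Long ratings tibble from a named list rater -> list(trial -> named domain
# ratings).
ratings_tbl <- function(trial_id, rater_id, domain, rating, review_id = NA_character_) {
  tibble::tibble(trial_id = trial_id, review_id = review_id, rater_id = rater_id,
                 domain = domain, rating = rob_factor(rating))
}
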