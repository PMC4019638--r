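test_that("weight matrices implement the identity, linear and quadratic schemes", {
  wl <- kappa_weights("linear")
  expect_equal(wl, matrix(c(1, .5, 0, .5, 1, .5, 0, .5, 1), 3), ignore_attr = TRUE)
  wq <- kappa_weights("quadratic")
  expect_equal(wq[1, 3], 0)
  expect_equal(wq[1, 2], 0.75)
  wi <- kappa_weights("identity")
  expect_equal(wi, diag(3), ignore_attr = TRUE)
  for (w in list(wl, wq, wi)) {
    expect_equal(diag(w), rep(1, 3), ignore_attr = TRUE)
    expect_equal(w, t(w), ignore_attr = TRUE)
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(kappa_weights(matrix(2, 3, 3)), class = "robagree_config_error")
})

test_that("the matrix formula agrees with the brute-force per-unit oracle", {
  set.seed(101)
  for (scheme in c("linear", "quadratic", "identity")) {
    w <- kappa_weights(scheme)
    for (rep_ in 1:40) {
      ct <- random_crosstab(max_n = 30)
      expect_equal(weighted_kappa(ct, scheme),
                   brute_force_weighted_kappa(as.matrix(ct), w),
                   tolerance = 1e-12)
    }
  }
})

test_that("identity weights reduce to classic unweighted Cohen's kappa", {
  set.seed(202)
  for (rep_ in 1:50) {
    ct <- random_crosstab()
    expect_equal(weighted_kappa(ct, "identity"),
                 cohen_kappa_direct(as.matrix(ct)), tolerance = 1e-12)
  }
})

test_that("kappa is bounded, transpose-symmetric and count-scale invariant", {
  set.seed(303)
  for (rep_ in 1:50) {
    ct <- random_crosstab()
    k <- weighted_kappa(ct)
    expect_gte(k, -1)
    expect_lte(k, 1)
    expect_equal(weighted_kappa(t(ct)), k, tolerance = 1e-12)
    scaled <- as_rob_crosstab(as.matrix(ct) * 7L)
    expect_equal(weighted_kappa(scaled), k, tolerance = 1e-12)
  }
})

test_that("canonical tables give their known kappa values", {
  # perfect agreement on any scheme
  diag3 <- as_rob_crosstab(diag(c(5, 2, 4)))
  for (scheme in c("linear", "quadratic", "identity")) {
    expect_equal(weighted_kappa(diag3, scheme), 1)
  }
  # observed equals chance exactly
  flat <- as_rob_crosstab(matrix(1, 2, 2), categories = c("low", "high"))
  expect_equal(weighted_kappa(flat), 0)
  # both raters constant on one category: kappa undefined
  const <- matrix(0L, 3, 3); const[2, 2] <- 10L
  expect_error(weighted_kappa(as_rob_crosstab(const)),
               class = "robagree_degenerate_kappa")
})

test_that("the published meta-analysis cross-tab yields kappa -0.29 under linear weights", {
  counts <- matrix(0L, 3, 3, dimnames = list(rob_levels(), rob_levels()))
  counts["unclear", "unclear"] <- 3L
  counts["unclear", "high"] <- 10L
  counts["high", "low"] <- 1L
  counts["high", "unclear"] <- 2L
  counts["high", "high"] <- 1L
  k <- weighted_kappa(as_rob_crosstab(counts), "linear")
  expect_equal(round(k, 2), -0.29)
  # the ordinal weighting is load-bearing: identity weights give a
  # different value on the same table
  expect_false(isTRUE(all.equal(weighted_kappa(as_rob_crosstab(counts), "identity"), k)))
})

test_that("bootstrap intervals are seeded, degenerate-aware and shrink with n", {
  ct <- rob_crosstab(c("low", "low", "unclear", "unclear", "high", "high"),
                     c("low", "unclear", "unclear", "high", "high", "high"))
  a <- kappa_test(ct, ci = "bootstrap", B = 500, seed = 9)
  b <- kappa_test(ct, ci = "bootstrap", B = 500, seed = 9)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_lte(a$ci_low, a$ci_high)
  # a diagonal-only table has no resampling variability
  d <- kappa_test(as_rob_crosstab(diag(c(3, 3, 3))), ci = "bootstrap",
                  B = 200, seed = 1)
  expect_equal(c(d$ci_low, d$ci_high), c(1, 1))
  # scaling all counts up narrows the interval (stochastic, seeded)
  big <- kappa_test(as_rob_crosstab(as.matrix(ct) * 10L), ci = "bootstrap",
                    B = 500, seed = 9)
  expect_lt(big$ci_high - big$ci_low, a$ci_high - a$ci_low)
  # published 17-pair table: the interval must contain the point estimate
  meta <- pair_ratings(
    ratings_tbl(sprintf("M%02d", 1:17), "ext", "overall",
                published_meta_ratings()$external),
    ratings_tbl(sprintf("M%02d", 1:17), "coch", "overall",
                published_meta_ratings()$cochrane))
  kt <- kappa_test(meta, ci = "bootstrap", B = 2000, seed = 4)
  expect_lte(kt$ci_low, -0.29)
  expect_gte(kt$ci_high, -0.29)
})

test_that("analytic intervals bracket the estimate and respect the kappa range", {
  set.seed(404)
  for (rep_ in 1:20) {
    ct <- random_crosstab()
    kt <- kappa_test(ct, ci = "analytic")
    expect_lte(kt$ci_low, kt$kappa)
    expect_gte(kt$ci_high, kt$kappa)
    expect_gte(kt$ci_low, -1)
    expect_lte(kt$ci_high, 1)
  }
  # tidy/glance expose the fit in broom shape
  kt <- kappa_test(random_crosstab(), ci = "analytic")
  td <- tidy(kt)
  expect_named(td, c("estimate", "conf.low", "conf.high", "conf.level",
                     "method", "ci.method", "n", "byrt_label"))
  expect_equal(td$estimate, kt$kappa)
  expect_equal(glance(kt)$kappa, kt$kappa)
})

test_that("Byrt bands label every kappa in [-1,1] exactly once, at 2-dp resolution", {
  expect_equal(byrt_classify(0.62), "good agreement")
  expect_equal(byrt_classify(0.55), "fair agreement")
  expect_equal(byrt_classify(0.00), "no agreement")
  expect_equal(byrt_classify(-0.29), "no agreement")
  expect_equal(byrt_classify(0.20), "poor agreement")
  expect_equal(byrt_classify(0.21), "slight agreement")
  expect_equal(byrt_classify(0.41), "fair agreement")
  expect_equal(byrt_classify(0.81), "very good agreement")
  expect_equal(byrt_classify(0.93), "excellent agreement")
  # rounding happens before banding: 0.204 -> 0.20 -> poor
  expect_equal(byrt_classify(0.204), "poor agreement")
  grid <- seq(-1, 1, by = 0.01)
  labels <- byrt_classify(grid)
  expect_false(any(is.na(labels)))
  expect_equal(sort(unique(labels)),
               sort(c("no agreement", "poor agreement", "slight agreement",
                      "fair agreement", "good agreement", "very good agreement",
                      "excellent agreement")))
  expect_error(byrt_classify(1.5), class = "robagree_precondition_error")
})

test_that("median_kappa is the standard median with a non-empty precondition", {
  expect_equal(median_kappa(0.4), 0.4)
  expect_equal(median_kappa(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(median_kappa(c(0.71, 0.79, 0.56, 0.54, 0.71, 0.50, 0.32)), 0.56)
  expect_error(median_kappa(numeric(0)), class = "robagree_precondition_error")
})
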