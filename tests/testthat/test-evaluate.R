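test_that("age recode hits every boundary", {
  expect_identical(recode_age(c(0, 19, 20, 25, 79, 80, 85, 105)),
                   c(1L, 1L, 2L, 2L, 7L, 8L, 8L, 8L))
  expect_error(recode_age(-1), "within")
  expect_error(recode_age(106), "within")
  expect_error(recode_age(NA), "within")
})

test_that("four_moments matches hand computation and a brute-force oracle", {
  fm <- four_moments(c(1, 2, 3, 4, 5))
  # hand: m2 = 2, m3 = 0, m4 = 6.8 -> skew 0, excess kurtosis -1.3
  expect_equal(fm$mean, 3)
  expect_equal(fm$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(round(fm$sd, 4), 1.5811)
  expect_equal(fm$skewness, 0)
  expect_equal(fm$excess_kurtosis, -1.3)

  # independent oracle on random vectors (e1071, moment-definition g1/g2)
  set.seed(9)
  for (n in c(10, 100, 1000)) {
    x <- rnorm(n) * 3 + runif(n)
    fm <- four_moments(x)
    expect_equal(fm$skewness, e1071::skewness(x, type = 1), tolerance = 1e-10)
    expect_equal(fm$excess_kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-10)
    expect_equal(fm$sd, sd(x), tolerance = 1e-10)
  }

  # constant input: sd zero, shape undefined
  fc <- four_moments(rep(4, 10))
  expect_equal(fc$sd, 0)
  expect_true(is.na(fc$skewness))
  expect_error(four_moments(1), "at least two")
})

test_that("large normal and uniform samples show the analytic shapes", {
  set.seed(19)
  z <- rnorm(100000)
  fz <- four_moments(z)
  expect_lt(abs(fz$skewness), 0.03)
  expect_lt(abs(fz$excess_kurtosis), 0.06)
  u <- runif(100000, 0, 100)
  fu <- four_moments(u)
  expect_equal(fu$excess_kurtosis, -1.2, tolerance = 0.03)
})

test_that("univariate comparison tabulates both populations side by side", {
  a <- tibble::tibble(v = rep(c("x", "y"), c(30, 70)), w = rnorm(100))
  b <- tibble::tibble(v = rep(c("x", "y"), c(35, 65)), w = rnorm(100))
  cmp <- compare_univariate(a, b, c("v", "w"))
  f <- cmp$frequencies
  expect_equal(f$pct_a, c(30, 70))
  expect_equal(f$pct_b, c(35, 65))
  expect_equal(sum(f$pct_a), 100, tolerance = 0.1)
  expect_equal(sum(f$pct_b), 100, tolerance = 0.1)

  # identity comparison
  self <- compare_univariate(a, a)
  expect_equal(self$frequencies$pct_a, self$frequencies$pct_b)
  expect_equal(self$moments$mean[1], self$moments$mean[2])

  # symmetry up to column order
  rev <- compare_univariate(b, a, c("v", "w"))
  expect_equal(rev$frequencies$pct_a, cmp$frequencies$pct_b)
  expect_equal(rev$frequencies$pct_b, cmp$frequencies$pct_a)

  expect_error(compare_univariate(a, b, "nope"), "nope")
})

test_that("stratified comparison: one-cell grid equals the unstratified estimate", {
  set.seed(23)
  a <- tibble::tibble(cell = "all", y = rbinom(500, 1, 0.3))
  b <- tibble::tibble(cell = "all", y = rbinom(500, 1, 0.32))
  out <- stratified_compare(a, b, "y", "cell")
  expect_identical(nrow(out), 2L)
  expect_equal(out$estimate[out$population == "a"], mean(a$y))
  expect_equal(out$estimate[out$population == "b"], mean(b$y))
  expect_error(stratified_compare(a, b, "y", character()), "empty")
})

test_that("zero-prevalence cells get a Wilson interval [0, >0]", {
  a <- tibble::tibble(g = rep(c("p", "q"), each = 50),
                      y = rep(c("no", "no"), each = 50))
  a$y[a$g == "q"] <- sample(c("no", "yes"), 50, replace = TRUE)
  out <- stratified_compare(a, a, "y", "g")
  zero <- out[out$g == "p" & out$population == "a", ]
  expect_equal(zero$estimate, 0)
  expect_equal(zero$lower, 0)
  expect_gt(zero$upper, 0)
})

test_that("Wilson intervals achieve near-nominal coverage", {
  set.seed(29)
  n <- 100; p <- 0.3
  hits <- vapply(seq_len(1000), function(i) {
    k <- rbinom(1, n, p)
    ci <- chainsynth:::wilson_ci(k, n)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, logical(1))
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.985)
})

test_that("small cells are flagged, and missing outcomes are counted", {
  a <- tibble::tibble(g = rep(c("p", "q"), c(10, 200)),
                      y = c(rnorm(10), rnorm(200)))
  a$y[15] <- NA
  out <- stratified_compare(a, a, "y", "g", min_n = 30)
  expect_true(all(out$small_cell[out$g == "p"]))
  expect_false(any(out$small_cell[out$g == "q"]))
  expect_identical(out$n_missing_outcome[out$g == "q" & out$population == "a"], 1L)
})

test_that("disclosure match rate: identity, disjoint and seed-only cases", {
  orig <- tibble::tibble(a = c("x", "x", "y"), b = c(1, 2, 1))
  expect_equal(disclosure_match_rate(orig, orig, c("a", "b"))$rate, 1)
  other <- tibble::tibble(a = c("z", "z"), b = c(9, 9))
  expect_equal(disclosure_match_rate(orig, other, c("a", "b"))$rate, 0)
  expect_error(disclosure_match_rate(orig, other, character()), "non-empty")

  # seed keys only: match rate 1 by construction of expand_seed
  s <- extract_seed_strata(orig, c("a", "b"), min_cell = 1)
  syn <- expand_seed(s)
  expect_equal(disclosure_match_rate(orig, syn, c("a", "b"))$rate, 1)

  # baseline reflects independent marginal draws
  base <- disclosure_match_rate(orig, orig, c("a", "b"))$baseline_rate
  expect_gt(base, 0); expect_lt(base, 1)
})

test_that("tv_distance handles categorical and binned numeric input", {
  expect_equal(tv_distance(c("a", "a", "b", "b"), c("a", "b", "b", "b")), 0.25)
  expect_equal(tv_distance(rep("a", 5), rep("a", 5)), 0)
  set.seed(31)
  x <- rnorm(20000); y <- rnorm(20000)
  expect_lt(tv_distance(x, y), 0.05)
  expect_gt(tv_distance(x, x + 3), 0.5)
})

test_that("evaluation report and plots assemble", {
  sc <- linear_scenario(3000, 53)
  truth <- simulate_truth(sc$config)
  bundle <- fit_sequence(truth, sc$plan, min_cell = 1)
  syn <- synthesize_population(bundle, rng_seed = 3)
  truth$age_class <- recode_age(truth$age)
  syn$age_class <- recode_age(syn$age)
  rep <- evaluate_populations(truth, syn,
                              variables = c("y1", "y2", "y3"),
                              stratified_outcomes = "y2",
                              strata_vars = c("age_class", "gender"),
                              key_vars = c("age", "gender"))
  expect_s3_class(rep, "chainsynth_eval_report")
  expect_equal(rep$disclosure$rate, 1)  # seed-only key set
  p1 <- ggplot2::autoplot(rep$univariate)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_stratified(rep$stratified$y2)
  expect_s3_class(p2, "ggplot")
})
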