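test_that("expand_seed replicates counts exactly in order", {
  s <- toy_strata(c(a = 3, b = 2))
  pop <- expand_seed(s)
  expect_identical(pop$g, c("a", "a", "a", "b", "b"))
  expect_identical(nrow(pop), attr(s, "total"))

  s0 <- toy_strata(c(a = 4, b = 0))
  expect_identical(expand_seed(s0)$g, rep("a", 4))
})

test_that("draw_outcome follows each family's sampling law", {
  X <- matrix(1, nrow = 100000, ncol = 1, dimnames = list(NULL, "(Intercept)"))

  # gaussian with zero residual sd is exactly the linear predictor
  fg <- chainsynth:::new_fitted("y", "gaussian", "continuous", list(),
                                design = NULL, coef = c(`(Intercept)` = 2.5),
                                vcov = matrix(0.1), residual_sd = 0, n_fit = 10)
  expect_equal(draw_outcome(fg, X[1:50, , drop = FALSE]), rep(2.5, 50))

  # intercept-only Bernoulli(0.3)
  fb <- chainsynth:::new_fitted("y", "logistic", "binary", list(),
                                design = NULL, coef = c(`(Intercept)` = qlogis(0.3)),
                                vcov = matrix(0.1), n_fit = 10,
                                levels = c("no", "yes"), ref = "no")
  set.seed(1)
  draws <- draw_outcome(fb, X)
  expect_lt(abs(mean(draws == "yes") - 0.3), 3 * sqrt(0.3 * 0.7 / 100000))

  # multinomial with softmax probabilities ~ (1, 0, 0): always the reference
  fm <- chainsynth:::new_fitted("y", "multinomial", "categorical", list(),
                                design = NULL,
                                coef = matrix(c(-50, -50), nrow = 2,
                                              dimnames = list(c("b", "c"), "(Intercept)")),
                                vcov = diag(2), n_fit = 10,
                                levels = c("a", "b", "c"), ref = "a")
  expect_identical(unique(draw_outcome(fm, X[1:200, , drop = FALSE])), "a")

  # covariate/design mismatch errors
  expect_error(draw_outcome(fb, cbind(X, X)), "does not match design")
})

test_that("calibration solves the capped scaling factor", {
  # already on target: identity with factor 1
  p0 <- calibrate_marginal(c(0.2, 0.6), 0.4)
  expect_equal(as.numeric(p0), c(0.2, 0.6))
  expect_equal(attr(p0, "factor"), 1)

  # linear case solved by hand: factor 2
  p1 <- calibrate_marginal(c(0.1, 0.3), 0.4)
  expect_equal(as.numeric(p1), c(0.2, 0.6))
  expect_equal(attr(p1, "factor"), 2.0)

  # capping active: compare against a brute-force grid scan
  p <- c(0.8, 0.2)
  out <- calibrate_marginal(p, 0.9)
  expect_equal(mean(out), 0.9, tolerance = 1e-10)
  grid <- seq(1, 5, by = 1e-4)
  scan <- vapply(grid, function(cc) mean(pmin(cc * p, 1)), numeric(1))
  c_scan <- grid[which.min(abs(scan - 0.9))]
  expect_equal(attr(out, "factor"), c_scan, tolerance = 1e-3)
  expect_equal(as.numeric(out), pmin(attr(out, "factor") * p, 1))

  # scaling down works too
  dn <- calibrate_marginal(c(0.4, 0.6), 0.25)
  expect_equal(mean(dn), 0.25, tolerance = 1e-10)
  expect_lt(attr(dn, "factor"), 1)

  expect_error(calibrate_marginal(c(0.1, 0.2), 1), "in \\(0, 1\\)")
  expect_error(calibrate_marginal(c(0, 0, 0.5), 0.8), "unattainable")
  expect_error(calibrate_marginal(c(-0.1, 0.5), 0.3), "\\[0, 1\\]")
})

test_that("synthesis conserves the seed joint distribution exactly", {
  sc <- linear_scenario(5000, 43)
  truth <- simulate_truth(sc$config)
  bundle <- fit_sequence(truth, sc$plan, min_cell = 1)
  syn <- synthesize_population(bundle, rng_seed = 7)
  expect_identical(nrow(syn), attr(bundle$strata, "total"))
  a <- dplyr::count(truth, age, gender) |> dplyr::arrange(age, gender)
  b <- dplyr::count(syn, age, gender) |> dplyr::arrange(age, gender)
  expect_equal(cols_only(a), cols_only(b))
})

test_that("synthesis is deterministic and replicates share outcome draws", {
  sc <- linear_scenario(3000, 47)
  truth <- simulate_truth(sc$config)
  bundle <- fit_sequence(truth, sc$plan, min_cell = 1)
  s1 <- synthesize_population(bundle, rng_seed = 11)
  s2 <- synthesize_population(bundle, rng_seed = 11)
  expect_identical(cols_only(s1), cols_only(s2))
  # point-estimate replicates are identical by design
  reps <- synthesize_population(bundle, rng_seed = 11, n_replicates = 2)
  expect_identical(cols_only(reps[[1]]), cols_only(reps[[2]]))
  # a different seed changes the draws
  s3 <- synthesize_population(bundle, rng_seed = 12)
  expect_false(identical(s1$y1, s3$y1))
  # parameter redraw differentiates replicates
  repsP <- synthesize_population(bundle, rng_seed = 11, n_replicates = 2,
                                 draw_parameters = TRUE)
  expect_false(identical(repsP[[1]]$y1, repsP[[2]]$y1))
})

test_that("intercept-only gaussian synthesis matches the bundle intercept", {
  set.seed(61)
  n <- 20000
  plan <- synthesis_plan(
    list(variable_spec("age", "continuous"),
         variable_spec("gender", "binary", levels = c("f", "m"))),
    list(variable_spec("y", "continuous")),
    list(model_spec("y", "gaussian")),
    age_var = "age")
  d <- tibble::tibble(age = sample(0:105, n, replace = TRUE),
                      gender = sample(c("f", "m"), n, replace = TRUE),
                      y = rnorm(n, 5, 2))
  bundle <- fit_sequence(d, plan, min_cell = 1)
  f <- bundle$models$y[[1]]
  syn <- synthesize_population(bundle, rng_seed = 3)
  expect_lt(abs(mean(syn$y) - f$coef[["(Intercept)"]]),
            3 * f$residual_sd / sqrt(n))
})

test_that("rows in unfitted strata error by default and can fall back", {
  # stratify the second outcome by the first, with one stratum unseen at fit
  plan <- synthesis_plan(
    list(variable_spec("age", "continuous"),
         variable_spec("gender", "binary", levels = c("f", "m"))),
    list(variable_spec("grp", "categorical", levels = c("u", "v", "w")),
         variable_spec("y", "continuous")),
    list(model_spec("grp", "multinomial", predictors = "age"),
         model_spec("y", "gaussian", predictors = "age", stratify_by = "grp")),
    age_var = "age")
  set.seed(71)
  n <- 2000
  d <- tibble::tibble(age = sample(20:80, n, replace = TRUE),
                      gender = sample(c("f", "m"), n, replace = TRUE),
                      grp = sample(c("u", "v"), n, replace = TRUE),
                      y = rnorm(n))
  d$y <- d$y + 2 * (d$grp == "v")
  bundle <- fit_sequence(d, plan, min_cell = 1)
  # make 'w' reachable in synthesis by editing the grp model towards 'w'
  f <- bundle$models$grp[[1]]
  f$coef <- rbind(f$coef, w = c(3, 0))
  rownames(f$coef)[nrow(f$coef)] <- "w"
  f$vcov <- diag(nrow(f$coef) * ncol(f$coef)) * 1e-6
  f$levels <- c(f$levels, "w")
  bundle$models$grp[[1]] <- f
  expect_error(synthesize_population(bundle, rng_seed = 5),
               "no fitted model .* grp=w")
  syn <- synthesize_population(bundle, rng_seed = 5, fallback = "largest")
  expect_false(anyNA(syn$y))
})

test_that("model-implied marginals agree with synthetic frequencies", {
  sc <- linear_scenario(40000, 83)
  truth <- simulate_truth(sc$config)
  bundle <- fit_sequence(truth, sc$plan, min_cell = 1)
  syn <- synthesize_population(bundle, rng_seed = 21)
  imp <- model_implied_marginals(bundle, rng_seed = 22)
  for (lv in c("a", "b", "c")) {
    p_syn <- mean(syn$y3 == lv)
    p_imp <- imp$value[imp$variable == "y3" & imp$level == lv]
    se <- sqrt(p_imp * (1 - p_imp) * 2 / nrow(syn))
    expect_lt(abs(p_syn - p_imp), 4 * se)
  }
})
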