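test_that("seed strata honour the minimum-cell rule and policies", {
  d <- tibble::tibble(g = c(rep("a", 9), rep("b", 10), rep("c", 40)),
                      h = "x")
  s_waive <- extract_seed_strata(d, c("g", "h"), min_cell = 10, policy = "waive")
  expect_identical(nrow(s_waive), 3L)
  expect_identical(s_waive$waived, c(TRUE, FALSE, FALSE))   # 9 < 10 waived
  expect_identical(attr(s_waive, "total"), 59L)

  s_drop <- extract_seed_strata(d, c("g", "h"), min_cell = 10, policy = "drop")
  expect_identical(nrow(s_drop), 2L)
  expect_identical(attr(s_drop, "total"), 50L)
  expect_false(any(s_drop$waived))

  # boundary: exactly min_cell passes unflagged
  expect_false(s_waive$waived[s_waive$g == "b"])

  # merge: the small stratum's count moves to its nearest neighbour
  d2 <- tibble::tibble(g = rep(c("a", "a", "b"), c(9, 30, 12)),
                       age = rep(c(40, 41, 40), c(9, 30, 12)))
  s_merge <- extract_seed_strata(d2, c("g", "age"), min_cell = 10, policy = "merge")
  expect_identical(attr(s_merge, "total"), 51L)
  expect_identical(s_merge$count[s_merge$g == "a"], 39L)

  # empty table
  s0 <- extract_seed_strata(d[0, ], c("g", "h"), min_cell = 10)
  expect_identical(nrow(s0), 0L)
  expect_identical(attr(s0, "total"), 0L)

  d$g[1] <- NA
  expect_error(extract_seed_strata(d, c("g", "h")), "missing values")
})

test_that("gaussian fits agree with the closed-form OLS oracle on the same draw", {
  set.seed(101)
  n <- 10000L
  plan <- tiny_plan()
  data <- tibble::tibble(
    age = runif(n, 0, 105),
    gender = sample(c("female", "male"), n, replace = TRUE))
  data$y_cont <- 2 + 3 * data$age + rnorm(n)
  fits <- fit_variable(data, plan$sequence[[1]], plan)
  f <- fits[[1]]
  # independent oracle: normal equations solved directly
  X <- cbind(1, data$age)
  beta <- drop(solve(crossprod(X), crossprod(X, data$y_cont)))
  expect_equal(unname(f$coef), beta, tolerance = 1e-8)
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$coef[["(Intercept)"]] - 2), 3 * se[1])
  expect_lt(abs(f$coef[["age"]] - 3), 3 * se[2])
  # residual sd near 1 (sampling error ~ 1/sqrt(2n))
  expect_equal(f$residual_sd, 1, tolerance = 0.05)
  expect_identical(f$n_fit, n)
})

test_that("constant outcomes give flagged degenerate models", {
  plan <- tiny_plan()
  d <- tibble::tibble(age = runif(50, 20, 60),
                      gender = "female",
                      y_cont = rnorm(50),
                      y_bin = "yes")
  fits <- fit_variable(d, plan$sequence[[2]], plan)
  f <- fits[[1]]
  expect_true(f$degenerate)
  expect_identical(f$constant, "yes")
  expect_identical(f$n_fit, 50L)
})

test_that("intercept-only multinomial recovers analytic log-odds", {
  set.seed(55)
  n <- 100000
  lv <- c("a", "b", "c")
  y <- sample(lv, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  plan <- synthesis_plan(
    list(variable_spec("age", "continuous"),
         variable_spec("gender", "binary", levels = c("f", "m"))),
    list(variable_spec("y", "categorical", levels = lv)),
    list(model_spec("y", "multinomial")),
    age_var = "age")
  d <- tibble::tibble(age = runif(n, 0, 100), gender = "f", y = y)
  f <- fit_variable(d, plan$sequence[[1]], plan)[[1]]
  expect_identical(f$ref, "c")  # most frequent level is the reference
  counts <- table(factor(y, lv))
  se <- sqrt(diag(f$vcov))
  for (j in seq_len(nrow(f$coef))) {
    lvj <- rownames(f$coef)[j]
    analytic <- log(0.2 * (lvj == "a") + 0.3 * (lvj == "b")) - log(0.5)
    expect_lt(abs(f$coef[j, 1] - analytic), 3 * se[(j - 1) * ncol(f$coef) + 1])
  }
})

test_that("fit_sequence assembles a bundle and zero-noise chains fit exactly", {
  seed_vars <- list(age = list(values = 20:60, probs = rep(1 / 41, 41)),
                    gender = list(levels = c("female", "male"), probs = c(0.5, 0.5)))
  cfg <- truth_config(3000, seed_vars,
                      list(truth_model("y_cont", "gaussian", lp = "1 + 0.5*age", sd = 0)),
                      survey_fraction = 0.5, survey_min_age = 0, rng_seed = 3)
  truth <- simulate_truth(cfg)
  plan <- synthesis_plan(
    list(variable_spec("age", "continuous"),
         variable_spec("gender", "binary", levels = c("female", "male"))),
    list(variable_spec("y_cont", "continuous")),
    list(model_spec("y_cont", "gaussian", predictors = "age")),
    age_var = "age")
  bundle <- fit_sequence(truth, plan, min_cell = 1)
  expect_s3_class(bundle, "chainsynth_bundle")
  expect_named(bundle$models, "y_cont")
  expect_lt(bundle$models$y_cont[[1]]$residual_sd, 1e-6)
  expect_identical(attr(bundle$strata, "total"), nrow(truth))
  g <- glance(bundle)
  expect_identical(g$n_outcomes, 1L)
  td <- tidy(bundle)
  expect_true(all(c("outcome", "term", "estimate", "std.error") %in% names(td)))
})

test_that("an invalid plan is rejected before fitting", {
  sc <- linear_scenario(200, 31)
  truth <- simulate_truth(sc$config)
  bad_plan <- sc$plan
  bad_plan$sequence[[1]]$predictors <- c("age", "y3")  # later outcome
  expect_error(fit_sequence(truth, bad_plan), "sequential constraint")
})

test_that("doubling the data roughly halves coefficient variances", {
  sc1 <- linear_scenario(4000, 61)
  sc2 <- linear_scenario(8000, 61)
  f1 <- fit_variable(simulate_truth(sc1$config), sc1$plan$sequence[[1]], sc1$plan)[[1]]
  f2 <- fit_variable(simulate_truth(sc2$config), sc2$plan$sequence[[1]], sc2$plan)[[1]]
  ratio <- mean(diag(f1$vcov) / diag(f2$vcov))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("bundles round-trip losslessly and validate on read", {
  sc <- linear_scenario(3000, 17)
  truth <- simulate_truth(sc$config)
  bundle <- fit_sequence(truth, sc$plan, min_cell = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_bundle(bundle, path)
  back <- read_bundle(path)
  for (nm in names(bundle$models)) {
    for (k in seq_along(bundle$models[[nm]])) {
      f0 <- bundle$models[[nm]][[k]]
      f1 <- back$models[[nm]][[k]]
      expect_identical(f1$coef, f0$coef)            # bit-exact
      expect_identical(unname(f1$vcov), unname(f0$vcov))
      expect_identical(f1$residual_sd, f0$residual_sd)
      expect_identical(f1$design$columns, f0$design$columns)
    }
  }
  expect_equal(as.data.frame(back$strata), as.data.frame(bundle$strata))
  expect_equal(back$plan, bundle$plan)

  # gzipped path round-trips too
  gz <- withr::local_tempfile(fileext = ".json.gz")
  write_bundle(bundle, gz)
  expect_identical(read_bundle(gz)$models$y1[[1]]$coef, bundle$models$y1[[1]]$coef)

  # hand-edited asymmetric covariance is rejected with the invariant named
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = ""),
                            simplifyVector = FALSE)
  v <- obj$models[[1]]$fits[[1]]$vcov
  v[[2]] <- chainsynth:::num_to_chr(chainsynth:::chr_to_num(v[[2]]) + 0.5)
  obj$models[[1]]$fits[[1]]$vcov <- v
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE), bad)
  expect_error(read_bundle(bad), "not symmetric")

  # empty file is a parse error
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  expect_error(read_bundle(empty), "parse error")
})

test_that("serialized bundles contain no row-length arrays", {
  sc <- linear_scenario(3000, 19)
  truth <- simulate_truth(sc$config)
  bundle <- fit_sequence(truth, sc$plan, min_cell = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_bundle(bundle, path)
  audit <- audit_bundle_disclosure(path, nrow(truth))
  expect_identical(audit$offending, 0L)
  expect_gt(audit$n_arrays, 0L)
})
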