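test_that("simulation is byte-identical under the same seed", {
  sc <- linear_scenario(2000, 11)
  a <- simulate_truth(sc$config)
  b <- simulate_truth(sc$config)
  expect_identical(cols_only(a), cols_only(b))
  expect_identical(attr(a, "pre_nonresponse"), attr(b, "pre_nonresponse"))
})

test_that("a deterministic chain makes outcomes exact functions of seeds", {
  seed_vars <- list(age = list(values = 0:105, probs = rep(1 / 106, 106)),
                    gender = list(levels = c("f", "m"), probs = c(0.5, 0.5)))
  models <- list(
    truth_model("y", "gaussian", lp = "2*age", sd = 0),
    truth_model("z", "logistic", levels = c("no", "yes"),
                lp = "1000*(age >= 50) - 500")  # probability 0 or 1
  )
  cfg <- truth_config(1000, seed_vars, models, survey_fraction = 0.5,
                      survey_min_age = 0, rng_seed = 4)
  pop <- simulate_truth(cfg)
  expect_equal(pop$y, 2 * pop$age)
  expect_identical(pop$z, ifelse(pop$age >= 50, "yes", "no"))
})

test_that("unbiased survey sampling hits the expected count", {
  seed_vars <- list(age = list(values = 0:105, probs = rep(1 / 106, 106)),
                    gender = list(levels = c("f", "m"), probs = c(0.5, 0.5)))
  cfg <- truth_config(100000, seed_vars,
                      list(truth_model("y", "gaussian", lp = "0", sd = 1)),
                      survey_fraction = 0.03, survey_age_bias = 1,
                      survey_min_age = 0, rng_seed = 9)
  pop <- simulate_truth(cfg)
  se <- sqrt(100000 * 0.03 * 0.97)
  expect_lt(abs(sum(pop$survey_flag) - 3000), 3 * se)
})

test_that("age-biased selection oversamples the elderly at the target size", {
  cfg <- demo_truth_config(50000, rng_seed = 3)
  pop <- simulate_truth(cfg)
  n_survey <- sum(pop$survey_flag)
  se <- sqrt(50000 * 0.03 * 0.97)
  expect_lt(abs(n_survey - 1500), 4 * se)
  expect_gt(mean(pop$age[pop$survey_flag == 1]),
            mean(pop$age[pop$age >= 19]))
})

test_that("nonresponse touches only survey-scope cells and is recoverable", {
  cfg <- demo_truth_config(30000, rng_seed = 5)
  pop <- simulate_truth(cfg)
  in_survey <- pop$survey_flag == 1
  # survey-scope columns are NA for all non-survey rows
  for (v in c("bmi", "smoking", "activity")) {
    expect_true(all(is.na(pop[[v]][!in_survey])))
  }
  # population-scope columns are complete
  for (v in c("age", "income_source", "lung_cancer", "p_chd")) {
    expect_false(anyNA(pop[[v]]))
  }
  # observed survey values equal the pre-nonresponse draw exactly
  pre <- attr(pop, "pre_nonresponse")
  expect_identical(pre$.row, which(in_survey))
  for (v in c("bmi", "smoking", "activity")) {
    obs <- !is.na(pop[[v]][in_survey])
    expect_identical(pop[[v]][in_survey][obs], pre[[v]][obs])
    expect_gt(sum(!obs), 0)  # some nonresponse was injected
  }
})

test_that("true marginals: closed forms and exact total-probability", {
  seed_vars <- list(age = list(values = 0:9, probs = rep(0.1, 10)),
                    gender = list(levels = c("f", "m"), probs = c(0.5, 0.5)))
  b0 <- log(0.3 / 0.7)  # constant-logit prevalence 0.3
  models <- list(
    truth_model("a", "logistic", levels = c("no", "yes"), lp = as.character(b0)),
    truth_model("b", "logistic", levels = c("no", "yes"),
                lp = paste0("-1 + 1.2*(a=='yes')")),
    truth_model("u", "multinomial", levels = c("p", "q", "r", "s"),
                lp = c(q = "0", r = "0", s = "0"))
  )
  cfg <- truth_config(100, seed_vars, models, survey_fraction = 0.5,
                      survey_min_age = 0, rng_seed = 2)

  ma <- true_marginals(cfg, "a")
  expect_identical(attr(ma, "method"), "exact")
  expect_equal(ma$prob[ma$level == "yes"], plogis(b0), tolerance = 1e-12)

  # two-stage chain: P(b) enumerated by hand over the 2-cell mixture
  mb <- true_marginals(cfg, "b")
  expect_identical(attr(mb, "method"), "exact")
  hand <- 0.3 * plogis(-1 + 1.2) + 0.7 * plogis(-1)
  expect_equal(mb$prob[mb$level == "yes"], hand, tolerance = 1e-12)

  mu <- true_marginals(cfg, "u")
  expect_equal(mu$prob, rep(0.25, 4), tolerance = 1e-12)

  # seed marginal comes straight from the configuration
  mg <- true_marginals(cfg, "gender")
  expect_equal(mg$prob, c(0.5, 0.5))

  expect_error(true_marginals(cfg, "nope"), "not defined")
})

test_that("simulated categorical marginals converge to the exact ones", {
  sc <- linear_scenario(100000, 13)
  pop <- simulate_truth(sc$config)
  m <- true_marginals(sc$config, "y2")
  expect_identical(attr(m, "method"), "monte_carlo")  # continuous ancestor y1
  p_hat <- mean(pop$y2 == "yes")
  p_ref <- m$prob[m$level == "yes"]
  se <- sqrt(p_ref * (1 - p_ref) * (1 / 100000 + 1 / attr(m, "mc_n")))
  expect_lt(abs(p_hat - p_ref), 4 * se)
})

test_that("percentile-style uniform variables show the uniform shape", {
  cfg <- demo_truth_config(100000, rng_seed = 8)
  pop <- simulate_truth(cfg)
  fm <- four_moments(pop$property_pct)
  expect_equal(fm$excess_kurtosis, -1.2, tolerance = 0.05)
  expect_equal(fm$mean, 50, tolerance = 0.5)
})

test_that("invalid generating references are named", {
  seed_vars <- list(age = list(values = 0:9, probs = rep(0.1, 10)),
                    gender = list(levels = c("f", "m"), probs = c(0.5, 0.5)))
  expect_error(
    truth_config(100, seed_vars,
                 list(truth_model("y", "gaussian", lp = "2*ghost", sd = 1)),
                 survey_min_age = 0),
    "ghost")
})
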