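# Shared fixtures, all built in code.

# Minimal two-variable plan: one gaussian, one logistic outcome on two seeds.
tiny_plan <- function() {
  seeds <- list(
    variable_spec("age", "continuous"),
    variable_spec("gender", "binary", levels = c("female", "male"))
  )
  outs <- list(
    variable_spec("y_cont", "continuous"),
    variable_spec("y_bin", "binary", levels = c("no", "yes"))
  )
  sequence <- list(
    model_spec("y_cont", "gaussian", predictors = "age"),
    model_spec("y_bin", "logistic", predictors = c("age", "y_cont"))
  )
  synthesis_plan(seeds, outs, sequence, age_var = "age")
}

# Linear-chain scenario with known generating coefficients in the fitted
# parametrization (linear age, no stratification): used for parameter
# recovery. Truth coefficient vectors are over columns (Intercept, age, y1).
linear_scenario <- function(n, rng_seed) {
  seed_vars <- list(
    age = list(values = 0:105, probs = rep(1 / 106, 106)),
    gender = list(levels = c("female", "male"), probs = c(0.5, 0.5))
  )
  models <- list(
    truth_model("y1", "gaussian", lp = "0.5 + 0.04*(age-50)", sd = 1.2),
    truth_model("y2", "logistic", levels = c("no", "yes"),
                lp = "-0.6 + 0.03*(age-50) + 0.5*y1"),
    truth_model("y3", "multinomial", levels = c("a", "b", "c"),
                lp = c(b = "-0.4 + 0.02*(age-50)", c = "0.8 - 0.3*y1"))
  )
  config <- truth_config(n, seed_vars, models, survey_fraction = 0.03,
                         survey_min_age = 0, rng_seed = rng_seed)
  seeds <- list(variable_spec("age", "continuous"),
                variable_spec("gender", "binary", levels = c("female", "male")))
  outs <- list(variable_spec("y1", "continuous"),
               variable_spec("y2", "binary", levels = c("no", "yes")),
               variable_spec("y3", "categorical", levels = c("a", "b", "c")))
  sequence <- list(
    model_spec("y1", "gaussian", predictors = "age"),
    model_spec("y2", "logistic", predictors = c("age", "y1")),
    model_spec("y3", "multinomial", predictors = c("age", "y1"))
  )
  plan <- synthesis_plan(seeds, outs, sequence, age_var = "age")
  # generating coefficients over (Intercept, age, y1); multinomial per level
  truth_coefs <- list(
    y1 = c(`(Intercept)` = 0.5 - 0.04 * 50, age = 0.04, y1 = NA),
    y2 = c(`(Intercept)` = -0.6 - 0.03 * 50, age = 0.03, y1 = 0.5),
    y3 = list(a = c(0, 0, 0),
              b = c(-0.4 - 0.02 * 50, 0.02, 0),
              c = c(0.8, 0, -0.3))
  )
  list(config = config, plan = plan, truth_coefs = truth_coefs,
       residual_sd = 1.2)
}

# Plain-column view of a table: drops every non-structural attribute so
# content comparisons ignore provenance metadata.
cols_only <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

# A small hand-built strata table.
toy_strata <- function(counts = c(a = 3, b = 2)) {
  extract_seed_strata(
    tibble::tibble(g = rep(names(counts), counts)), "g", min_cell = 1)
}
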