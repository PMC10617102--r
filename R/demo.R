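# The demo scenario: a toy-scale analogue of a national registry + health
# survey setting. Four seed variables (single-year age 0-105, gender, region,
# urbanization), six population-scope socio-economic outcomes (a 14-level
# income source, two percentile-coded variables, household type and size,
# ethnicity), three survey-scope lifestyle variables with MAR item
# nonresponse (BMI, smoking, physical activity), two rare cancer outcomes
# using missing-indicator lifestyle predictors, and four model-based disease
# probability columns. It exercises every model family, both fitting scopes,
# imputation, and calibration.

demo_income_levels <- c("employee", "civil_servant", "director", "other_labour",
                        "owner", "property", "unemployment", "disability",
                        "retirement", "social_assistance", "other_social",
                        "study_grant", "other", "none")
demo_ethnicity_levels <- c("dutch", "moroccan", "turkish", "surinam",
                           "antilles", "other_nonwest", "other_west")
demo_smoking_levels <- c("never", "past", "light", "heavy")

demo_seed_vars <- function() {
  age_w <- c(rep(1.3, 50), rep(1.2, 20), rep(0.8, 10), rep(0.45, 10), rep(0.12, 16))
  list(
    age = list(values = 0:105, probs = age_w / sum(age_w)),
    gender = list(levels = c("female", "male"), probs = c(0.505, 0.495)),
    region = list(levels = c("north", "east", "west", "south", "metro"),
                  probs = c(0.20, 0.22, 0.28, 0.20, 0.10)),
    urbanization = list(levels = paste0("u", 1:5),
                        probs = c(0.15, 0.20, 0.25, 0.25, 0.15))
  )
}

demo_true_models <- function() {
  inc <- setNames(c(
    "-1.8 - 0.02*(age-40)",                                   # civil_servant
    "-3.0 + 0.01*(age-40)",                                   # director
    "-4.3",                                                   # other_labour
    "-1.2 + 0.012*(age-40) + 0.25*(region=='south')",         # owner
    "-4.6 + 0.03*(age-40)",                                   # property
    "-3.4 + 0.3*(region=='metro')",                           # unemployment
    "-3.2 + 0.025*(age-40)",                                  # disability
    "-6.0 + 0.15*pmax(age-50, 0)",                            # retirement
    "-2.9 + 0.35*(region=='metro') - 0.01*(age-40)",          # social_assistance
    "-3.6",                                                   # other_social
    "-2.0 - 0.25*pmin(pmax(age-18, 0), 16)",                  # study_grant
    "-4.8",                                                   # other
    "1.8 - 0.16*pmin(age, 27)"                                # none (children)
  ), demo_income_levels[-1])
  list(
    truth_model("income_source", "multinomial", lp = inc,
                levels = demo_income_levels),
    truth_model("income_pct", "gaussian", sd = 22,
                lp = paste0("52 + 6*(income_source=='employee') +",
                            "14*(income_source=='director') +",
                            "8*(income_source=='civil_servant') -",
                            "14*(income_source=='social_assistance') -",
                            "9*(income_source=='unemployment') + 0.06*(age-40)")),
    truth_model("property_pct", "uniform", min = 0, max = 100),
    truth_model("household_type", "logistic",
                levels = c("non_institutional", "institutional"),
                lp = "-6.5 + 0.16*pmax(age-60, 0) + 0.4*(gender=='female')"),
    truth_model("household_size", "multinomial",
                levels = c("1", "2", "3", "4", "5", "6plus"),
                lp = setNames(c(
                  "0.6 - 0.012*(age-40) - 2.5*(household_type=='institutional')",
                  "-0.2 + 0.012*abs(age-35) - 3*(household_type=='institutional')",
                  "0.3 - 0.02*abs(age-38) - 3*(household_type=='institutional')",
                  "-0.5 - 0.025*abs(age-40) - 3*(household_type=='institutional')",
                  "-1.4 - 0.03*abs(age-40) - 3*(household_type=='institutional')"),
                  c("2", "3", "4", "5", "6plus"))),
    truth_model("ethnicity", "multinomial", levels = demo_ethnicity_levels,
                lp = setNames(c(
                  "-3.6 + 1.2*(region=='metro') - 0.01*(age-30)",
                  "-3.5 + 1.1*(region=='metro') - 0.01*(age-30)",
                  "-3.6 + 1.3*(region=='metro')",
                  "-4.4 + 1.2*(region=='metro')",
                  "-2.9 + 0.6*(region=='metro')",
                  "-2.1 + 0.2*(region=='metro')"),
                  demo_ethnicity_levels[-1])),
    truth_model("bmi", "lognormal", sd = 0.18, source_scope = "survey",
                lp = "3.17 + 0.0025*pmin(age, 60) + 0.01*(gender=='male')"),
    truth_model("smoking", "multinomial", levels = demo_smoking_levels,
                source_scope = "survey",
                lp = setNames(c(
                  "-1.3 + 0.045*(age-40) + 0.25*(gender=='male')",
                  "-1.2 - 0.012*(age-40) + 0.2*(gender=='male')",
                  "-2.3 + 0.02*(bmi-25)"),
                  c("past", "light", "heavy"))),
    truth_model("activity", "logistic", levels = c("no", "yes"),
                source_scope = "survey",
                lp = "0.9 - 0.012*(age-40) - 0.05*(bmi-25)"),
    truth_model("lung_cancer", "logistic", levels = c("no", "yes"),
                lp = paste0("-9.5 + 0.055*age + 0.95*(smoking=='heavy') +",
                            "0.55*(smoking=='light') + 0.45*(smoking=='past')")),
    truth_model("pancreas_cancer", "logistic", levels = c("no", "yes"),
                lp = "-10.4 + 0.055*age"),
    truth_model("p_chd", "probability", sd = 0.4,
                lp = "-5.6 + 0.07*age + 0.4*(gender=='male') + 0.3*(smoking=='heavy')"),
    truth_model("p_stroke", "probability", sd = 0.4,
                lp = "-6.5 + 0.075*age"),
    truth_model("p_diabetes", "probability", sd = 0.4,
                lp = "-5.3 + 0.055*age + 0.05*(bmi-25)"),
    truth_model("p_copd", "probability", sd = 0.4,
                lp = paste0("-6.2 + 0.06*age + 0.9*(smoking=='heavy') +",
                            "0.5*(smoking=='past')"))
  )
}

#' Demo configuration of the truth simulator
#'
#' The fixed validation scenario used throughout the package's tests and
#' vignette: a registry-like population with a ~3% age-biased adult survey
#' subsample carrying lifestyle variables under MAR item nonresponse, rare
#' cancer outcomes, and model-based disease-probability columns.
#'
#' @param n_population Population size.
#' @param rng_seed Integer seed.
#' @return A [truth_config()].
#' @export
demo_truth_config <- function(n_population = 100000L, rng_seed = 1L) {
  truth_config(
    n_population = n_population,
    seed_vars = demo_seed_vars(),
    true_models = demo_true_models(),
    survey_fraction = 0.03,
    survey_age_bias = 1.5,
    survey_min_age = 19,
    nonresponse = list(
      bmi = "-2.2 + 0.035*(age-50)",
      smoking = "-2.5 + 0.02*(age-50) + 0.3*(gender=='male')",
      activity = "-2.0 + 0.015*(age-50)"
    ),
    rng_seed = rng_seed
  )
}

#' Demo synthesis plan
#'
#' The synthesis plan matching [demo_truth_config()]: population-scope
#' socio-economic variables first, then survey-scope lifestyle variables
#' (fitted on the survey subsample after imputation), then the rare cancers
#' with missing-indicator lifestyle predictors, then disease-probability
#' columns fitted on the survey subsample. All models are stratified by
#' gender and use a natural spline of age.
#'
#' @param age_spline_df Spline degrees of freedom for age terms.
#' @return A [synthesis_plan()].
#' @export
demo_plan <- function(age_spline_df = 4L) {
  seed_specs <- list(
    variable_spec("age", "continuous"),
    variable_spec("gender", "binary", levels = c("female", "male")),
    variable_spec("region", "categorical",
                  levels = c("north", "east", "west", "south", "metro")),
    variable_spec("urbanization", "categorical", levels = paste0("u", 1:5))
  )
  out_specs <- list(
    variable_spec("income_source", "categorical", levels = demo_income_levels),
    variable_spec("income_pct", "continuous"),
    variable_spec("property_pct", "continuous"),
    variable_spec("household_type", "binary",
                  levels = c("non_institutional", "institutional")),
    variable_spec("household_size", "categorical",
                  levels = c("1", "2", "3", "4", "5", "6plus")),
    variable_spec("ethnicity", "categorical", levels = demo_ethnicity_levels),
    variable_spec("bmi", "continuous", source_scope = "survey",
                  missing_allowed = TRUE),
    variable_spec("smoking", "categorical", levels = demo_smoking_levels,
                  source_scope = "survey", missing_allowed = TRUE),
    variable_spec("activity", "binary", levels = c("no", "yes"),
                  source_scope = "survey", missing_allowed = TRUE),
    variable_spec("lung_cancer", "binary", levels = c("no", "yes")),
    variable_spec("pancreas_cancer", "binary", levels = c("no", "yes")),
    variable_spec("p_chd", "probability"),
    variable_spec("p_stroke", "probability"),
    variable_spec("p_diabetes", "probability"),
    variable_spec("p_copd", "probability")
  )
  df <- age_spline_df
  sequence <- list(
    model_spec("income_source", "multinomial",
               predictors = c("age", "region", "urbanization"),
               stratify_by = "gender", age_spline_df = df),
    model_spec("income_pct", "gaussian",
               predictors = c("age", "income_source"),
               stratify_by = "gender", age_spline_df = df),
    model_spec("property_pct", "gaussian",
               predictors = c("age", "income_pct"),
               stratify_by = "gender", age_spline_df = df),
    # institutional residence is rare (~1%) and concentrated at high ages:
    # linear age, to keep events-per-parameter sane at demo scale
    model_spec("household_type", "logistic",
               predictors = "age",
               stratify_by = "gender"),
    model_spec("household_size", "multinomial",
               predictors = c("age", "household_type"),
               stratify_by = "gender", age_spline_df = df),
    model_spec("ethnicity", "multinomial",
               predictors = c("age", "region", "urbanization"),
               stratify_by = "gender", age_spline_df = df),
    model_spec("bmi", "gaussian",
               predictors = "age",
               stratify_by = "gender", age_spline_df = df, fit_on = "survey"),
    model_spec("smoking", "multinomial",
               predictors = c("age", "bmi"),
               stratify_by = "gender", age_spline_df = df, fit_on = "survey"),
    model_spec("activity", "logistic",
               predictors = c("age", "bmi", "smoking"),
               stratify_by = "gender", age_spline_df = df, fit_on = "survey"),
    # rare outcomes: linear age (too few events per stratum to support a
    # spline at demo scale) and a single missing-indicator lifestyle term
    model_spec("lung_cancer", "logistic",
               predictors = c("age", "region", "smoking"),
               missing_indicator_predictors = "smoking",
               stratify_by = "gender"),
    model_spec("pancreas_cancer", "logistic",
               predictors = "age",
               stratify_by = "gender"),
    model_spec("p_chd", "gaussian",
               predictors = c("age", "smoking", "bmi"),
               stratify_by = "gender", age_spline_df = df, fit_on = "survey"),
    model_spec("p_stroke", "gaussian",
               predictors = "age",
               stratify_by = "gender", age_spline_df = df, fit_on = "survey"),
    model_spec("p_diabetes", "gaussian",
               predictors = c("age", "bmi"),
               stratify_by = "gender", age_spline_df = df, fit_on = "survey"),
    model_spec("p_copd", "gaussian",
               predictors = c("age", "smoking"),
               stratify_by = "gender", age_spline_df = df, fit_on = "survey")
  )
  synthesis_plan(seed_specs, out_specs, sequence, age_var = "age")
}

#' Misspecified-chain stress scenario
#'
#' A fixed four-outcome scenario demonstrating how sequential synthesis
#' accumulates error under model misspecification. The generating chain is
#' quadratic in each predecessor while the matching plan fits main (linear)
#' effects only. Because least-squares and logistic fits reproduce the
#' observed outcome mean on the fitting distribution, a single misspecified
#' model barely moves the marginal; what propagates is distributional
#' *shape*: the first outcome synthesizes almost perfectly, the second
#' acquires a shape distortion (its true conditional is curved), and every
#' later outcome both inherits its predecessors' distorted joint and adds a
#' fresh distortion of its own, so marginal total-variation distance grows
#' along the sequence.
#'
#' @param n_population Population size.
#' @param rng_seed Integer seed.
#' @return List with `config` (a [truth_config()]) and `plan`
#'   (a [synthesis_plan()]).
#' @export
misspec_scenario <- function(n_population = 50000L, rng_seed = 1L) {
  seed_vars <- list(
    age = list(values = 0:105, probs = rep(1 / 106, 106)),
    gender = list(levels = c("female", "male"), probs = c(0.5, 0.5))
  )
  models <- list(
    truth_model("y1", "gaussian", lp = "0.02*(age-40)", sd = 1),
    truth_model("y2", "gaussian", lp = "0.6*y1^2 - 0.3*y1", sd = 1),
    truth_model("y3", "gaussian", lp = "0.5*y2^2 - 0.4*y2 + 0.3*y1", sd = 1),
    truth_model("y4", "gaussian", lp = "0.4*y3^2 - 0.4*y3 + 0.3*y2", sd = 1)
  )
  config <- truth_config(n_population, seed_vars, models,
                         survey_fraction = 0.03, survey_min_age = 0,
                         rng_seed = rng_seed)
  seed_specs <- list(
    variable_spec("age", "continuous"),
    variable_spec("gender", "binary", levels = c("female", "male"))
  )
  out_specs <- lapply(paste0("y", 1:4), variable_spec, vtype = "continuous")
  sequence <- lapply(1:4, function(k) {
    model_spec(paste0("y", k), "gaussian",
               predictors = c("age", if (k > 1) paste0("y", seq_len(k - 1))),
               stratify_by = "gender", age_spline_df = 4L)
  })
  list(config = config,
       plan = synthesis_plan(seed_specs, out_specs, sequence, age_var = "age"))
}

#' Total-variation distance between two marginals
#'
#' Half the L1 distance between relative frequency tables. Categorical
#' vectors are tabulated directly; numeric vectors are first discretized on
#' a common quantile grid of `x` (`bins` cells), the usual device for
#' comparing continuous marginals on a TV scale.
#'
#' @param x,y Vectors (missing values dropped). `x` defines the bin grid for
#'   numeric input.
#' @param bins Number of quantile bins for numeric input.
#' @return TV distance in `[0, 1]`.
#' @export
tv_distance <- function(x, y, bins = 10L) {
  if (is.numeric(x) && is.numeric(y)) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), na.rm = TRUE))
    br[1] <- -Inf; br[length(br)] <- Inf
    x <- cut(as.numeric(x), br)
    y <- cut(as.numeric(y), br)
  }
  lv <- sort(unique(c(as.character(x[!is.na(x)]), as.character(y[!is.na(y)]))))
  px <- table(factor(as.character(x), levels = lv)) / sum(!is.na(x))
  py <- table(factor(as.character(y), levels = lv)) / sum(!is.na(y))
  sum(abs(as.numeric(px) - as.numeric(py))) / 2
}

#' Run the full demo pipeline
#'
#' End-to-end exercise of the two-step procedure on the demo scenario:
#' simulate the confidential truth population, fit the sequential chain with
#' multiple imputation (M = 5) in the secure zone, write and re-read the
#' disclosure-safe bundle, synthesize one replicate (calibrating lung-cancer
#' prevalence to the truth population marginal), and evaluate synthetic
#' against truth. When `out_dir` is given, every intermediate artifact is
#' written there (bundle JSON, synthetic population CSV, evaluation long
#' tables, a machine-readable run summary).
#'
#' @param out_dir Output directory, or `NULL` to keep everything in memory.
#' @param rng_seed Integer seed driving the whole run.
#' @param n_population Truth population size.
#' @param m_imputations Imputation count for survey nonresponse.
#' @return (Invisibly) list with `truth`, `plan`, `bundle`, `synthetic`,
#'   `report`, `calibration_target`, and `paths` (when writing).
#' @export
run_demo <- function(out_dir = NULL, rng_seed = 1L, n_population = 100000L,
                     m_imputations = 5L) {
  cfg <- demo_truth_config(n_population, rng_seed = derive_seed(rng_seed, 1L))
  truth <- simulate_truth(cfg)
  plan <- demo_plan()
  bundle <- fit_sequence(truth, plan, min_cell = 10L,
                         m_imputations = m_imputations,
                         rng_seed = derive_seed(rng_seed, 2L))
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$bundle <- file.path(out_dir, "bundle.json.gz")
    write_bundle(bundle, paths$bundle)
    bundle <- read_bundle(paths$bundle)
  }
  target <- mean(truth$lung_cancer == "yes")
  synthetic <- synthesize_population(
    bundle, rng_seed = derive_seed(rng_seed, 3L),
    calibration_targets = list(lung_cancer = target),
    fallback = "largest")

  eval_vars <- c("income_source", "income_pct", "property_pct",
                 "household_type", "household_size", "ethnicity",
                 "lung_cancer", "pancreas_cancer")
  truth_e <- dplyr::mutate(truth, age_class = recode_age(.data$age))
  synth_e <- dplyr::mutate(synthetic, age_class = recode_age(.data$age))
  report <- evaluate_populations(
    truth_e, synth_e, variables = eval_vars,
    stratified_outcomes = "household_type",
    strata_vars = c("age_class", "gender"),
    key_vars = c("age", "gender", "region", "urbanization",
                 "income_source", "household_size", "ethnicity"))

  if (!is.null(out_dir)) {
    paths$synthetic <- file.path(out_dir, "synthetic_population.csv")
    write_population(synthetic, paths$synthetic)
    paths$frequencies <- file.path(out_dir, "eval_frequencies.csv")
    readr::write_csv(report$univariate$frequencies, paths$frequencies)
    paths$moments <- file.path(out_dir, "eval_moments.csv")
    readr::write_csv(report$univariate$moments, paths$moments)
    paths$summary <- file.path(out_dir, "run_summary.json")
    summary <- list(
      n_truth = nrow(truth), n_synthetic = nrow(synthetic),
      seed_strata_total = attr(bundle$strata, "total"),
      n_seed_strata = nrow(bundle$strata),
      n_waived_strata = sum(bundle$strata$waived),
      lung_calibration_target = target,
      lung_calibration_factor =
        attr(synthetic, "provenance")$calibration_factors$lung_cancer,
      disclosure_match_rate = report$disclosure$rate,
      rng_seed = rng_seed)
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(truth = truth, plan = plan, bundle = bundle,
                 synthetic = synthetic, report = report,
                 calibration_target = target, paths = paths))
}
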