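#' Declare one generating model of the truth simulator
#'
#' The truth simulator draws a "confidential" ground-truth population from a
#' known sequential chain, so the whole fit-export-synthesize pipeline can be
#' validated against generating parameters. Each generating model states its
#' linear predictor(s) as R expressions over seed variables and earlier
#' outcomes, which keeps coefficients and interaction terms explicit and lets
#' marginals be computed analytically where the ancestry is discrete.
#'
#' Families: `gaussian` (`value = lp + N(0, sd^2)`), `logistic`
#' (`Bernoulli(plogis(lp))`), `multinomial` (softmax over per-level linear
#' predictors, first level reference at 0), `probability`
#' (`plogis(lp + N(0, sd^2))`, emulating upstream model-based disease
#' probabilities), plus two generator-only shapes used to stress the gaussian
#' fitting family: `uniform` (`U(min, max)`) and `lognormal`
#' (`exp(lp + N(0, sdlog^2))`).
#'
#' @param outcome Variable name.
#' @param family Generating family (see Details).
#' @param lp Linear-predictor expression (string), or for `multinomial` a
#'   named character vector of expressions for every non-reference level.
#' @param sd Residual standard deviation (`gaussian`, `probability`) or
#'   `sdlog` (`lognormal`).
#' @param levels Category labels (`logistic`: exactly 2, first = "no"/0;
#'   `multinomial`: reference first).
#' @param min,max Range for `uniform`.
#' @param source_scope `"population"` or `"survey"` (survey-scope values are
#'   blanked outside the survey subsample).
#' @return A `chainsynth_truth_model`.
#' @export
truth_model <- function(outcome,
                        family = c("gaussian", "logistic", "multinomial",
                                   "probability", "uniform", "lognormal"),
                        lp = "0", sd = 1, levels = NULL,
                        min = 0, max = 1,
                        source_scope = c("population", "survey")) {
  family <- match.arg(family)
  source_scope <- match.arg(source_scope)
  if (family == "logistic") {
    levels <- levels %||% c("no", "yes")
    stopifnot(length(levels) == 2)
  }
  if (family == "multinomial") {
    stopifnot(!is.null(levels), length(levels) >= 2,
              !is.null(names(lp)), all(names(lp) %in% levels[-1]),
              length(lp) == length(levels) - 1)
  }
  structure(list(outcome = outcome, family = family, lp = lp, sd = sd,
                 levels = levels, min = min, max = max,
                 source_scope = source_scope),
            class = "chainsynth_truth_model")
}

#' Configure the truth simulator
#'
#' @param n_population Number of individuals to draw.
#' @param seed_vars Named list describing seed-variable marginals; each entry
#'   is `list(values = ..., probs = ...)` (numeric values, e.g. single-year
#'   age) or `list(levels = ..., probs = ...)` (categorical). Seeds are drawn
#'   independently.
#' @param true_models Ordered list of [truth_model()] objects; each may
#'   reference seed variables and earlier outcomes only.
#' @param survey_fraction Expected survey-subsample share of the whole
#'   population (default 0.03, the canonical ~3% health-monitor fraction).
#' @param survey_age_bias Odds multiplier on survey participation per decade
#'   of age; 1 = unbiased, >1 oversamples the elderly.
#' @param survey_min_age Minimum age for survey eligibility (health surveys
#'   typically cover adults; default 19).
#' @param nonresponse Named list mapping survey-scope outcome names to
#'   logit-scale missingness expressions (evaluated per survey row), the MAR
#'   item-nonresponse mechanism.
#' @param rng_seed Integer seed; identical configs + seed give byte-identical
#'   populations.
#' @return A `chainsynth_truth_config`.
#' @export
truth_config <- function(n_population, seed_vars, true_models,
                         survey_fraction = 0.03, survey_age_bias = 1,
                         survey_min_age = 19,
                         nonresponse = list(), rng_seed = 1L) {
  stopifnot(n_population >= 1, survey_fraction > 0, survey_fraction <= 1,
            survey_age_bias > 0)
  for (nm in names(seed_vars)) {
    sv <- seed_vars[[nm]]
    vals <- sv$values %||% sv$levels
    stopifnot(length(vals) == length(sv$probs), abs(sum(sv$probs) - 1) < 1e-8)
  }
  cfg <- structure(
    list(n_population = as.integer(n_population), seed_vars = seed_vars,
         true_models = true_models, survey_fraction = survey_fraction,
         survey_age_bias = survey_age_bias, survey_min_age = survey_min_age,
         nonresponse = nonresponse, rng_seed = as.integer(rng_seed)),
    class = "chainsynth_truth_config")
  check_truth_refs(cfg)
  cfg
}

# every lp expression may reference only seeds and earlier outcomes
check_truth_refs <- function(config) {
  known <- names(config$seed_vars)
  for (tm in config$true_models) {
    refs <- unique(unlist(lapply(tm$lp, function(e) all.vars(parse(text = e)))))
    bad <- setdiff(refs, known)
    if (length(bad)) {
      abort(paste0("generating model for '", tm$outcome,
                   "' references undefined variable(s): ",
                   paste(bad, collapse = ", ")))
    }
    known <- c(known, tm$outcome)
  }
  for (nm in names(config$nonresponse)) {
    if (nm %!in% known) abort(paste0("nonresponse for undefined variable '", nm, "'"))
    refs <- all.vars(parse(text = config$nonresponse[[nm]]))
    bad <- setdiff(refs, known)
    if (length(bad)) {
      abort(paste0("nonresponse model for '", nm,
                   "' references undefined variable(s): ", paste(bad, collapse = ", ")))
    }
  }
  invisible(config)
}

eval_lp <- function(expr, data) {
  v <- eval(parse(text = expr), envir = data, enclos = baseenv())
  if (length(v) == 1) v <- rep(as.numeric(v), nrow(data))
  as.numeric(v)
}

# vectorised categorical draw from an n x K probability matrix
sample_categories <- function(probs, levels) {
  cum <- t(apply(probs, 1, cumsum))
  u <- runif(nrow(probs)) * cum[, ncol(cum)]
  idx <- rowSums(u > cum) + 1L
  levels[idx]
}

softmax_probs <- function(lps) {
  m <- do.call(cbind, lps)
  m <- cbind(0, m)                       # reference level linear predictor 0
  m <- exp(m - apply(m, 1, max))
  m / rowSums(m)
}

draw_truth_outcome <- function(tm, data) {
  n <- nrow(data)
  switch(tm$family,
    gaussian = eval_lp(tm$lp, data) + rnorm(n, 0, tm$sd),
    probability = plogis(eval_lp(tm$lp, data) + rnorm(n, 0, tm$sd)),
    logistic = tm$levels[rbinom(n, 1, plogis(eval_lp(tm$lp, data))) + 1L],
    multinomial = {
      lps <- lapply(tm$levels[-1], function(lv) eval_lp(tm$lp[[lv]], data))
      sample_categories(softmax_probs(lps), tm$levels)
    },
    uniform = runif(n, tm$min, tm$max),
    lognormal = exp(eval_lp(tm$lp, data) + rnorm(n, 0, tm$sd))
  )
}

#' Simulate a ground-truth population with a biased survey subsample
#'
#' Draws `n_population` individuals from the configured generative chain:
#' independent seed variables, then each outcome in order conditional on its
#' declared predictors. A survey subsample is then selected (age-biased when
#' `survey_age_bias != 1`, emulating oversampling of the elderly) and item
#' nonresponse is injected into survey-scope columns among survey rows only.
#' Survey-scope columns are `NA` for all non-survey rows.
#'
#' The pre-nonresponse values of survey rows are retained in attribute
#' `"pre_nonresponse"` so imputation procedures can be validated against the
#' values that were actually masked.
#'
#' @param config A [truth_config()].
#' @return A tibble with one row per person, a 0/1 `survey_flag` column, and
#'   attributes `"pre_nonresponse"` and `"provenance"`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "chainsynth_truth_config"))
  check_truth_refs(config)
  with_seed(config$rng_seed, function() {
    n <- config$n_population
    pop <- tibble(.rows = n)
    for (nm in names(config$seed_vars)) {
      sv <- config$seed_vars[[nm]]
      vals <- sv$values %||% sv$levels
      pop[[nm]] <- sample(vals, n, replace = TRUE, prob = sv$probs)
    }
    for (tm in config$true_models) {
      pop[[tm$outcome]] <- draw_truth_outcome(tm, pop)
    }

    age <- pop[["age"]] %||% rep(0, n)
    eligible <- age >= config$survey_min_age
    target <- n * config$survey_fraction
    if (sum(eligible) < target) {
      abort("survey_fraction unattainable: too few survey-eligible individuals")
    }
    p_sel <- rep(0, n)
    if (config$survey_age_bias == 1) {
      p_sel[eligible] <- target / sum(eligible)
    } else {
      slope <- log(config$survey_age_bias)
      z <- (age[eligible] - mean(age[eligible])) / 10
      a <- stats::uniroot(function(a) sum(plogis(a + slope * z)) - target,
                          lower = -50, upper = 50, tol = 1e-10)$root
      p_sel[eligible] <- plogis(a + slope * z)
    }
    pop$survey_flag <- rbinom(n, 1, p_sel)

    survey_cols <- vapply(config$true_models, function(tm)
      if (tm$source_scope == "survey") tm$outcome else NA_character_, character(1))
    survey_cols <- survey_cols[!is.na(survey_cols)]
    in_survey <- pop$survey_flag == 1

    pre_nr <- pop[in_survey, c(survey_cols), drop = FALSE]
    pre_nr$.row <- which(in_survey)

    for (nm in names(config$nonresponse)) {
      p_miss <- plogis(eval_lp(config$nonresponse[[nm]], pop[in_survey, ]))
      drop <- rbinom(sum(in_survey), 1, p_miss) == 1
      col <- pop[[nm]]
      col[which(in_survey)[drop]] <- NA
      pop[[nm]] <- col
    }
    for (nm in survey_cols) {
      col <- pop[[nm]]
      col[!in_survey] <- NA
      pop[[nm]] <- col
    }

    attr(pop, "pre_nonresponse") <- as_tibble(pre_nr)
    attr(pop, "provenance") <- list(config_hash = content_hash(unclass(config)),
                                    rng_seed = config$rng_seed)
    pop
  })
}

#' Marginal distribution implied by a truth configuration
#'
#' Computes the marginal law of one variable under the generating chain,
#' analytically by total probability whenever every ancestor of the variable
#' is discrete (seed variables, logistic or multinomial outcomes) and the
#' joint ancestor grid is tractable, and otherwise by high-precision Monte
#' Carlo. Serves as the oracle against which simulated and synthesized
#' marginals are judged.
#'
#' @param config A [truth_config()].
#' @param variable Variable name.
#' @param n_mc Monte-Carlo size for the fallback path.
#' @return For discrete variables a tibble `(level, prob)`; for continuous
#'   variables a tibble `(moment, value)` with mean, sd, skewness and excess
#'   kurtosis. Attribute `"method"` is `"exact"` or `"monte_carlo"`.
#' @export
true_marginals <- function(config, variable, n_mc = 500000L) {
  stopifnot(inherits(config, "chainsynth_truth_config"))
  if (variable %in% names(config$seed_vars)) {
    sv <- config$seed_vars[[variable]]
    out <- tibble(level = as.character(sv$values %||% sv$levels),
                  prob = as.numeric(sv$probs))
    attr(out, "method") <- "exact"
    return(out)
  }
  outcomes <- vapply(config$true_models, `[[`, character(1), "outcome")
  pos <- match(variable, outcomes)
  if (is.na(pos)) abort(paste0("variable '", variable, "' not defined in config"))
  tm <- config$true_models[[pos]]

  exact <- try(exact_marginal(config, pos), silent = TRUE)
  if (!inherits(exact, "try-error") && !is.null(exact)) return(exact)

  # Monte-Carlo fallback on an enlarged copy of the chain (no survey masking)
  mc_cfg <- config
  mc_cfg$n_population <- as.integer(n_mc)
  mc_cfg$nonresponse <- list()
  mc_cfg$survey_fraction <- 1
  mc_cfg$survey_min_age <- 0
  mc_cfg$rng_seed <- derive_seed(config$rng_seed, 104729L)
  pop <- simulate_truth(mc_cfg)
  x <- pop[[variable]]
  out <- if (tm$family %in% c("logistic", "multinomial")) {
    tab <- table(factor(x, levels = tm$levels))
    tibble(level = names(tab), prob = as.numeric(tab) / length(x))
  } else {
    fm <- four_moments(x)
    tibble(moment = c("mean", "sd", "skewness", "excess_kurtosis"),
           value = c(fm$mean, fm$sd, fm$skewness, fm$excess_kurtosis))
  }
  attr(out, "method") <- "monte_carlo"
  attr(out, "mc_n") <- n_mc
  out
}

# Exact marginal by enumerating the discrete ancestor grid; NULL/error when
# any ancestor is continuous or the grid exceeds the cell cap.
exact_marginal <- function(config, pos, max_cells = 200000L) {
  models <- config$true_models
  outcomes <- vapply(models, `[[`, character(1), "outcome")
  tm <- models[[pos]]
  if (tm$family %!in% c("logistic", "multinomial")) return(NULL)

  needed <- unique(unlist(lapply(tm$lp, function(e) all.vars(parse(text = e)))))
  repeat {
    extra <- character()
    for (v in intersect(needed, outcomes)) {
      k <- match(v, outcomes)
      if (models[[k]]$family %!in% c("logistic", "multinomial")) return(NULL)
      extra <- c(extra, unlist(lapply(models[[k]]$lp,
                                      function(e) all.vars(parse(text = e)))))
    }
    new_needed <- unique(c(needed, extra))
    if (length(new_needed) == length(needed)) break
    needed <- new_needed
  }

  grid <- tibble(prob = 1)
  for (nm in intersect(names(config$seed_vars), needed)) {
    sv <- config$seed_vars[[nm]]
    vals <- sv$values %||% sv$levels
    grid <- tidyr::crossing(grid, tibble(!!nm := vals, .p = sv$probs)) |>
      dplyr::mutate(prob = prob * .data$.p) |> dplyr::select(-".p")
    if (nrow(grid) > max_cells) return(NULL)
  }
  for (k in seq_len(pos - 1L)) {
    nm <- outcomes[k]
    if (nm %!in% needed) next
    mk <- models[[k]]
    probs <- truth_cat_probs(mk, grid)
    pieces <- lapply(seq_along(mk$levels), function(j) {
      g <- grid
      g[[nm]] <- mk$levels[j]
      g$prob <- g$prob * probs[, j]
      g
    })
    grid <- dplyr::bind_rows(pieces) |> dplyr::filter(prob > 0)
    if (nrow(grid) > max_cells) return(NULL)
  }

  probs <- truth_cat_probs(tm, grid)
  marg <- as.numeric(colSums(probs * grid$prob))
  out <- tibble(level = tm$levels, prob = marg / sum(grid$prob))
  attr(out, "method") <- "exact"
  out
}

truth_cat_probs <- function(tm, data) {
  if (tm$family == "logistic") {
    p <- plogis(eval_lp(tm$lp, data))
    cbind(1 - p, p)
  } else {
    softmax_probs(lapply(tm$levels[-1], function(lv) eval_lp(tm$lp[[lv]], data)))
  }
}
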