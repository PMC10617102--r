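#' Declare a variable in a synthesis plan
#'
#' A `variable_spec` records everything the engine needs to know about one
#' column of the person-level table: its measurement type, the admissible
#' category levels, whether it is observed for the whole population or only
#' for survey participants, and whether item nonresponse is allowed.
#'
#' @param name Column name (unique within a plan).
#' @param vtype One of `"categorical"`, `"binary"`, `"continuous"`,
#'   `"probability"`. Probability variables take values in `[0, 1]` (e.g.
#'   model-based disease probabilities carried as columns).
#' @param levels Ordered character vector of category labels. Required for
#'   categorical/binary (at least two), forbidden otherwise.
#' @param source_scope `"population"` if observed for every row,
#'   `"survey"` if observed only for survey-flagged rows.
#' @param missing_allowed Whether item nonresponse may occur in this column
#'   (within its scope).
#'
#' @return An object of class `chainsynth_variable`.
#' @export
#' @examples
#' variable_spec("smoking", "categorical",
#'   levels = c("never", "past", "light", "heavy"), source_scope = "survey")
variable_spec <- function(name, vtype,
                          levels = NULL,
                          source_scope = c("population", "survey"),
                          missing_allowed = FALSE) {
  stopifnot(is_string(name))
  vtype <- match.arg(vtype, c("categorical", "binary", "continuous", "probability"))
  source_scope <- match.arg(source_scope)
  if (vtype %in% c("categorical", "binary")) {
    if (is.null(levels) || length(levels) < 2) {
      abort(paste0("variable '", name, "': categorical/binary specs need at least 2 levels"))
    }
    levels <- as.character(levels)
    if (anyDuplicated(levels)) abort(paste0("variable '", name, "': duplicated levels"))
    if (vtype == "binary" && length(levels) != 2) {
      abort(paste0("variable '", name, "': binary specs need exactly 2 levels"))
    }
  } else if (!is.null(levels)) {
    abort(paste0("variable '", name, "': continuous/probability specs take no levels"))
  }
  structure(
    list(name = name, vtype = vtype, levels = levels,
         source_scope = source_scope, missing_allowed = isTRUE(missing_allowed)),
    class = "chainsynth_variable"
  )
}

#' Declare the regression model for one outcome in the sequence
#'
#' @param outcome Name of the outcome variable.
#' @param family `"gaussian"` (continuous and probability outcomes; probability
#'   outcomes are modelled on the logit scale), `"logistic"` (binary) or
#'   `"multinomial"` (categorical).
#' @param predictors Variable names entering the linear predictor. Under the
#'   sequential constraint these may only be seed variables or outcomes earlier
#'   in the sequence.
#' @param stratify_by Variables the model is stratified by (a separate fit per
#'   combination); gender at minimum in typical plans. Must be disjoint from
#'   `predictors`.
#' @param age_spline_df If the age variable is among the predictors, represent
#'   it by a natural cubic spline with this many degrees of freedom (`NULL`
#'   for a linear age term).
#' @param missing_indicator_predictors Subset of `predictors` encoded by the
#'   missing-indicator method: a filled value plus a 0/1 missingness flag, so
#'   rows without the predictor remain usable.
#' @param fit_on `"population"` to fit on all rows, `"survey"` to fit on
#'   survey-flagged rows only.
#'
#' @return An object of class `chainsynth_model_spec`.
#' @export
model_spec <- function(outcome, family = c("gaussian", "logistic", "multinomial"),
                       predictors = character(),
                       stratify_by = character(),
                       age_spline_df = NULL,
                       missing_indicator_predictors = character(),
                       fit_on = c("population", "survey")) {
  stopifnot(is_string(outcome))
  family <- match.arg(family)
  fit_on <- match.arg(fit_on)
  if (!is.null(age_spline_df)) {
    stopifnot(is.numeric(age_spline_df), length(age_spline_df) == 1, age_spline_df >= 2)
    age_spline_df <- as.integer(age_spline_df)
  }
  structure(
    list(outcome = outcome, family = family,
         predictors = as.character(predictors),
         stratify_by = as.character(stratify_by),
         age_spline_df = age_spline_df,
         missing_indicator_predictors = as.character(missing_indicator_predictors),
         fit_on = fit_on),
    class = "chainsynth_model_spec"
  )
}

#' Assemble a synthesis plan
#'
#' A plan fixes the seed variables (whose joint counts are exported verbatim),
#' the ordered sequence of outcome models, and the admissible age range.
#'
#' @param seed_vars List of [variable_spec()] for the seed variables (the
#'   low-disclosure-risk anchors: age, gender, region, urbanization in the
#'   canonical setup).
#' @param outcome_vars List of [variable_spec()] for the modelled outcomes.
#' @param sequence Ordered list of [model_spec()], one per outcome.
#' @param age_var Name of the age variable (must be a seed variable).
#' @param age_range Two-element numeric, ages admitted into the synthesis;
#'   defaults to `c(0, 105)`.
#'
#' @return An object of class `chainsynth_plan`.
#' @seealso [validate_plan()], [fit_sequence()]
#' @export
synthesis_plan <- function(seed_vars, outcome_vars, sequence,
                           age_var, age_range = c(0, 105)) {
  stopifnot(is.list(seed_vars), is.list(outcome_vars), is.list(sequence))
  stopifnot(is_string(age_var), is.numeric(age_range), length(age_range) == 2)
  structure(
    list(seed_vars = seed_vars, outcome_vars = outcome_vars,
         sequence = sequence, age_var = age_var,
         age_range = as.numeric(age_range)),
    class = "chainsynth_plan"
  )
}

plan_seed_names <- function(plan) vapply(plan$seed_vars, `[[`, character(1), "name")
plan_outcome_names <- function(plan) vapply(plan$outcome_vars, `[[`, character(1), "name")
plan_sequence_outcomes <- function(plan) vapply(plan$sequence, `[[`, character(1), "outcome")

plan_variable <- function(plan, name) {
  for (v in c(plan$seed_vars, plan$outcome_vars)) if (v$name == name) return(v)
  NULL
}

family_for_vtype <- function(vtype) {
  switch(vtype,
         continuous = "gaussian", probability = "gaussian",
         binary = "logistic", categorical = "multinomial")
}

#' Validate a synthesis plan
#'
#' Checks every structural invariant of a plan and returns the violations as a
#' character vector instead of throwing, so a plan authored in YAML can be
#' linted in one pass. An empty result means the plan is well formed.
#'
#' Checked rules: unique variable names; each sequence outcome declared exactly
#' once and carrying a matching [variable_spec()]; the sequential constraint
#' (predictors of the k-th outcome drawn only from seed variables and outcomes
#' 1..k-1); family/vtype agreement (gaussian for continuous/probability,
#' logistic for binary, multinomial for categorical); `predictors` and
#' `stratify_by` disjoint; stratification variables categorical; age range
#' ordered within `[0, 105]`.
#'
#' @param plan A [synthesis_plan()].
#' @return Character vector of violation messages; `character(0)` when valid.
#' @export
#' @examples
#' seeds <- list(variable_spec("gender", "binary", c("f", "m")))
#' outs <- list(variable_spec("y", "continuous"))
#' plan <- synthesis_plan(seeds, outs,
#'   list(model_spec("y", "gaussian", predictors = "gender")),
#'   age_var = "age")
#' validate_plan(plan) # character(0) apart from the age-var note
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "chainsynth_plan"))
  bad <- character()
  say <- function(...) bad[[length(bad) + 1L]] <<- paste0(...)

  seed_names <- plan_seed_names(plan)
  out_names <- plan_outcome_names(plan)
  all_names <- c(seed_names, out_names)
  if (anyDuplicated(all_names)) {
    say("duplicate variable names in plan: ",
        paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }

  seq_out <- plan_sequence_outcomes(plan)
  if (anyDuplicated(seq_out)) {
    say("outcome appears more than once in sequence: ",
        paste(unique(seq_out[duplicated(seq_out)]), collapse = ", "))
  }
  for (nm in setdiff(seq_out, out_names)) {
    say("model '", nm, "': outcome has no variable_spec in the plan")
  }
  for (nm in setdiff(out_names, seq_out)) {
    say("variable '", nm, "': declared as outcome but missing from the sequence")
  }

  for (k in seq_along(plan$sequence)) {
    ms <- plan$sequence[[k]]
    allowed <- c(seed_names, seq_out[seq_len(k - 1L)])
    off <- setdiff(ms$predictors, allowed)
    if (length(off)) {
      say("model '", ms$outcome, "' (position ", k,
          "): sequential constraint violated, predictors not among seed variables ",
          "or earlier outcomes: ", paste(off, collapse = ", "))
    }
    vs <- plan_variable(plan, ms$outcome)
    if (!is.null(vs)) {
      expected <- family_for_vtype(vs$vtype)
      if (!identical(ms$family, expected)) {
        say("model '", ms$outcome, "': family mismatch, '", ms$family,
            "' declared for ", vs$vtype, " outcome (expected '", expected, "')")
      }
    }
    both <- intersect(ms$predictors, ms$stratify_by)
    if (length(both)) {
      say("model '", ms$outcome, "': variables in both predictors and stratify_by: ",
          paste(both, collapse = ", "))
    }
    off2 <- setdiff(ms$stratify_by, allowed)
    if (length(off2)) {
      say("model '", ms$outcome, "': stratify_by not among seed variables or earlier outcomes: ",
          paste(off2, collapse = ", "))
    }
    for (sv in ms$stratify_by) {
      v <- plan_variable(plan, sv)
      if (!is.null(v) && v$vtype %!in% c("categorical", "binary")) {
        say("model '", ms$outcome, "': stratify_by variable '", sv, "' is not categorical")
      }
    }
    off3 <- setdiff(ms$missing_indicator_predictors, ms$predictors)
    if (length(off3)) {
      say("model '", ms$outcome, "': missing_indicator_predictors not among predictors: ",
          paste(off3, collapse = ", "))
    }
  }

  if (plan$age_var %!in% all_names) {
    say("age_var '", plan$age_var, "' is not a plan variable")
  }
  if (plan$age_range[1] >= plan$age_range[2] ||
      plan$age_range[1] < 0 || plan$age_range[2] > 105) {
    say("age_range must be increasing and within [0, 105]")
  }
  bad
}

# ---- association measures for ranking -------------------------------------

cramers_v <- function(x, y) {
  tab <- table(x, y)
  if (min(dim(tab)) < 2) return(0)
  n <- sum(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (n * (min(dim(tab)) - 1)))
  min(v, 1)
}

# correlation ratio eta: share of variance of the numeric variable explained
# by the grouping variable
correlation_ratio <- function(groups, values) {
  ok <- !is.na(groups) & !is.na(values)
  groups <- groups[ok]; values <- values[ok]
  tot <- sum((values - mean(values))^2)
  if (tot <= 0) return(0)
  m <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  between <- sum(n * (m - mean(values))^2)
  sqrt(max(0, min(1, between / tot)))
}

# association on a common [0,1] scale for mixed-type column pairs
mixed_association <- function(x, y) {
  xn <- is.numeric(x); yn <- is.numeric(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(0)
  if (xn && yn) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    abs(stats::cor(x, y))
  } else if (!xn && !yn) {
    cramers_v(x, y)
  } else if (xn) {
    correlation_ratio(y, x)
  } else {
    correlation_ratio(x, y)
  }
}

#' Rank candidate outcomes for the modelling sequence
#'
#' Orders candidate variables by decreasing strength of association with the
#' growing conditioning set (seed variables plus already-ranked candidates),
#' the greedy analogue of ranking "top-down by decrease in magnitude of
#' correlation". Association is measured on a common `[0, 1]` scale: absolute
#' Pearson correlation (numeric-numeric), Cramer's V (categorical-categorical)
#' and the correlation ratio eta (mixed); a candidate's score against the set
#' is the maximum over its pairwise associations. Ties break by variable name.
#'
#' @param data Person-level data frame.
#' @param seed_vars Names of the seed variables (the initial conditioning set).
#' @param candidates Names of the variables to rank.
#' @return Character vector: `candidates` in suggested modelling order.
#' @export
rank_variables <- function(data, seed_vars, candidates) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(seed_vars, candidates), names(data))
  if (length(missing_cols)) {
    abort(paste0("variables absent from data: ", paste(missing_cols, collapse = ", ")))
  }
  candidates <- as.character(candidates)
  ranked <- character()
  remaining <- candidates
  while (length(remaining)) {
    cond <- c(seed_vars, ranked)
    scores <- vapply(remaining, function(cand) {
      max(vapply(cond, function(cv) mixed_association(data[[cand]], data[[cv]]),
                 numeric(1)), 0)
    }, numeric(1))
    best <- max(scores)
    pick <- sort(remaining[scores == best])[1]  # lexicographic tie-break
    ranked <- c(ranked, pick)
    remaining <- setdiff(remaining, pick)
  }
  ranked
}

# ---- YAML plan IO ----------------------------------------------------------

#' Read or write a synthesis plan as YAML
#'
#' Plans are authored declaratively; the YAML layout mirrors
#' [variable_spec()] and [model_spec()] field names one-to-one.
#'
#' @param path File path.
#' @param plan A [synthesis_plan()] (for `write_plan`).
#' @return `read_plan` returns a [synthesis_plan()]; `write_plan` the path,
#'   invisibly.
#' @export
read_plan <- function(path) {
  plan_from_list(yaml::read_yaml(path))
}

#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "chainsynth_plan"))
  yaml::write_yaml(plan_to_list(plan), path)
  invisible(path)
}

# plain-list representations shared by the YAML plan files and the JSON bundle
plan_from_list <- function(raw) {
  as_varspec <- function(v) {
    variable_spec(unlist(v$name), unlist(v$vtype), levels = unlist(v$levels),
                  source_scope = unlist(v$source_scope) %||% "population",
                  missing_allowed = isTRUE(unlist(v$missing_allowed)))
  }
  as_modspec <- function(m) {
    model_spec(unlist(m$outcome), unlist(m$family),
               predictors = unlist(m$predictors) %||% character(),
               stratify_by = unlist(m$stratify_by) %||% character(),
               age_spline_df = unlist(m$age_spline_df),
               missing_indicator_predictors =
                 unlist(m$missing_indicator_predictors) %||% character(),
               fit_on = unlist(m$fit_on) %||% "population")
  }
  synthesis_plan(
    seed_vars = lapply(raw$seed_vars, as_varspec),
    outcome_vars = lapply(raw$outcome_vars, as_varspec),
    sequence = lapply(raw$sequence, as_modspec),
    age_var = unlist(raw$age_var),
    age_range = unlist(raw$age_range) %||% c(0, 105)
  )
}

plan_to_list <- function(plan) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  list(
    seed_vars = lapply(plan$seed_vars, strip),
    outcome_vars = lapply(plan$outcome_vars, strip),
    sequence = lapply(plan$sequence, strip),
    age_var = plan$age_var,
    age_range = plan$age_range
  )
}

#' @export
print.chainsynth_plan <- function(x, ...) {
  cat("<chainsynth_plan>\n")
  cat("  seed variables:   ", paste(plan_seed_names(x), collapse = ", "), "\n")
  cat("  sequence (", length(x$sequence), " outcomes):\n", sep = "")
  for (k in seq_along(x$sequence)) {
    ms <- x$sequence[[k]]
    cat(sprintf("    %2d. %s [%s, fit on %s]\n", k, ms$outcome, ms$family, ms$fit_on))
  }
  cat("  age variable: ", x$age_var, " in [",
      x$age_range[1], ", ", x$age_range[2], "]\n", sep = "")
  invisible(x)
}
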