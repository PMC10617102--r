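#' Tabulate seed-variable strata with the minimum-cell rule
#'
#' Counts individuals per combination of seed-variable values. These counts
#' are the only row-level information that ever leaves the secure zone, so the
#' function enforces a minimum stratum size (default 10 persons per
#' combination): strata below it are either dropped, waived (retained but
#' flagged, the usual choice when the seed variables themselves are
#' insensitive), or merged into the nearest stratum.
#'
#' @param data Person-level data frame.
#' @param seed_vars Names of the seed columns (must be complete).
#' @param min_cell Minimum stratum count (default 10).
#' @param policy `"waive"` (keep, flag), `"drop"` (remove), or `"merge"`
#'   (add the count to the nearest stratum that agrees on all but the last
#'   seed variable; falls back to drop when no such stratum exists).
#' @return A tibble of class `chainsynth_strata`: one row per retained
#'   stratum with the seed values, `count` and `waived` columns; attributes
#'   `total` (sum of retained counts), `seed_vars`, `min_cell`, `policy`.
#' @export
extract_seed_strata <- function(data, seed_vars, min_cell = 10L,
                                policy = c("waive", "drop", "merge")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(seed_vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("seed column(s) absent: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) > 0 && anyNA(data[seed_vars])) {
    bad <- seed_vars[vapply(data[seed_vars], anyNA, logical(1))]
    abort(paste0("missing values in seed column(s): ", paste(bad, collapse = ", ")))
  }
  tab <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(seed_vars)), name = "count") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(seed_vars)))
  small <- tab$count < min_cell
  tab$waived <- FALSE
  if (any(small)) {
    if (policy == "waive") {
      tab$waived <- small
    } else if (policy == "drop") {
      tab <- tab[!small, , drop = FALSE]
    } else { # merge into nearest neighbour on the last seed variable
      last <- seed_vars[length(seed_vars)]
      head_vars <- seed_vars[-length(seed_vars)]
      for (i in which(small)) {
        cand <- rep(TRUE, nrow(tab))
        for (v in head_vars) cand <- cand & (tab[[v]] == tab[[v]][i])
        cand[i] <- FALSE
        cand <- cand & tab$count >= min_cell
        if (any(cand)) {
          j <- which(cand)
          if (is.numeric(tab[[last]])) {
            j <- j[which.min(abs(tab[[last]][j] - tab[[last]][i]))]
          } else {
            j <- j[which.max(tab$count[j])]
          }
          tab$count[j] <- tab$count[j] + tab$count[i]
          tab$count[i] <- 0L
        }
      }
      tab <- tab[tab$count >= min_cell, , drop = FALSE]
    }
  }
  out <- as_tibble(tab)
  for (a in setdiff(names(attributes(out)), c("names", "row.names", "class"))) {
    attr(out, a) <- NULL   # drop attributes inherited from the input table
  }
  attr(out, "total") <- sum(out$count)
  attr(out, "seed_vars") <- seed_vars
  attr(out, "min_cell") <- as.integer(min_cell)
  attr(out, "policy") <- policy
  class(out) <- c("chainsynth_strata", class(out))
  out
}

# ---- single-model fitting --------------------------------------------------

new_fitted <- function(outcome, family, vtype, stratum, design = NULL,
                       coef = NULL, vcov = NULL, residual_sd = NULL,
                       n_fit, levels = NULL, ref = NULL,
                       degenerate = FALSE, constant = NULL,
                       transform = "identity", quasi_separated = FALSE) {
  structure(
    list(outcome = outcome, family = family, vtype = vtype, stratum = stratum,
         design = design, coef = coef, vcov = vcov, residual_sd = residual_sd,
         n_fit = as.integer(n_fit), levels = levels, ref = ref,
         degenerate = isTRUE(degenerate), constant = constant,
         transform = transform, quasi_separated = isTRUE(quasi_separated)),
    class = "chainsynth_fitted")
}

clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

fit_gaussian_stratum <- function(y, X, ctx) {
  fit <- lm.fit(X, y)
  p <- fit$rank
  if (p < ncol(X)) {
    abort(paste0(ctx, ": design matrix rank-deficient (",
                 p, " < ", ncol(X), " columns)"))
  }
  res <- fit$residuals
  dfres <- length(y) - p
  sigma2 <- if (dfres > 0) sum(res^2) / dfres else 0
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  V <- sigma2 * XtX_inv
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = setNames(fit$coefficients, colnames(X)),
       vcov = V, residual_sd = sqrt(sigma2))
}

fit_logistic_stratum <- function(y01, X, ctx) {
  fit <- suppressWarnings(glm.fit(X, y01, family = binomial()))
  if (!fit$converged) abort(paste0(ctx, ": logistic fit did not converge"))
  # perfect separation drives (nearly) every fitted probability to 0/1;
  # unbounded drift of a zero-event subgroup (e.g. a missing-indicator cell)
  # only affects that subgroup and is tolerated but flagged
  mu <- fit$fitted.values
  if (mean(pmin(mu, 1 - mu) < 1e-8) > 0.5) {
    abort(paste0(ctx, ": separation detected in logistic fit"))
  }
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  V <- tryCatch(solve(XtWX),
                error = function(e) abort(paste0(ctx, ": singular information matrix")))
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = setNames(fit$coefficients, colnames(X)), vcov = V,
       quasi_separated = any(abs(fit$coefficients) > 15))
}

fit_multinomial_stratum <- function(y, X, levels_obs, ref, ctx) {
  yf <- factor(y, levels = c(ref, setdiff(levels_obs, ref)))
  df <- as.data.frame(X[, -1, drop = FALSE])
  if (ncol(df)) names(df) <- paste0("c", seq_len(ncol(df)))  # syntactic, remapped below
  fml <- if (ncol(df)) yf ~ . else yf ~ 1
  fit <- tryCatch(
    nnet::multinom(fml, data = df, trace = FALSE, Hess = TRUE,
                   maxit = 300, MaxNWts = 20000, reltol = 1e-8),
    error = function(e) abort(paste0(ctx, ": multinomial fit failed: ", conditionMessage(e))))
  if (fit$convergence != 0) abort(paste0(ctx, ": multinomial fit did not converge"))
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)  # two observed levels
  if (any(abs(cf) > 35)) {
    abort(paste0(ctx, ": (quasi-)separation detected in multinomial fit"))
  }
  nonref <- setdiff(levels(yf), ref)
  dimnames(cf) <- list(nonref, colnames(X))
  # canonical parameter order: level-major, matching as.vector(t(coef))
  V <- vcov(fit)
  pn <- as.vector(t(outer(nonref, colnames(X), paste, sep = ":")))
  dimnames(V) <- list(pn, pn)
  list(coef = cf, vcov = V)
}

#' Fit one outcome's per-stratum regression models
#'
#' Fits the declared family by maximum likelihood within each stratum of
#' `stratify_by`: ordinary least squares for gaussian outcomes (probability
#' outcomes are logit-transformed first, clamped to `[1e-6, 1 - 1e-6]`),
#' iteratively reweighted least squares for logistic, and baseline-category
#' multinomial logit for categorical outcomes. Coefficient covariances come
#' from the inverse observed information (classical `sigma^2 (X'X)^{-1}` for
#' OLS). A stratum whose outcome is constant yields a flagged degenerate
#' model that simply emits the constant.
#'
#' @param data Fitting rows (already restricted to the model's `fit_on`
#'   scope); outcome must be non-missing.
#' @param ms A [model_spec()].
#' @param plan The enclosing [synthesis_plan()].
#' @return List of `chainsynth_fitted`, one per stratum, named by stratum key.
#' @export
fit_variable <- function(data, ms, plan) {
  stopifnot(inherits(ms, "chainsynth_model_spec"), inherits(plan, "chainsynth_plan"))
  vs <- plan_variable(plan, ms$outcome)
  if (is.null(vs)) abort(paste0("outcome '", ms$outcome, "' not declared in plan"))
  keep <- !is.na(data[[ms$outcome]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) abort(paste0("no rows with observed outcome '", ms$outcome, "'"))
  strata <- split_strata(data, ms$stratify_by)
  keys <- attr(strata, "keys")

  models <- imap(strata, function(rows, key) {
    sub <- data[rows, , drop = FALSE]
    ctx <- paste0("outcome '", ms$outcome, "', stratum ", key)
    stratum <- if (length(ms$stratify_by)) as.list(keys[match(key, names(strata)), ]) else list()
    y <- sub[[ms$outcome]]

    if (length(unique(y)) == 1L) {
      return(new_fitted(ms$outcome, ms$family, vs$vtype, stratum,
                        n_fit = nrow(sub), levels = vs$levels,
                        degenerate = TRUE, constant = y[[1]]))
    }
    design <- build_design(ms, sub, plan)
    X <- encode(design, sub)
    if (nrow(X) < ncol(X) + 2) {
      abort(paste0(ctx, ": too few rows (", nrow(X), ") for ", ncol(X), " parameters"))
    }

    if (ms$family == "gaussian") {
      transform <- if (vs$vtype == "probability") "logit" else "identity"
      yy <- if (transform == "logit") qlogis(clamp_prob(as.numeric(y))) else as.numeric(y)
      f <- fit_gaussian_stratum(yy, X, ctx)
      new_fitted(ms$outcome, ms$family, vs$vtype, stratum, design,
                 f$coef, f$vcov, f$residual_sd, nrow(sub), transform = transform)
    } else if (ms$family == "logistic") {
      y01 <- as.numeric(factor(y, levels = vs$levels)) - 1
      f <- fit_logistic_stratum(y01, X, ctx)
      new_fitted(ms$outcome, ms$family, vs$vtype, stratum, design,
                 f$coef, f$vcov, NULL, nrow(sub),
                 levels = vs$levels, ref = vs$levels[1],
                 quasi_separated = f$quasi_separated)
    } else {
      obs_levels <- vs$levels[vs$levels %in% unique(as.character(y))]
      ref <- names(sort(table(factor(y, levels = obs_levels)), decreasing = TRUE))[1]
      f <- fit_multinomial_stratum(as.character(y), X, obs_levels, ref, ctx)
      new_fitted(ms$outcome, ms$family, vs$vtype, stratum, design,
                 f$coef, f$vcov, NULL, nrow(sub),
                 levels = c(ref, setdiff(obs_levels, ref)), ref = ref)
    }
  })
  models
}

# ---- full sequence ---------------------------------------------------------

#' Fit the sequential model chain and assemble the export bundle
#'
#' Runs the whole secure-zone step: validates the plan, enforces the age
#' range, tabulates the seed strata under the minimum-cell rule, then fits
#' every outcome model in sequence order. Survey-scope fits with item
#' nonresponse go through chained-equation multiple imputation
#' ([impute_chained()]) with the per-imputation fits pooled by Rubin's rules
#' ([pool_rubin()]) before export, so the bundle carries pooled coefficients
#' and total covariances. The result holds no row-level data beyond the seed
#' stratum counts.
#'
#' @param data Person-level confidential table (with `survey_flag` if the plan
#'   has survey-scope models).
#' @param plan A valid [synthesis_plan()].
#' @param min_cell,min_cell_policy Passed to [extract_seed_strata()].
#' @param m_imputations Number of completed datasets for survey nonresponse
#'   (default 5).
#' @param mice_iterations Chained-equation sweeps per imputation.
#' @param rng_seed Seed driving the imputation draws.
#' @return A `chainsynth_bundle`: plan, seed strata, fitted models in
#'   sequence order, provenance.
#' @export
fit_sequence <- function(data, plan, min_cell = 10L,
                         min_cell_policy = "waive",
                         m_imputations = 5L, mice_iterations = 10L,
                         rng_seed = 1L) {
  stopifnot(inherits(plan, "chainsynth_plan"))
  bad <- validate_plan(plan)
  if (length(bad)) {
    abort(paste0("invalid plan:\n", paste(" -", bad, collapse = "\n")))
  }
  if (plan$age_var %in% names(data)) {
    in_range <- data[[plan$age_var]] >= plan$age_range[1] &
      data[[plan$age_var]] <= plan$age_range[2]
    data <- data[in_range, , drop = FALSE]
  }
  seed_names <- plan_seed_names(plan)
  strata <- extract_seed_strata(data, seed_names, min_cell = min_cell,
                                policy = min_cell_policy)

  survey_scope <- vapply(plan$outcome_vars, function(v)
    if (v$source_scope == "survey") v$name else NA_character_, character(1))
  survey_scope <- survey_scope[!is.na(survey_scope)]
  has_survey_fit <- any(vapply(plan$sequence, function(m) m$fit_on == "survey", logical(1)))
  imputations <- NULL
  if (has_survey_fit && length(survey_scope)) {
    if ("survey_flag" %!in% names(data)) abort("plan has survey-scope models but data lacks 'survey_flag'")
    srows <- data[data$survey_flag == 1, , drop = FALSE]
    needs_imp <- vapply(survey_scope, function(v) anyNA(srows[[v]]), logical(1))
    if (any(needs_imp)) {
      imputations <- impute_chained(
        srows, chain_specs_from_plan(plan),
        M = m_imputations, iterations = mice_iterations,
        rng_seed = derive_seed(rng_seed, 11L))
    }
  }

  models <- list()
  for (k in seq_along(plan$sequence)) {
    ms <- plan$sequence[[k]]
    fits <- tryCatch({
      if (ms$fit_on == "survey") {
        if (!is.null(imputations)) {
          fit_pooled_variable(imputations, ms, plan)
        } else {
          fit_variable(data[data$survey_flag == 1, , drop = FALSE], ms, plan)
        }
      } else {
        fit_variable(data, ms, plan)
      }
    }, error = function(e) {
      abort(paste0("sequence position ", k, ": ", conditionMessage(e)))
    })
    models[[ms$outcome]] <- fits
  }

  structure(
    list(plan = plan, strata = strata, models = models,
         provenance = list(
           fitted_at = format(Sys.time(), tz = "UTC", usetz = TRUE),
           data_hash = content_hash(list(dim(data), names(data))),
           n_fit_rows = nrow(data),
           software = paste0("chainsynth ",
                             as.character(utils::packageVersion("chainsynth"))),
           m_imputations = if (!is.null(imputations)) imputations$M)),
    class = "chainsynth_bundle")
}

# Fit a survey-scope model on each completed imputation and pool with Rubin's
# rules; degenerate strata and residual variances are taken from the first
# imputation (variance pooled as the mean across imputations).
fit_pooled_variable <- function(imputations, ms, plan) {
  per_imp <- lapply(imputations$tables, fit_variable, ms = ms, plan = plan)
  keys <- names(per_imp[[1]])
  out <- lapply(keys, function(key) {
    fits <- lapply(per_imp, `[[`, key)
    fits <- fits[!vapply(fits, is.null, logical(1))]
    base <- fits[[1]]
    if (length(fits) == 1L || base$degenerate) return(base)
    if (any(vapply(fits, `[[`, logical(1), "degenerate"))) return(fits[[1]])
    vec <- function(f) if (is.matrix(f$coef)) as.vector(t(f$coef)) else f$coef
    pooled <- pool_rubin(lapply(fits, function(f) list(coef = vec(f), vcov = f$vcov)))
    base$coef <- if (is.matrix(base$coef)) {
      matrix(pooled$Q_bar, nrow = nrow(base$coef), byrow = TRUE,
             dimnames = dimnames(base$coef))
    } else setNames(pooled$Q_bar, names(base$coef))
    base$vcov <- pooled$T
    dimnames(base$vcov) <- dimnames(fits[[1]]$vcov)
    if (!is.null(base$residual_sd)) {
      base$residual_sd <- sqrt(mean(vapply(fits, `[[`, numeric(1), "residual_sd")^2))
    }
    base
  })
  setNames(out, keys)
}

#' @export
print.chainsynth_bundle <- function(x, ...) {
  cat("<chainsynth_bundle>\n")
  cat("  seed strata: ", nrow(x$strata), " (total ", attr(x$strata, "total"),
      ", ", sum(x$strata$waived), " waived)\n", sep = "")
  cat("  models:\n")
  for (nm in names(x$models)) {
    cat(sprintf("    %-18s %d stratum fit(s)\n", nm, length(x$models[[nm]])))
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a model bundle into a coefficient table
#'
#' @param x A `chainsynth_bundle`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: outcome, stratum, (category
#'   for multinomial), term, estimate, std.error.
#' @export
tidy.chainsynth_bundle <- function(x, ...) {
  rows <- list()
  for (nm in names(x$models)) {
    for (key in names(x$models[[nm]])) {
      f <- x$models[[nm]][[key]]
      if (f$degenerate) {
        rows[[length(rows) + 1L]] <- tibble(
          outcome = nm, stratum = key, category = NA_character_,
          term = "(constant)", estimate = suppressWarnings(as.numeric(f$constant)),
          std.error = 0)
        next
      }
      se <- sqrt(pmax(0, diag(f$vcov)))
      if (is.matrix(f$coef)) {
        est <- as.vector(t(f$coef))
        rows[[length(rows) + 1L]] <- tibble(
          outcome = nm, stratum = key,
          category = rep(rownames(f$coef), each = ncol(f$coef)),
          term = rep(colnames(f$coef), nrow(f$coef)),
          estimate = est, std.error = se)
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          outcome = nm, stratum = key, category = NA_character_,
          term = names(f$coef), estimate = unname(f$coef), std.error = se)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' One-line summary of a model bundle
#'
#' @param x A `chainsynth_bundle`.
#' @param ... Unused.
#' @return One-row tibble: number of models, strata, waived strata, total
#'   population represented.
#' @export
glance.chainsynth_bundle <- function(x, ...) {
  tibble(
    n_outcomes = length(x$models),
    n_stratum_fits = sum(vapply(x$models, length, integer(1))),
    n_seed_strata = nrow(x$strata),
    n_waived_strata = sum(x$strata$waived),
    population_total = attr(x$strata, "total"))
}
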