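#' Conditional imputation models for survey nonresponse
#'
#' Builds the default chained-equation specification from a plan: every
#' survey-scope variable that allows missingness gets a conditional model of
#' its declared family, with the seed variables (age as a natural spline) and
#' all other survey-scope variables as predictors. Under item nonresponse
#' that is missing-at-random given age and gender, these conditionals make
#' the imputation well posed.
#'
#' @param plan A [synthesis_plan()].
#' @param age_spline_df Spline df for the age term in each conditional.
#' @return A `chainsynth_chain_specs` object (list of [model_spec()] with the
#'   plan attached).
#' @export
chain_specs_from_plan <- function(plan, age_spline_df = 3L) {
  survey_vars <- vapply(plan$outcome_vars, function(v)
    if (v$source_scope == "survey") v$name else NA_character_, character(1))
  survey_vars <- survey_vars[!is.na(survey_vars)]
  imputable <- vapply(plan$outcome_vars, function(v)
    v$source_scope == "survey" && v$missing_allowed, logical(1))
  targets <- vapply(plan$outcome_vars[imputable], `[[`, character(1), "name")
  specs <- lapply(targets, function(v) {
    vs <- plan_variable(plan, v)
    model_spec(v, family_for_vtype(vs$vtype),
               predictors = c(plan_seed_names(plan), setdiff(survey_vars, v)),
               age_spline_df = if (plan$age_var %in% plan_seed_names(plan)) age_spline_df,
               fit_on = "survey")
  })
  structure(setNames(specs, targets), plan = plan,
            class = "chainsynth_chain_specs")
}

# posterior-predictive draw of missing values for one conditional model
draw_imputation <- function(ms, plan, data, obs, mis) {
  vs <- plan_variable(plan, ms$outcome)
  # chained-equation conditionals ignore the sequential constraint on purpose:
  # build the design directly
  design <- build_design(ms, data[obs, , drop = FALSE], plan)
  Xo <- encode(design, data[obs, , drop = FALSE])
  Xm <- encode(design, data[mis, , drop = FALSE])
  y <- data[[ms$outcome]][obs]
  ctx <- paste0("imputation model for '", ms$outcome, "'")

  if (length(unique(y)) == 1L) return(rep(y[[1]], length(mis)))

  if (ms$family == "gaussian") {
    transform <- if (vs$vtype == "probability") "logit" else "identity"
    yy <- if (transform == "logit") qlogis(clamp_prob(as.numeric(y))) else as.numeric(y)
    fit <- lm.fit(Xo, yy)
    p <- fit$rank
    if (p < ncol(Xo)) abort(paste0(ctx, ": rank-deficient design"))
    dfres <- length(yy) - p
    rss <- sum(fit$residuals^2)
    sigma2_star <- rss / rchisq(1, df = dfres)
    XtX_inv <- chol2inv(qr.R(fit$qr))
    beta_star <- fit$coefficients +
      drop(t(chol(sigma2_star * XtX_inv)) %*% rnorm(p))
    draw <- drop(Xm %*% beta_star) + rnorm(length(mis), 0, sqrt(sigma2_star))
    if (transform == "logit") plogis(draw) else draw
  } else if (ms$family == "logistic") {
    y01 <- as.numeric(factor(y, levels = vs$levels)) - 1
    f <- fit_logistic_stratum(y01, Xo, ctx)
    beta_star <- MASS::mvrnorm(1, f$coef, f$vcov)
    vs$levels[rbinom(length(mis), 1, plogis(drop(Xm %*% beta_star))) + 1L]
  } else {
    obs_levels <- vs$levels[vs$levels %in% unique(as.character(y))]
    ref <- names(sort(table(factor(y, levels = obs_levels)), decreasing = TRUE))[1]
    f <- fit_multinomial_stratum(as.character(y), Xo, obs_levels, ref, ctx)
    beta_star <- MASS::mvrnorm(1, as.vector(t(f$coef)), f$vcov)
    B <- matrix(beta_star, nrow = nrow(f$coef), byrow = TRUE)
    lps <- lapply(seq_len(nrow(B)), function(j) drop(Xm %*% B[j, ]))
    sample_categories(softmax_probs(lps), c(ref, rownames(f$coef)))
  }
}

#' Chained-equation multiple imputation of survey item nonresponse
#'
#' Produces `M` completed copies of the survey rows by sequential conditional
#' draws in the chained-equation style: missing cells are first filled by
#' random draws from the observed marginals, then each variable with
#' missingness is repeatedly re-imputed from its conditional model fitted on
#' the currently completed data, for a fixed number of full sweeps. Gaussian
#' conditionals use proper posterior-predictive draws (scaled inverse
#' chi-squared residual variance, normal coefficients); categorical
#' conditionals draw coefficients from their asymptotic normal and then
#' sample categories. Observed cells are never altered.
#'
#' @param data Survey rows (a data frame); missingness only in variables with
#'   a chain spec.
#' @param chain_specs From [chain_specs_from_plan()].
#' @param M Number of completed datasets (default 5, the usual replication
#'   count for risk-factor surveys).
#' @param iterations Full chained-equation sweeps per imputation (default 10).
#' @param rng_seed Integer seed; results are reproducible given the seed.
#' @return A `chainsynth_imputation_set`: list with `M`, `tables` (list of
#'   completed tibbles), `chain_specs`, `iterations`, `rng_seed`.
#' @export
impute_chained <- function(data, chain_specs, M = 5L, iterations = 10L,
                           rng_seed = 1L) {
  stopifnot(inherits(chain_specs, "chainsynth_chain_specs"), M >= 1, iterations >= 1)
  plan <- attr(chain_specs, "plan")
  data <- as_tibble(data)
  targets <- names(chain_specs)
  all_missing <- targets[vapply(targets, function(v) all(is.na(data[[v]])), logical(1))]
  if (length(all_missing)) {
    abort(paste0("variable(s) missing for every row (conditional inestimable): ",
                 paste(all_missing, collapse = ", ")))
  }
  miss_outside <- setdiff(names(which(vapply(data, anyNA, logical(1)))),
                          targets)
  miss_outside <- intersect(miss_outside, c(plan_seed_names(plan), plan_outcome_names(plan)))
  if (length(miss_outside)) {
    abort(paste0("missingness in variable(s) without a chain spec: ",
                 paste(miss_outside, collapse = ", ")))
  }
  miss_idx <- lapply(setNames(targets, targets), function(v) which(is.na(data[[v]])))
  active <- targets[vapply(miss_idx, length, integer(1)) > 0]

  tables <- lapply(seq_len(M), function(m) {
    with_seed(derive_seed(rng_seed, 211L, m), function() {
      cur <- data
      for (v in active) {  # initial fill from observed marginals
        obs_vals <- cur[[v]][!is.na(cur[[v]])]
        cur[[v]][miss_idx[[v]]] <- sample(obs_vals, length(miss_idx[[v]]), replace = TRUE)
      }
      if (length(active)) {
        for (it in seq_len(iterations)) {
          for (v in active) {
            mis <- miss_idx[[v]]
            obs <- setdiff(seq_len(nrow(cur)), mis)
            cur[[v]][mis] <- draw_imputation(chain_specs[[v]], plan, cur, obs, mis)
          }
        }
      }
      cur
    })
  })
  structure(list(M = as.integer(M), tables = tables, chain_specs = chain_specs,
                 iterations = as.integer(iterations), rng_seed = as.integer(rng_seed)),
            class = "chainsynth_imputation_set")
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines `M` sets of coefficient estimates and covariance matrices into a
#' pooled estimate: `Q_bar` is the mean estimate, `W` the mean
#' within-imputation covariance, `B` the between-imputation empirical
#' covariance (divisor `M - 1`), and the total covariance
#' `T = W + (1 + 1/M) B`. With a single estimate, `B` is undefined and
#' `T = W`.
#'
#' @param estimates List of `list(coef = <numeric vector>, vcov = <matrix>)`
#'   (a scalar variance is accepted for scalar estimates).
#' @return A `chainsynth_pooled`: list with `Q_bar`, `W`, `B`, `T`, `M`.
#' @export
#' @examples
#' pool_rubin(list(list(coef = 1, vcov = 0.5), list(coef = 3, vcov = 0.5)))
pool_rubin <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 1)
  coefs <- lapply(estimates, function(e) as.numeric(e$coef))
  d <- length(coefs[[1]])
  if (any(vapply(coefs, length, integer(1)) != d)) {
    abort("pool_rubin: estimate dimensions differ")
  }
  covs <- lapply(estimates, function(e) {
    V <- e$vcov
    if (is.null(dim(V))) V <- diag(as.numeric(V), nrow = d)
    if (!all(dim(V) == d)) abort("pool_rubin: covariance dimensions differ from estimates")
    V
  })
  M <- length(estimates)
  Q_bar <- Reduce(`+`, coefs) / M
  W <- Reduce(`+`, covs) / M
  if (M == 1) {
    B <- NULL
    Tm <- W
  } else {
    dev <- lapply(coefs, function(q) tcrossprod(q - Q_bar))
    B <- Reduce(`+`, dev) / (M - 1)
    Tm <- W + (1 + 1 / M) * B
  }
  structure(list(Q_bar = Q_bar, W = W, B = B, T = Tm, M = M),
            class = "chainsynth_pooled")
}

#' @export
print.chainsynth_pooled <- function(x, ...) {
  cat("<chainsynth_pooled> M =", x$M, "\n")
  cat("  Q_bar:", format(x$Q_bar, digits = 4), "\n")
  cat("  total variance diag:", format(diag(x$T), digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.chainsynth_pooled <- function(x, ...) {
  tibble(term = names(x$Q_bar) %||% paste0("b", seq_along(x$Q_bar) - 1L),
         estimate = unname(x$Q_bar),
         std.error = sqrt(diag(x$T)),
         within_var = diag(x$W),
         between_var = if (is.null(x$B)) NA_real_ else diag(x$B))
}
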