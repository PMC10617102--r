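#' Expand seed-strata counts into a seed population
#'
#' Deterministically replicates each seed-variable combination by its exported
#' count - no sampling is involved, so the synthetic seed joint distribution
#' equals the strata table exactly. Rows appear in stratum order, then index.
#'
#' @param strata A `chainsynth_strata` table from [extract_seed_strata()] (or
#'   read back from a bundle).
#' @return Tibble of seed columns with `sum(count)` rows.
#' @export
expand_seed <- function(strata) {
  stopifnot(inherits(strata, "chainsynth_strata"))
  seed_vars <- attr(strata, "seed_vars")
  out <- tidyr::uncount(as_tibble(strata)[c(seed_vars, "count")], count)
  for (a in setdiff(names(attributes(out)), c("names", "row.names", "class"))) {
    attr(out, a) <- NULL
  }
  stopifnot(nrow(out) == attr(strata, "total"))
  out
}

#' Draw one outcome from a fitted predictive equation
#'
#' Vectorised sampling of an outcome column given an encoded covariate
#' matrix: gaussian values are `X b` plus a normal residual draw, logistic
#' outcomes are Bernoulli in the inverse-logit of the linear predictor,
#' multinomial categories follow the softmax over per-category linear
#' predictors (reference category at 0), and probability-type outcomes are
#' the inverse logit of a gaussian draw on the logit scale. Degenerate
#' models emit their constant.
#'
#' @param model A `chainsynth_fitted`.
#' @param X Covariate matrix matching `model$design` (ignored for degenerate
#'   models).
#' @return Vector of drawn values (character for categorical outcomes).
#' @export
draw_outcome <- function(model, X) {
  stopifnot(inherits(model, "chainsynth_fitted"))
  if (model$degenerate) return(rep(model$constant, nrow(X)))
  probs <- outcome_probs(model, X)
  n <- nrow(X)
  switch(model$family,
    gaussian = {
      v <- probs$lp + rnorm(n, 0, model$residual_sd)
      if (model$transform == "logit") plogis(v) else v
    },
    logistic = model$levels[rbinom(n, 1, probs$p) + 1L],
    multinomial = sample_categories(probs$p, model$levels))
}

# linear predictors / event probabilities for a fitted model on encoded rows
outcome_probs <- function(model, X) {
  check_X <- function(p) {
    if (ncol(X) != p) {
      abort(paste0("covariate matrix (", ncol(X), " columns) does not match design of '",
                   model$outcome, "' (", p, " columns)"))
    }
  }
  if (model$family == "multinomial") {
    check_X(ncol(model$coef))
    lps <- lapply(seq_len(nrow(model$coef)), function(j) drop(X %*% model$coef[j, ]))
    list(p = softmax_probs(lps))
  } else {
    check_X(length(model$coef))
    lp <- drop(X %*% model$coef)
    if (model$family == "logistic") list(p = plogis(lp)) else list(lp = lp)
  }
}

#' Calibrate a probability vector to a target mean
#'
#' Scales all probabilities by one common factor `c`, capping at 1, with `c`
#' solved by monotone bisection so that the capped mean equals
#' `target_mean` - the post-hoc prevalence calibration used when a generated
#' rare-outcome prevalence must match a known population marginal.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param target_mean Desired mean, in `(0, 1)` and attainable (at most the
#'   share of nonzero probabilities).
#' @return The adjusted vector, with the solved factor in attribute
#'   `"factor"`. The capped mean matches the target within `1e-10`.
#' @export
#' @examples
#' calibrate_marginal(c(0.1, 0.3), 0.4) # factor 2: (0.2, 0.6)
calibrate_marginal <- function(probabilities, target_mean) {
  p <- as.numeric(probabilities)
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  if (!is.numeric(target_mean) || length(target_mean) != 1 ||
      target_mean <= 0 || target_mean >= 1) {
    abort("target_mean must be a single value in (0, 1)")
  }
  attainable <- mean(p > 0)
  if (target_mean > attainable + 1e-12) {
    abort(paste0("target mean ", target_mean, " unattainable: at most ",
                 signif(attainable, 6), " with the zero pattern of the input"))
  }
  m0 <- mean(p)
  if (abs(m0 - target_mean) <= 1e-15) {
    out <- p
    attr(out, "factor") <- 1
    return(out)
  }
  capped_mean <- function(c) mean(pmin(c * p, 1))
  c_lin <- target_mean / m0
  if (max(c_lin * p) <= 1) {           # no capping: exact linear solution
    out <- c_lin * p
    attr(out, "factor") <- c_lin
    return(out)
  }
  lo <- 0; hi <- c_lin
  while (capped_mean(hi) < target_mean) hi <- hi * 2
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (capped_mean(mid) < target_mean) lo <- mid else hi <- mid
  }
  cc <- (lo + hi) / 2
  if (abs(capped_mean(cc) - target_mean) > 1e-10) {
    abort("calibration bisection failed to reach the target within 1e-10")
  }
  out <- pmin(cc * p, 1)
  attr(out, "factor") <- cc
  out
}

#' Synthesize a population from a model bundle
#'
#' The open-zone step: expands the exported seed-strata counts into a seed
#' population and draws every outcome in sequence order from the bundle's
#' predictive equations, each conditional on the seed variables and the
#' previously synthesized columns, routed through the per-stratum fits by the
#' row's own (possibly synthesized) stratum values. Optionally the
#' coefficients of every model are redrawn once per replicate from
#' `MVN(Q, T)` to propagate parameter uncertainty, and selected variables are
#' calibrated to target marginals.
#'
#' Calibrated binary outcomes additionally carry a `<name>_prob` column with
#' the calibrated per-row probabilities (whose mean equals the target), since
#' a realized Bernoulli draw cannot hit the target exactly. Probability-type
#' outcomes are emitted as probability columns by default; set
#' `probability_as_binary = TRUE` to emit realized states instead.
#'
#' @param bundle A `chainsynth_bundle` (from [fit_sequence()] or
#'   [read_bundle()]).
#' @param rng_seed Integer seed. Outcome draws depend only on the seed and
#'   sequence position, so replicates with `draw_parameters = FALSE` are
#'   identical and replicates with `draw_parameters = TRUE` differ only
#'   through the parameter redraw.
#' @param n_replicates Number of synthetic populations.
#' @param draw_parameters Redraw coefficients from their estimated sampling
#'   distribution once per replicate.
#' @param calibration_targets Named list `variable = target_mean` for
#'   [calibrate_marginal()] on binary or probability-type outcomes.
#' @param fallback What to do when a row's stratum has no fitted model
#'   (possible when stratifying on a synthesized variable): `"error"`
#'   (default) or `"largest"` (route to the fit with the largest `n_fit`).
#' @param probability_as_binary Emit Bernoulli realizations for
#'   probability-type outcomes.
#' @return One tibble (or a list of tibbles for `n_replicates > 1`) with
#'   attributes `"replicate"` and `"provenance"` (bundle hash, seed,
#'   calibration factors applied).
#' @export
synthesize_population <- function(bundle, rng_seed = 1L, n_replicates = 1L,
                                  draw_parameters = FALSE,
                                  calibration_targets = NULL,
                                  fallback = c("error", "largest"),
                                  probability_as_binary = FALSE) {
  stopifnot(inherits(bundle, "chainsynth_bundle"), n_replicates >= 1)
  fallback <- match.arg(fallback)
  reps <- lapply(seq_len(n_replicates), function(r) {
    synth_one(bundle, rng_seed, r, draw_parameters, calibration_targets,
              fallback, probability_as_binary)
  })
  if (n_replicates == 1L) reps[[1]] else reps
}

synth_one <- function(bundle, rng_seed, replicate, draw_parameters,
                      calibration_targets, fallback, probability_as_binary,
                      record_implied = FALSE) {
  pop <- expand_seed(bundle$strata)
  n <- nrow(pop)
  models <- bundle$models
  if (draw_parameters) {
    models <- with_seed(derive_seed(rng_seed, 31L, replicate), function() {
      lapply(models, function(fits) lapply(fits, redraw_coefficients))
    })
  }
  factors <- list()
  implied <- list()
  for (k in seq_along(models)) {
    outcome <- names(models)[k]
    fits <- models[[k]]
    ms <- bundle$plan$sequence[[k]]
    vs <- plan_variable(bundle$plan, outcome)
    routed <- route_rows(pop, ms$stratify_by, fits, outcome, fallback)

    with_seed(derive_seed(rng_seed, 97L, k), function() {
      if (ms$family == "gaussian") {
        col <- rep(NA_real_, n)
        for (j in seq_along(fits)) {
          rows <- routed[[j]]
          if (!length(rows)) next
          f <- fits[[j]]
          col[rows] <- if (f$degenerate) as.numeric(f$constant) else {
            draw_outcome(f, encode(f$design, pop[rows, , drop = FALSE]))
          }
        }
        if (outcome %in% names(calibration_targets)) {
          if (vs$vtype != "probability") {
            abort(paste0("calibration target for non-probability gaussian outcome '",
                         outcome, "'"))
          }
          col <- calibrate_marginal(col, calibration_targets[[outcome]])
          factors[[outcome]] <<- attr(col, "factor")
          col <- as.numeric(col)
        }
        if (vs$vtype == "probability" && probability_as_binary) {
          pop[[paste0(outcome, "_prob")]] <<- col
          col <- as.numeric(rbinom(n, 1, col))
        }
        if (record_implied) implied[[outcome]] <<- tibble(
          variable = outcome, level = NA_character_, value = mean(col))
        pop[[outcome]] <<- col
      } else if (ms$family == "logistic") {
        pvec <- rep(NA_real_, n)
        lv <- fits[[1]]$levels %||% vs$levels
        for (j in seq_along(fits)) {
          rows <- routed[[j]]
          if (!length(rows)) next
          f <- fits[[j]]
          pvec[rows] <- if (f$degenerate) {
            as.numeric(identical(as.character(f$constant), vs$levels[2]))
          } else {
            outcome_probs(f, encode(f$design, pop[rows, , drop = FALSE]))$p
          }
        }
        if (outcome %in% names(calibration_targets)) {
          pvec <- calibrate_marginal(pvec, calibration_targets[[outcome]])
          factors[[outcome]] <<- attr(pvec, "factor")
          pvec <- as.numeric(pvec)
          pop[[paste0(outcome, "_prob")]] <<- pvec
        }
        if (record_implied) implied[[outcome]] <<- tibble(
          variable = outcome, level = vs$levels,
          value = c(1 - mean(pvec), mean(pvec)))
        pop[[outcome]] <<- vs$levels[rbinom(n, 1, pvec) + 1L]
      } else { # multinomial
        col <- rep(NA_character_, n)
        acc <- setNames(numeric(length(vs$levels)), vs$levels)
        for (j in seq_along(fits)) {
          rows <- routed[[j]]
          if (!length(rows)) next
          f <- fits[[j]]
          if (f$degenerate) {
            col[rows] <- as.character(f$constant)
            acc[as.character(f$constant)] <- acc[as.character(f$constant)] + length(rows)
          } else {
            P <- outcome_probs(f, encode(f$design, pop[rows, , drop = FALSE]))$p
            col[rows] <- sample_categories(P, f$levels)
            acc[f$levels] <- acc[f$levels] + colSums(P)
          }
        }
        if (record_implied) implied[[outcome]] <<- tibble(
          variable = outcome, level = names(acc), value = unname(acc) / n)
        pop[[outcome]] <<- col
      }
    })
  }
  attr(pop, "replicate") <- replicate
  attr(pop, "provenance") <- list(
    bundle_hash = content_hash(list(names(models), attr(bundle$strata, "total"))),
    rng_seed = rng_seed,
    draw_parameters = draw_parameters,
    calibration_factors = factors)
  if (record_implied) attr(pop, "implied_marginals") <- dplyr::bind_rows(implied)
  pop
}

# assign each row to a stratum fit index; list parallel to fits
route_rows <- function(pop, stratify_by, fits, outcome, fallback) {
  if (length(stratify_by) == 0) return(list(seq_len(nrow(pop))))
  key <- rep("", nrow(pop))
  for (v in stratify_by) {
    if (v %!in% names(pop)) {
      abort(paste0("stratification variable '", v, "' not yet synthesized for '",
                   outcome, "'"))
    }
    key <- paste0(key, ifelse(nzchar(key), "|", ""), v, "=", as.character(pop[[v]]))
  }
  idx <- match(key, names(fits))
  if (anyNA(idx)) {
    if (fallback == "error") {
      missing_keys <- unique(key[is.na(idx)])
      abort(paste0("no fitted model for outcome '", outcome, "' in stratum ",
                   missing_keys[1],
                   if (length(missing_keys) > 1) paste0(" (and ", length(missing_keys) - 1,
                                                        " more)"),
                   "; consider fallback = \"largest\""))
    }
    largest <- which.max(vapply(fits, `[[`, integer(1), "n_fit"))
    idx[is.na(idx)] <- largest
  }
  lapply(seq_along(fits), function(j) which(idx == j))
}

redraw_coefficients <- function(f) {
  if (f$degenerate) return(f)
  if (is.matrix(f$coef)) {
    draw <- MASS::mvrnorm(1, as.vector(t(f$coef)), f$vcov)
    f$coef <- matrix(draw, nrow = nrow(f$coef), byrow = TRUE,
                     dimnames = dimnames(f$coef))
  } else {
    f$coef <- setNames(MASS::mvrnorm(1, f$coef, f$vcov), names(f$coef))
  }
  f
}

#' Model-implied marginals of a bundle
#'
#' Computes the marginal distribution each variable would have under the
#' bundle's own predictive equations applied to the seed population, with
#' categorical marginals Rao-Blackwellized (per-row category probabilities
#' averaged over rows, conditional on the sampled history), so they carry far
#' less Monte-Carlo noise than a realized draw. Used to separate model error
#' from sampling error when judging a synthetic population.
#'
#' @param bundle A `chainsynth_bundle`.
#' @param rng_seed Seed for the history sampling.
#' @param calibration_targets As in [synthesize_population()]; supply the
#'   same targets used at synthesis time so implied and synthesized marginals
#'   refer to the same (calibrated) equations.
#' @param fallback As in [synthesize_population()].
#' @return Tibble `(variable, level, value)`: category probabilities for
#'   discrete variables (`level` set) and means for continuous ones
#'   (`level = NA`).
#' @export
model_implied_marginals <- function(bundle, rng_seed = 1L,
                                    calibration_targets = NULL,
                                    fallback = c("error", "largest")) {
  fallback <- match.arg(fallback)
  pop <- synth_one(bundle, derive_seed(rng_seed, 53L), 1L,
                   draw_parameters = FALSE,
                   calibration_targets = calibration_targets,
                   fallback = fallback, probability_as_binary = FALSE,
                   record_implied = TRUE)
  attr(pop, "implied_marginals")
}
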