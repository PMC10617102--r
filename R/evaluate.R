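#' Recode age into the eight-level evaluation classes
#'
#' Standard stratification recode for utility evaluation: class 1 for ages
#' below 20, decade classes 2..7 for 20-29 through 70-79, class 8 for 80 and
#' above.
#'
#' @param age Numeric vector of ages in `[0, 105]`.
#' @return Integer vector of classes 1..8.
#' @export
#' @examples
#' recode_age(c(0, 19, 20, 25, 79, 80, 105)) # 1 1 2 2 7 8 8
recode_age <- function(age) {
  age <- as.numeric(age)
  if (any(is.na(age)) || any(age < 0 | age > 105)) {
    abort("ages must be within [0, 105] and non-missing")
  }
  as.integer(ifelse(age < 20, 1L, ifelse(age >= 80, 8L, floor(age / 10))))
}

#' First four moments of a numeric vector
#'
#' Mean, standard deviation (n-1 divisor), skewness `g1 = m3 / m2^1.5` and
#' excess kurtosis `g2 = m4 / m2^2 - 3`, with `m_k` the population central
#' moments. A normal sample has skewness and excess kurtosis near zero; a
#' uniform sample has excess kurtosis -1.2 (the shape of percentile-coded
#' variables).
#'
#' @param x Numeric vector, at least two non-missing values.
#' @return One-row tibble `(n, mean, sd, skewness, excess_kurtosis)`;
#'   skewness/kurtosis are `NA` for a constant vector.
#' @export
#' @examples
#' four_moments(1:5) # mean 3, sd 1.5811, skewness 0, excess kurtosis -1.3
four_moments <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 2) abort("four_moments needs at least two non-missing values")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  if (m2 <= 0) {
    return(tibble(n = n, mean = mu, sd = 0,
                  skewness = NA_real_, excess_kurtosis = NA_real_))
  }
  tibble(n = n, mean = mu, sd = sqrt(sum(d^2) / (n - 1)),
         skewness = m3 / m2^1.5, excess_kurtosis = m4 / m2^2 - 3)
}

infer_kind <- function(x) {
  if (is.numeric(x)) "continuous" else "categorical"
}

#' Univariate comparison of two populations
#'
#' Side-by-side frequency tables (in percent) for categorical variables and
#' four-moment summaries for continuous variables, the univariate half of a
#' synthetic-data utility report. Percentages are computed over non-missing
#' values and sum to 100 per variable and population.
#'
#' @param a,b Data frames sharing the compared columns (conventionally the
#'   original and the synthetic population).
#' @param variables Columns to compare; defaults to all shared columns.
#' @return A `chainsynth_univariate`: list with `frequencies`
#'   (`variable, level, pct_a, pct_b`) and `moments`
#'   (`variable, population, n, mean, sd, skewness, excess_kurtosis`).
#' @export
compare_univariate <- function(a, b, variables = NULL) {
  variables <- variables %||% intersect(names(a), names(b))
  for (v in variables) {
    if (v %!in% names(a) || v %!in% names(b)) {
      abort(paste0("variable '", v, "' absent from one of the populations"))
    }
    if (infer_kind(a[[v]]) != infer_kind(b[[v]])) {
      abort(paste0("variable '", v, "' has mismatched types across populations"))
    }
  }
  freq_tab <- function(x, lv) {
    x <- x[!is.na(x)]
    100 * as.numeric(table(factor(as.character(x), levels = lv))) / length(x)
  }
  freqs <- list(); moms <- list()
  for (v in variables) {
    if (infer_kind(a[[v]]) == "categorical") {
      lv <- sort(unique(c(as.character(a[[v]]), as.character(b[[v]]))))
      lv <- lv[!is.na(lv)]
      freqs[[v]] <- tibble(variable = v, level = lv,
                           pct_a = freq_tab(a[[v]], lv),
                           pct_b = freq_tab(b[[v]], lv))
    } else {
      moms[[v]] <- dplyr::bind_rows(
        dplyr::mutate(four_moments(a[[v]]), variable = v, population = "a"),
        dplyr::mutate(four_moments(b[[v]]), variable = v, population = "b")) |>
        dplyr::select("variable", "population", "n", "mean", "sd",
                      "skewness", "excess_kurtosis")
    }
  }
  structure(list(frequencies = dplyr::bind_rows(freqs),
                 moments = dplyr::bind_rows(moms)),
            class = "chainsynth_univariate")
}

#' @export
print.chainsynth_univariate <- function(x, ...) {
  cat("<chainsynth_univariate>\n")
  if (nrow(x$frequencies)) {
    cat("Frequencies (%):\n")
    print(dplyr::mutate(x$frequencies,
                        dplyr::across(c("pct_a", "pct_b"), ~ round(.x, 1))), n = 40)
  }
  if (nrow(x$moments)) {
    cat("Moments:\n")
    print(dplyr::mutate(x$moments,
                        dplyr::across(c("mean", "sd", "skewness", "excess_kurtosis"),
                                      ~ round(.x, 2))), n = 20)
  }
  invisible(x)
}

wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Stratified comparison of one outcome over a demographic grid
#'
#' Joint-distribution contrast in the style of stratified utility panels:
#' per cell of the stratification grid (typically age class x gender x
#' smoking x education), the outcome's prevalence with a Wilson 95% CI
#' (binary outcomes) or mean with a t-based CI (continuous outcomes), for
#' both populations. Rows with a missing outcome are excluded and counted;
#' cells below `min_n` are flagged, not hidden.
#'
#' @param a,b Data frames (original and synthetic).
#' @param outcome Outcome column. Binary outcomes may be character/factor with
#'   two levels (prevalence of the second) or 0/1 numeric.
#' @param strata_vars Stratification columns, complete in both populations.
#' @param min_n Minimum cell size before flagging (default 30).
#' @param conf Confidence level.
#' @return Long tibble: `population`, the strata columns, `n`,
#'   `n_missing_outcome`, `estimate`, `lower`, `upper`, `small_cell`.
#' @export
stratified_compare <- function(a, b, outcome, strata_vars,
                               min_n = 30L, conf = 0.95) {
  if (length(strata_vars) == 0) abort("empty stratification grid")
  one_pop <- function(data, label) {
    missing_cols <- setdiff(c(outcome, strata_vars), names(data))
    if (length(missing_cols)) {
      abort(paste0("column(s) absent from population ", label, ": ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (anyNA(data[strata_vars])) {
      abort(paste0("missing values in strata columns of population ", label))
    }
    y <- data[[outcome]]
    binary <- !is.numeric(y)
    if (binary) {
      lv <- sort(unique(as.character(y[!is.na(y)])))
      if (length(lv) > 2) abort(paste0("outcome '", outcome, "' is not binary or continuous"))
      yn <- as.numeric(as.character(y) == lv[length(lv)])
    } else yn <- as.numeric(y)
    data |>
      dplyr::mutate(.y = yn) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(strata_vars))) |>
      dplyr::group_modify(function(g, key) {
        obs <- g$.y[!is.na(g$.y)]
        n <- length(obs)
        if (n == 0) {
          return(tibble(n = 0L, n_missing_outcome = nrow(g),
                        estimate = NA_real_, lower = NA_real_, upper = NA_real_))
        }
        if (binary) {
          ci <- wilson_ci(sum(obs), n, conf)
          tibble(n = n, n_missing_outcome = nrow(g) - n,
                 estimate = mean(obs), lower = ci[["lower"]], upper = ci[["upper"]])
        } else {
          se <- if (n > 1) sd(obs) / sqrt(n) else 0
          tq <- if (n > 1) qt(1 - (1 - conf) / 2, df = n - 1) else 0
          tibble(n = n, n_missing_outcome = nrow(g) - n,
                 estimate = mean(obs), lower = mean(obs) - tq * se,
                 upper = mean(obs) + tq * se)
        }
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(population = label, small_cell = .data$n < min_n)
  }
  out <- dplyr::bind_rows(one_pop(a, "a"), one_pop(b, "b")) |>
    dplyr::relocate("population")
  attr(out, "outcome") <- outcome
  out
}

#' Exact-match disclosure rate of a synthetic population
#'
#' Fraction of synthetic rows whose full key-variable tuple occurs in the
#' original confidential data, reported with the baseline rate expected if
#' each synthetic row instead drew its key values independently from the
#' original's marginals. Matching on the seed variables alone is 1 by
#' construction (seed strata are copied verbatim); the statistic is
#' informative for keys extending beyond the seeds.
#'
#' @param original,synthetic Data frames.
#' @param key_vars Non-empty set of key columns present in both.
#' @return One-row tibble: `rate`, `matched`, `n_synthetic`,
#'   `baseline_rate`.
#' @export
disclosure_match_rate <- function(original, synthetic, key_vars) {
  if (length(key_vars) == 0) abort("key_vars must be non-empty")
  missing_cols <- setdiff(key_vars, intersect(names(original), names(synthetic)))
  if (length(missing_cols)) {
    abort(paste0("key column(s) absent: ", paste(missing_cols, collapse = ", ")))
  }
  okeys <- original[key_vars] |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.character))
  skeys <- synthetic[key_vars] |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.character))
  odist <- dplyr::distinct(okeys)
  matched <- nrow(dplyr::semi_join(skeys, odist, by = key_vars))
  # baseline: P(tuple drawn from the product of original marginals hits the
  # original's observed key set)
  marg <- lapply(setNames(key_vars, key_vars), function(v) {
    tab <- table(okeys[[v]])
    as.numeric(tab[match(odist[[v]], names(tab))]) / nrow(okeys)
  })
  baseline <- sum(Reduce(`*`, marg))
  tibble(rate = matched / nrow(skeys), matched = matched,
         n_synthetic = nrow(skeys), baseline_rate = baseline)
}

#' Full utility-evaluation report
#'
#' Bundles the univariate comparison, stratified contrasts and the
#' disclosure match rate into one report object, mirroring the evaluation
#' protocol for synthetic starting populations.
#'
#' @param original,synthetic Data frames.
#' @param variables Columns for the univariate section.
#' @param stratified_outcomes Outcomes for [stratified_compare()] (optional).
#' @param strata_vars Stratification grid columns for those outcomes.
#' @param key_vars Key set for [disclosure_match_rate()] (optional).
#' @return A `chainsynth_eval_report`: list with `univariate`, `stratified`
#'   (named list of long tibbles), `disclosure`, `metadata`.
#' @export
evaluate_populations <- function(original, synthetic,
                                 variables = NULL,
                                 stratified_outcomes = character(),
                                 strata_vars = character(),
                                 key_vars = NULL) {
  univ <- compare_univariate(original, synthetic, variables)
  strat <- lapply(setNames(stratified_outcomes, stratified_outcomes), function(v) {
    stratified_compare(original, synthetic, v, strata_vars)
  })
  disc <- if (!is.null(key_vars)) disclosure_match_rate(original, synthetic, key_vars)
  structure(list(univariate = univ, stratified = strat, disclosure = disc,
                 metadata = list(n_original = nrow(original),
                                 n_synthetic = nrow(synthetic),
                                 created = "chainsynth evaluation report")),
            class = "chainsynth_eval_report")
}

#' @export
print.chainsynth_eval_report <- function(x, ...) {
  cat("<chainsynth_eval_report> original n =", x$metadata$n_original,
      ", synthetic n =", x$metadata$n_synthetic, "\n")
  print(x$univariate)
  if (length(x$stratified)) {
    cat("Stratified outcomes:", paste(names(x$stratified), collapse = ", "), "\n")
  }
  if (!is.null(x$disclosure)) {
    cat(sprintf("Disclosure match rate: %.4f (baseline %.4f)\n",
                x$disclosure$rate, x$disclosure$baseline_rate))
  }
  invisible(x)
}

#' Plot a univariate comparison
#'
#' Dodged bar chart of category percentages in both populations, one facet
#' per variable.
#'
#' @param object A `chainsynth_univariate` from [compare_univariate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chainsynth_univariate <- function(object, ...) {
  df <- tidyr::pivot_longer(object$frequencies, c("pct_a", "pct_b"),
                            names_to = "population", values_to = "pct") |>
    dplyr::mutate(population = dplyr::recode(.data$population,
                                             pct_a = "original", pct_b = "synthetic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$pct,
                                   fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = NULL, y = "frequency (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stratified comparison panel
#'
#' Estimates with confidence intervals over one x-axis stratification
#' variable (conventionally the eight-level age class), faceted by the
#' remaining strata, colour-coded by population.
#'
#' @param comparison Output of [stratified_compare()].
#' @param x Stratum column mapped to the x axis (default `"age_class"`).
#' @return A ggplot object.
#' @export
plot_stratified <- function(comparison, x = "age_class") {
  facets <- setdiff(names(comparison),
                    c("population", x, "n", "n_missing_outcome",
                      "estimate", "lower", "upper", "small_cell"))
  p <- ggplot2::ggplot(comparison,
                       ggplot2::aes(x = factor(.data[[x]]), y = .data$estimate,
                                    colour = .data$population)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.4),
                             size = 0.3) +
    ggplot2::labs(x = x, y = attr(comparison, "outcome") %||% "estimate") +
    ggplot2::theme_minimal()
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets, labeller = ggplot2::label_both)
  }
  p
}
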