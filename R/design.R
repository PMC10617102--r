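#' Natural cubic spline basis with reusable knots
#'
#' Thin wrapper around [splines::ns()] that always returns the knots it used,
#' so a basis constructed at fit time can be re-evaluated bit-compatibly on
#' new data at synthesis time. With `knots = NULL`, interior knots sit at
#' equally spaced quantiles of `x` and boundary knots at its range, following
#' the usual convention for spline functions of age.
#'
#' @param x Numeric vector, finite.
#' @param df Degrees of freedom (number of basis columns), at least 2.
#' @param knots Interior knots to reuse; `NULL` to place them from `x`.
#' @param boundary Boundary knots to reuse; `NULL` to take `range(x)`.
#' @return Numeric matrix with `df` columns (or `length(knots) + 1` when knots
#'   are supplied) and attributes `"knots"` and `"boundary"`.
#' @export
#' @examples
#' b <- build_spline_basis(runif(100, 0, 105), df = 4)
#' b2 <- build_spline_basis(c(10, 50, 90), df = 4,
#'   knots = attr(b, "knots"), boundary = attr(b, "boundary"))
build_spline_basis <- function(x, df = 4L, knots = NULL, boundary = NULL) {
  if (!is.numeric(x) || any(!is.finite(x))) abort("spline basis needs finite numeric x")
  if (is.null(knots)) {
    if (df < 2) abort("spline df must be at least 2")
    basis <- splines::ns(x, df = df)
  } else {
    basis <- splines::ns(x, knots = knots,
                         Boundary.knots = boundary %||% range(x))
  }
  out <- unclass(basis)[, , drop = FALSE]
  attributes(out) <- list(dim = dim(out),
                          knots = as.numeric(attr(basis, "knots")),
                          boundary = as.numeric(attr(basis, "Boundary.knots")))
  out
}

# ---- design specification --------------------------------------------------

# A design spec is the frozen recipe for one model's covariate matrix: an
# ordered term list whose parameters (spline knots, reference levels, centring
# means) are fixed at fit time and serialized into the bundle, so fit-time and
# synthesis-time matrices agree exactly.

new_design <- function(terms) {
  cols <- unlist(lapply(terms, `[[`, "columns"), use.names = FALSE)
  structure(list(terms = terms, columns = c("(Intercept)", cols)),
            class = "chainsynth_design")
}

# Build the design spec for a model spec on fitting data. `plan` supplies
# variable types; missing-indicator continuous predictors are centred at the
# fit-time mean of observed values (fill 0 = "at the mean"), categorical ones
# filled at the modal observed level.
build_design <- function(ms, data, plan) {
  terms <- list()
  for (p in ms$predictors) {
    vs <- plan_variable(plan, p)
    if (is.null(vs)) abort(paste0("predictor '", p, "' not declared in plan"))
    mi <- p %in% ms$missing_indicator_predictors
    x <- data[[p]]
    if (vs$vtype %in% c("continuous", "probability")) {
      if (identical(p, plan$age_var) && !is.null(ms$age_spline_df)) {
        if (mi) abort("age spline with missing indicator is not supported")
        b <- build_spline_basis(x[!is.na(x)], df = ms$age_spline_df)
        terms[[length(terms) + 1L]] <- list(
          type = "spline", var = p,
          knots = attr(b, "knots"), boundary = attr(b, "boundary"),
          columns = paste0(p, "_ns", seq_len(ncol(b))))
      } else {
        center <- if (mi) mean(x, na.rm = TRUE) else 0
        terms[[length(terms) + 1L]] <- list(
          type = "linear", var = p, center = center, missing_indicator = mi,
          columns = c(p, if (mi) paste0(p, "_missing")))
      }
    } else {
      lv <- vs$levels
      obs <- factor(x[!is.na(x)], levels = lv)
      ref <- if (length(obs)) names(sort(table(obs), decreasing = TRUE))[1] else lv[1]
      terms[[length(terms) + 1L]] <- list(
        type = "onehot", var = p, levels = lv, ref = ref, missing_indicator = mi,
        columns = c(paste0(p, "=", setdiff(lv, ref)),
                    if (mi) paste0(p, "_missing")))
    }
  }
  new_design(terms)
}

#' Encode data rows into a numeric design matrix
#'
#' Applies a frozen design specification to a data frame: intercept, linear
#' and spline terms for numeric predictors, reference-omitted one-hot columns
#' for categorical predictors, and (filled value, 0/1 flag) pairs for
#' missing-indicator terms. The operation is row-local: permuting input rows
#' permutes output rows identically.
#'
#' @param design A design specification from a fitted model
#'   (`model$design`).
#' @param data Data frame containing every referenced variable.
#' @return Numeric matrix, one row per input row, no `NA`/`NaN`.
#' @export
encode <- function(design, data) {
  stopifnot(inherits(design, "chainsynth_design"))
  n <- nrow(data)
  mats <- list(`(Intercept)` = matrix(1, nrow = n, ncol = 1))
  for (tm in design$terms) {
    if (tm$var %!in% names(data)) abort(paste0("variable '", tm$var, "' absent from data"))
    x <- data[[tm$var]]
    if (tm$type == "spline") {
      if (anyNA(x)) abort(paste0("missing values in spline variable '", tm$var, "'"))
      m <- build_spline_basis(as.numeric(x), knots = tm$knots, boundary = tm$boundary)
      attributes(m) <- list(dim = dim(m))
    } else if (tm$type == "linear") {
      miss <- is.na(x)
      if (any(miss) && !isTRUE(tm$missing_indicator)) {
        abort(paste0("missing values in '", tm$var, "' without missing-indicator encoding"))
      }
      val <- as.numeric(x) - tm$center
      val[miss] <- 0
      m <- cbind(val, if (isTRUE(tm$missing_indicator)) as.numeric(miss))
    } else { # onehot
      miss <- is.na(x)
      if (any(miss) && !isTRUE(tm$missing_indicator)) {
        abort(paste0("missing values in '", tm$var, "' without missing-indicator encoding"))
      }
      xc <- as.character(x)
      unseen <- setdiff(unique(xc[!miss]), tm$levels)
      if (length(unseen)) {
        abort(paste0("variable '", tm$var, "': level(s) not seen at fit time: ",
                     paste(unseen, collapse = ", ")))
      }
      xc[miss] <- tm$ref  # reference fill under the missing-indicator method
      keep <- setdiff(tm$levels, tm$ref)
      m <- matrix(0, nrow = n, ncol = length(keep))
      for (j in seq_along(keep)) m[, j] <- as.numeric(xc == keep[j])
      if (isTRUE(tm$missing_indicator)) m <- cbind(m, as.numeric(miss))
    }
    mats[[length(mats) + 1L]] <- m
  }
  out <- do.call(cbind, mats)
  colnames(out) <- design$columns
  out
}

#' Partition rows into model strata
#'
#' Splits a data frame into one subset per observed combination of the
#' stratification variables (e.g. gender, or gender by smoking status). The
#' subsets are disjoint, cover every row, and are keyed deterministically.
#'
#' @param data Data frame.
#' @param stratify_by Character vector of stratification columns; empty for a
#'   single all-rows stratum.
#' @return Named list of integer row-index vectors; attribute `"keys"` holds a
#'   tibble of the stratum values, one row per stratum, in list order.
#' @export
split_strata <- function(data, stratify_by) {
  stopifnot(is.data.frame(data))
  if (length(stratify_by) == 0) {
    keys <- tibble(.rows = 0)[0, 0]
    out <- list(`(all)` = seq_len(nrow(data)))
    attr(out, "keys") <- tibble::tibble_row()[0, ]
    return(out)
  }
  missing_cols <- setdiff(stratify_by, names(data))
  if (length(missing_cols)) {
    abort(paste0("stratification columns absent: ", paste(missing_cols, collapse = ", ")))
  }
  sub <- data[stratify_by]
  if (anyNA(sub)) {
    bad <- stratify_by[vapply(sub, anyNA, logical(1))]
    abort(paste0("missing values in stratification column(s): ",
                 paste(bad, collapse = ", ")))
  }
  sub <- dplyr::mutate(sub, dplyr::across(dplyr::everything(), as.character))
  keys <- dplyr::distinct(sub) |> dplyr::arrange(dplyr::across(dplyr::everything()))
  idx <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(sub))
    for (v in stratify_by) sel <- sel & (sub[[v]] == keys[[v]][i])
    which(sel)
  })
  names(idx) <- vapply(seq_len(nrow(keys)),
                       function(i) stratum_key(as.list(keys[i, ])), character(1))
  attr(idx, "keys") <- keys
  idx
}
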