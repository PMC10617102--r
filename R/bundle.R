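# Bundle serialization. All floating-point numbers are written as 17
# significant-digit decimal strings, which round-trip IEEE doubles exactly, so
# read(write(bundle)) is bit-identical. The file is plain JSON (optionally
# gzipped via a .gz path).

BUNDLE_FORMAT <- "chainsynth-bundle"
BUNDLE_VERSION <- 1L

#' Write or read a disclosure-safe model bundle
#'
#' The bundle file is the only artifact that crosses from the secure zone to
#' the open zone. It contains the synthesis plan, the seed-strata counts, and
#' per-model coefficient vectors, covariance matrices, residual standard
#' deviations and design recipes - never row-level data. Floating-point
#' values are stored as full-precision decimal strings so the round-trip is
#' lossless.
#'
#' `read_bundle` re-validates structural invariants (format marker, symmetric
#' covariance matrices, coefficient/covariance dimension agreement) and fails
#' with a pointed message on hand-edited or truncated files.
#'
#' @param bundle A `chainsynth_bundle` from [fit_sequence()].
#' @param path File path; a `.gz` suffix gzips the JSON.
#' @return `write_bundle` returns `path` invisibly; `read_bundle` a
#'   `chainsynth_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "chainsynth_bundle"))
  obj <- list(
    format = BUNDLE_FORMAT,
    version = BUNDLE_VERSION,
    plan = plan_to_list(bundle$plan),
    strata = strata_to_list(bundle$strata),
    models = lapply(names(bundle$models), function(nm) {
      list(outcome = nm,
           fits = lapply(unname(bundle$models[[nm]]), fitted_to_list))
    }),
    provenance = bundle$provenance
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE, null = "null",
                              digits = NA), con)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) abort(paste0("bundle file not found: ", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  close(con)
  if (!nzchar(trimws(txt))) abort(paste0("bundle parse error: empty file ", path))
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) abort(paste0("bundle parse error in ", path,
                                                   ": ", conditionMessage(e))))
  if (!identical(unlist(obj$format), BUNDLE_FORMAT)) {
    abort(paste0("bundle parse error: missing '", BUNDLE_FORMAT, "' format marker"))
  }
  models <- list()
  for (m in obj$models) {
    nm <- unlist(m$outcome)
    fits <- lapply(m$fits, fitted_from_list)
    names(fits) <- vapply(fits, function(f) stratum_key(f$stratum), character(1))
    models[[nm]] <- fits
  }
  structure(
    list(plan = plan_from_list(obj$plan),
         strata = strata_from_list(obj$strata),
         models = models,
         provenance = lapply(obj$provenance, unlist)),
    class = "chainsynth_bundle")
}

# ---- component converters --------------------------------------------------

strata_to_list <- function(strata) {
  seed_vars <- attr(strata, "seed_vars")
  list(
    seed_vars = seed_vars,
    numeric_vars = seed_vars[vapply(strata[seed_vars], is.numeric, logical(1))],
    min_cell = attr(strata, "min_cell"),
    policy = attr(strata, "policy"),
    total = attr(strata, "total"),
    columns = lapply(setNames(seed_vars, seed_vars),
                     function(v) as.character(strata[[v]])),
    count = as.integer(strata$count),
    waived = strata$waived
  )
}

strata_from_list <- function(x) {
  seed_vars <- unlist(x$seed_vars)
  numeric_vars <- unlist(x$numeric_vars) %||% character()
  cols <- lapply(setNames(seed_vars, seed_vars), function(v) {
    vals <- unlist(x$columns[[v]])
    if (v %in% numeric_vars) as.numeric(vals) else vals
  })
  out <- as_tibble(cols)
  out$count <- as.integer(unlist(x$count))
  out$waived <- as.logical(unlist(x$waived))
  if (sum(out$count) != unlist(x$total)) {
    abort("bundle invariant violated: strata counts do not sum to recorded total")
  }
  attr(out, "total") <- as.integer(unlist(x$total))
  attr(out, "seed_vars") <- seed_vars
  attr(out, "min_cell") <- as.integer(unlist(x$min_cell))
  attr(out, "policy") <- unlist(x$policy)
  class(out) <- c("chainsynth_strata", class(out))
  out
}

design_to_list <- function(design) {
  list(columns = design$columns,
       terms = lapply(design$terms, function(tm) {
         for (f in c("knots", "boundary", "center")) {
           if (!is.null(tm[[f]])) tm[[f]] <- num_to_chr(tm[[f]])
         }
         tm
       }))
}

design_from_list <- function(x) {
  terms <- lapply(x$terms, function(tm) {
    tm <- lapply(tm, unlist)
    for (f in c("knots", "boundary", "center")) {
      if (!is.null(tm[[f]])) tm[[f]] <- chr_to_num(tm[[f]])
    }
    if (!is.null(tm$missing_indicator)) tm$missing_indicator <- as.logical(tm$missing_indicator)
    tm
  })
  structure(list(terms = terms, columns = unlist(x$columns)),
            class = "chainsynth_design")
}

fitted_to_list <- function(f) {
  out <- list(
    outcome = f$outcome, family = f$family, vtype = f$vtype,
    stratum = f$stratum, n_fit = f$n_fit, degenerate = f$degenerate,
    transform = f$transform, levels = f$levels, ref = f$ref,
    quasi_separated = f$quasi_separated
  )
  if (f$degenerate) {
    out$constant <- as.character(f$constant)
    out$constant_numeric <- is.numeric(f$constant)
    return(out)
  }
  out$design <- design_to_list(f$design)
  if (is.matrix(f$coef)) {
    out$coef <- num_to_chr(as.vector(t(f$coef)))
    out$coef_rows <- rownames(f$coef)
    out$coef_cols <- colnames(f$coef)
  } else {
    out$coef <- num_to_chr(unname(f$coef))
    out$coef_cols <- names(f$coef)
  }
  out$vcov <- num_to_chr(as.vector(f$vcov))
  out$vcov_dim <- nrow(f$vcov)
  if (!is.null(f$residual_sd)) out$residual_sd <- num_to_chr(f$residual_sd)
  out
}

fitted_from_list <- function(x) {
  g <- function(f) unlist(x[[f]])
  stratum <- lapply(x$stratum, unlist)
  if (isTRUE(g("degenerate"))) {
    const <- g("constant")
    if (isTRUE(g("constant_numeric"))) const <- as.numeric(const)
    return(new_fitted(g("outcome"), g("family"), g("vtype"), stratum,
                      n_fit = as.integer(g("n_fit")), levels = g("levels"),
                      degenerate = TRUE, constant = const,
                      transform = g("transform") %||% "identity"))
  }
  coef_cols <- g("coef_cols")
  coef_rows <- g("coef_rows")
  cf <- chr_to_num(g("coef"))
  cf <- if (!is.null(coef_rows)) {
    matrix(cf, nrow = length(coef_rows), byrow = TRUE,
           dimnames = list(coef_rows, coef_cols))
  } else setNames(cf, coef_cols)
  d <- as.integer(g("vcov_dim"))
  V <- matrix(chr_to_num(g("vcov")), nrow = d, ncol = d)
  n_par <- if (is.matrix(cf)) length(cf) else length(cf)
  if (d != n_par) {
    abort(paste0("bundle invariant violated: covariance dimension ", d,
                 " does not match ", n_par, " coefficients for outcome '",
                 g("outcome"), "'"))
  }
  if (max(abs(V - t(V))) > 1e-12 * max(1, max(abs(V)))) {
    abort(paste0("bundle invariant violated: covariance matrix not symmetric ",
                 "for outcome '", g("outcome"), "'"))
  }
  pn <- if (is.matrix(cf)) {
    as.vector(t(outer(coef_rows, coef_cols, paste, sep = ":")))
  } else coef_cols
  dimnames(V) <- list(pn, pn)
  rsd <- x$residual_sd
  new_fitted(g("outcome"), g("family"), g("vtype"), stratum,
             design = design_from_list(x$design),
             coef = cf, vcov = V,
             residual_sd = if (!is.null(rsd)) chr_to_num(unlist(rsd)),
             n_fit = as.integer(g("n_fit")),
             levels = g("levels"), ref = g("ref"),
             transform = g("transform") %||% "identity",
             quasi_separated = isTRUE(g("quasi_separated")))
}

#' Audit a serialized bundle for row-level disclosure
#'
#' Structural check of the disclosure property: a released bundle must not
#' contain any numeric array whose length equals the confidential fitting
#' population size (which would indicate a leaked row-level column). Scans
#' every array in the JSON document and reports the offenders.
#'
#' @param path Path to a bundle file.
#' @param n_confidential Row count of the confidential fitting data.
#' @return A list with `max_array_length`, `n_arrays`, and `offending` (count
#'   of arrays of exactly the confidential length).
#' @export
audit_bundle_disclosure <- function(path, n_confidential) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  close(con)
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  lens <- integer()
  walk <- function(x) {
    if (is.list(x)) {
      if (length(x) && all(!vapply(x, is.list, logical(1))) && is.null(names(x))) {
        lens[[length(lens) + 1L]] <<- length(x)
      }
      for (el in x) walk(el)
    }
  }
  walk(obj)
  list(max_array_length = if (length(lens)) max(lens) else 0L,
       n_arrays = length(lens),
       offending = sum(lens == n_confidential))
}
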