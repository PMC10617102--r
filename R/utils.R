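#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr uncount pivot_longer pivot_wider complete nesting
#' @importFrom purrr map map_dbl map_chr map_int map_lgl map2 imap keep compact list_rbind
#' @importFrom stats plogis qlogis rnorm runif rbinom quantile sd var coef vcov
#'   lm.fit glm.fit binomial gaussian model.matrix qt qnorm rchisq setNames
#'   complete.cases aggregate
#' @importFrom utils head modifyList
NULL

# Derive a child RNG seed from a base seed and a small set of integer keys.
# Keeps results stable when unrelated parts of a pipeline change: each
# (stage, replicate, position) combination owns its own stream. Result is a
# valid 32-bit R seed.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    h <- (h * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Evaluate fn under a temporary RNG state; restores the caller's state.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

# Stable single-string key for a stratum (named list or one-row data frame).
stratum_key <- function(values) {
  if (is.data.frame(values)) values <- as.list(values)
  if (length(values) == 0) return("(all)")
  paste(paste0(names(values), "=", vapply(values, as.character, character(1))),
        collapse = "|")
}

# Full-precision decimal text for doubles; round-trips exactly through
# as.numeric (17 significant digits).
num_to_chr <- function(x) {
  out <- sprintf("%.17g", as.double(x))
  out[is.na(x)] <- "NA"
  out
}

chr_to_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(x %in% c("NA", "NaN"))
  if (any(bad)) {
    abort(paste0("malformed numeric field: ", x[which(bad)[1]]))
  }
  out
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

`%!in%` <- function(x, table) !(x %in% table)

# cheap deterministic content hash (FNV-1a over serialized bytes)
content_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 3L)
  h <- 2166136261
  for (b in as.integer(bytes[seq(1, length(bytes), by = max(1L, length(bytes) %/% 512L))])) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
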