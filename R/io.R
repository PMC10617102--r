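#' Read or write a person-level population table
#'
#' Format is chosen by extension: `.csv` (RFC 4180, header row, UTF-8, empty
#' string for missing) via readr, `.parquet` via arrow when installed.
#'
#' @param data Data frame (for `write_population`).
#' @param path File path ending in `.csv` or `.parquet`.
#' @return `read_population` returns a tibble; `write_population` the path,
#'   invisibly.
#' @export
read_population <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("parquet support needs the 'arrow' package")
    }
    return(as_tibble(arrow::read_parquet(path)))
  }
  readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_population
#' @export
write_population <- function(data, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("parquet support needs the 'arrow' package")
    }
    arrow::write_parquet(data, path)
  } else {
    readr::write_csv(data, path, na = "", progress = FALSE)
  }
  invisible(path)
}
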