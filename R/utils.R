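#' Round half away from zero
#'
#' Fixed-precision rounding where exact halves round up (away from zero),
#' matching how percentages are conventionally printed in comparative-genomics
#' reports. Base \code{round()} rounds half to even, which would print
#' 66.665 as 66.66.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to \code{digits} places.
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Write a report table as TSV
#'
#' All report writers in the package emit plain tab-separated text with a
#' header row and no quoting, so outputs diff cleanly between runs.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTsvReport <- function(df, path) {
  stopifnot(is.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Collapse a list column into a comma-joined character vector for TSV output.
joinIds <- function(x) vapply(x, paste, character(1), collapse = ",")

# Deterministic child seed derivation: one user seed fans out to per-stage
# streams without coupling their consumption order. Kept below 2^31 - 1.
childSeed <- function(seed, stage) {
  (as.integer(seed) * 1103L + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
}
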