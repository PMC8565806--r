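#' Round half away from zero
#'
#' Decimal rounding that resolves ties upward (so 0.125 -> 0.13 at two
#' digits), matching how percentages are conventionally printed in
#' pharmacovigilance reports. Base `round()` uses round-half-even, which
#' disagrees on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# shared intra-cell delimiter for multi-valued fields
MULTI_DELIM <- ";"

split_multi <- function(x, delim = MULTI_DELIM) {
  out <- strsplit(x, delim, fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[!is.na(v) & nzchar(v)]
  })
}

join_multi <- function(x, delim = MULTI_DELIM) {
  vapply(x, paste, character(1), collapse = delim)
}

`%||%` <- rlang::`%||%`
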