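#' Round half away from zero
#'
#' Fixed-point rounding with ties going away from zero (half-up for positive
#' numbers), as used in printed clinical tables. Base R's [round()] rounds
#' half to even, which makes printed percentages irreproducible.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(2.65, 1)  # 2.7, where round() gives 2.6
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # eps guard against representation error just below a .5 boundary
  trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / scale
}

#' Format a percentage with one decimal, half-up
#' @param x Percentage value (already on the 0-100 scale).
#' @return Character vector like "2.6".
#' @keywords internal
fmt_pct1 <- function(x) {
  formatC(round_half_up(x, 1), format = "f", digits = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ephcohort <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

# recycle-safe elementwise check that allows NA through
chk_range <- function(x, lo = -Inf, hi = Inf, name = deparse(substitute(x))) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    stop_ephcohort(sprintf(
      "%s outside [%s, %s] at rows: %s", name, lo, hi,
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  invisible(x)
}
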