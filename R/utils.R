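# internal helpers shared across the package

# run `code` under a temporary seed when one is supplied, otherwise use the
# current RNG stream
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Round half-up for score display
#'
#' Scores are reported to two decimals with exact halves rounded up
#' (so 1.125 displays as 1.13), matching how published score tables are
#' printed. All internal computation keeps full precision; this is a
#' presentation helper only.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return `round_half_up()` returns a numeric vector; `format_score()` a
#'   character vector with exactly `digits` decimals.
#' @examples
#' round_half_up(asin(sqrt(0.75)))   # 1.05
#' format_score(pi / 4)              # "0.79"
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @rdname round_half_up
#' @export
format_score <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (!is.null(len) && length(x) != len) {
    abort(sprintf("`%s` must have length %d.", name, len))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}
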