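# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the current stream untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from one master seed; keeps every
# stochastic sub-step independently reproducible. Values stay < 2^31.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_numeric_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", name))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", name))
  invisible(x)
}

assert_same_length <- function(x, y, xname = "x", yname = "y") {
  if (length(x) != length(y)) {
    abort(sprintf("`%s` (length %d) and `%s` (length %d) must have the same length.",
                  xname, length(x), yname, length(y)))
  }
}

assert_nonnegative <- function(x, name) {
  if (any(x < 0)) {
    abort(sprintf("`%s` must be nonnegative; found %d negative value(s).",
                  name, sum(x < 0)))
  }
  invisible(x)
}

#' Bin a p-value into significance stars
#'
#' Uses the conventional bins: `ns` (p >= 0.05), `*` (p < .05), `**` (p < .01),
#' `***` (p < .001), `****` (p < .0001).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of the same length.
#' @export
#' @examples
#' significance_stars(c(0.2, 0.03, 0.004, 2e-4, 5e-6))
significance_stars <- function(p) {
  assert_numeric_vector(p, "p")
  cut(p,
      breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) %>% as.character()
}
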