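# Statistical primitives: normality testing, normality-gated two-sample
# comparison, Mann-Whitney U, Spearman correlation, OLS trend fits.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the framework's
#' preconditions made explicit: 3 <= n <= 5000 and nonzero variance.
#'
#' @param x Numeric vector.
#' @return A one-row tibble with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  assert_numeric_vector(x, "x")
  n <- length(x)
  if (n < 3 || n > 5000) {
    abort(sprintf("Shapiro-Wilk requires 3 <= n <= 5000; got n = %d.", n))
  }
  if (var(x) == 0) abort("Shapiro-Wilk is undefined for a constant sample.")
  sw <- shapiro.test(x)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' The p-value is exact (full enumeration of rank assignments) when
#' `n_a * n_b <= 400` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b Numeric vectors (nonempty).
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (location of `a`
#'   relative to `b`).
#' @return A one-row tibble with `statistic` (U for sample `a`), `p_value`,
#'   and `exact` (logical).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")  # U = 0, p = 0.05
mann_whitney_u <- function(a, b, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  assert_numeric_vector(a, "a")
  assert_numeric_vector(b, "b")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(wilcox.test(
    a, b,
    alternative = switch(alternative, two_sided = "two.sided", alternative),
    exact = use_exact, correct = TRUE
  ))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         exact = use_exact)
}

#' Two-sample comparison with a normality gate
#'
#' Both samples are first checked for normality with Shapiro-Wilk. If both
#' pass at `alpha_normality`, Welch's unequal-variance t-test is used;
#' otherwise the (two-sided) Mann-Whitney U test. The path taken is recorded
#' so every downstream dominance call is auditable.
#'
#' @param a,b Numeric vectors with at least 3 values each.
#' @param alpha Significance level for the comparison (default 0.05).
#' @param alpha_normality Gate level for the normality tests (default 0.05).
#' @return A one-row tibble: `method` (`"welch_t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, `n_a`, `n_b`, `normality_p_a`, `normality_p_b`,
#'   `alpha`, `significant`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05, alpha_normality = 0.05) {
  assert_numeric_vector(a, "a")
  assert_numeric_vector(b, "b")
  if (length(a) < 3 || length(b) < 3) {
    abort("compare_distributions() needs at least 3 values per sample.")
  }
  # constant samples carry no normality information; route them to the
  # nonparametric branch rather than erroring
  p_a <- if (var(a) == 0) 0 else shapiro_wilk(a)$p_value
  p_b <- if (var(b) == 0) 0 else shapiro_wilk(b)$p_value
  if (p_a >= alpha_normality && p_b >= alpha_normality) {
    tt <- t.test(a, b, var.equal = FALSE)
    method <- "welch_t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    mw <- mann_whitney_u(a, b, "two_sided")
    method <- "mann_whitney"; stat <- mw$statistic; p <- mw$p_value
  }
  tibble(method = method, statistic = stat, p_value = p,
         n_a = length(a), n_b = length(b),
         normality_p_a = p_a, normality_p_b = p_b,
         alpha = alpha, significant = p < alpha)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with the p-value from the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return A one-row tibble with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  assert_same_length(x, y, "x", "y")
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  n <- length(x)
  if (n < 4) abort(sprintf("Spearman correlation needs n >= 4; got n = %d.", n))
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) abort("Zero rank variance; correlation undefined.")
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Ordinary least-squares trend fit
#'
#' Fits `y ~ x` by least squares and classifies the direction of the donor
#' contribution trend: because smaller donor-to-outcome distances mean a
#' larger donor contribution, a significantly *negative* slope of distance on
#' time is reported as `increasing_contribution`, a significantly positive
#' slope as `decreasing_contribution`, and anything non-significant as
#' `flat`.
#'
#' @param x,y Numeric vectors, n >= 3; `x` must have positive variance.
#' @param alpha Significance level for the slope test (default 0.05).
#' @return A one-row tibble: `slope`, `intercept`, `p_value` (two-sided test
#'   of slope = 0), `r_squared`, `n_points`, `direction`.
#' @export
ols_fit <- function(x, y, alpha = 0.05) {
  assert_same_length(x, y, "x", "y")
  assert_numeric_vector(x, "x"); assert_numeric_vector(y, "y")
  if (length(x) < 3) abort("ols_fit() needs at least 3 points.")
  if (var(x) == 0) abort("`x` has zero variance; slope is undefined.")
  fit <- lm(y ~ x)
  # a perfect fit is a legitimate input here (planted lines); the summary
  # warning about it is noise
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) 1
       else sm$coefficients[2, 4]
  direction <- if (p < alpha && slope < 0) "increasing_contribution"
               else if (p < alpha && slope > 0) "decreasing_contribution"
               else "flat"
  tibble(slope = slope, intercept = unname(coef(fit)[1]),
         p_value = p, r_squared = sm$r.squared,
         n_points = length(x), direction = direction)
}
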