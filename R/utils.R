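# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All stochastic exported functions route
# through this so that a seed argument fully determines their output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, name = "p") {
  if (length(p) == 0L) stop2(name, " is empty")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop2(name, " must lie in [0, 1]")
  invisible(p)
}

#' Container for a chi-squared test result
#'
#' Light-weight result object used by the enrichment and distribution tests.
#' Holds the statistic, degrees of freedom, p-value, and the observed and
#' expected counts together with standardized residuals (O - E) / sqrt(E).
#'
#' @param statistic chi-squared statistic.
#' @param df degrees of freedom.
#' @param p_value p-value.
#' @param observed named observed counts.
#' @param expected expected counts under the null.
#' @param method short description of the test.
#' @return An object of class `chi_square_result`.
#' @export
chi_square_result <- function(statistic, df, p_value, observed, expected,
                              method = "chi-squared test") {
  stopifnot(abs(sum(observed) - sum(expected)) < 1e-9 * max(1, sum(observed)))
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value),
         observed = observed, expected = expected,
         residuals = (observed - expected) / sqrt(expected),
         method = method),
    class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("X-squared = %.4g, df = %s, p-value = %.4g\n",
              x$statistic, format(x$df), x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2),
               residual = round(x$residuals, 2))
  print(tab)
  invisible(x)
}
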