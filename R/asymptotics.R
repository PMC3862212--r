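#' Centering constant for the multinomial log-mass
#'
#' `c_n = (K - 1) * log(2 * pi * n) + sum(log(theta))`, the non-random
#' sequence that centers `-2 log p(X^n | theta)` so it converges in
#' distribution to chi-squared on K - 1 degrees of freedom.
#'
#' @param n number of multinomial trials.
#' @param theta strictly positive probability vector.
#' @return the centering constant.
#' @export
centering_constant <- function(n, theta) {
  if (n < 1) stop("n must be at least 1")
  if (any(theta <= 0)) stop("all theta components must be positive")
  (length(theta) - 1) * log(2 * pi * n) + sum(log(theta))
}

#' Centered multinomial log-mass statistic
#'
#' `-2 * log p(x | theta) - c_n`; asymptotically chi-squared on K - 1 degrees
#' of freedom as n grows. This is the large-sample limit of the log predictive
#' ordinate test statistic: as the mutant sample grows, the posterior
#' concentrates and the predictive ordinate approaches the true multinomial
#' ordinate.
#'
#' @param x count vector.
#' @param theta strictly positive probability vector.
#' @return a list of class `"centered_stat"` with `value`, `df = K - 1` and
#'   the centering constant `c_n`.
#' @export
centered_logmass <- function(x, theta) {
  n <- sum(x)
  c_n <- centering_constant(n, theta)
  v <- -2 * ldmultinom(x, theta) - c_n
  structure(list(value = v, df = length(theta) - 1, c_n = c_n),
            class = "centered_stat")
}

#' @export
print.centered_stat <- function(x, ...) {
  cat(sprintf("centered -2 log mass = %.4f (df = %d, c_n = %.4f)\n",
              x$value, x$df, x$c_n))
  invisible(x)
}

#' Limiting p-value of the predictive ordinate test
#'
#' `h(v) = P( f(U) <= f(V) | V = v )` with `U, V` iid chi-squared on `df`
#' degrees of freedom and `f` their density: the probability that an
#' independent copy lands where the density is no higher. For `df <= 2` the
#' density is monotone decreasing, so `h` is the upper-tail probability; for
#' `df >= 3` the density is unimodal at `df - 2` and the level set
#' `{f <= f(v)}` is the union of both tails, with the matching root on the
#' other side of the mode found by bisection. `h(V)` is exactly uniform when
#' `V` is chi-squared distributed (probability integral transform), which is
#' what makes the conditional predictive p-value asymptotically uniform.
#'
#' @param v non-negative statistic value(s).
#' @param df degrees of freedom (at least 1).
#' @return value(s) of `h(v)` in `[0, 1]`.
#' @examples
#' limiting_pvalue(2, df = 2)  # exp(-1)
#' @export
limiting_pvalue <- function(v, df) {
  if (df < 1) stop("df must be at least 1")
  if (any(v < 0)) stop("v must be non-negative")
  if (df <= 2) return(pchisq(v, df, lower.tail = FALSE))
  vapply(v, function(vi) {
    mode <- df - 2
    if (vi == mode) return(1)
    ldens <- function(u) dchisq(u, df, log = TRUE)
    lv <- ldens(vi)
    if (!is.finite(lv)) return(0)  # v = 0: the level set has measure zero
    if (vi < mode) {
      lo <- vi
      # bracket the matching root to the right of the mode
      hi <- mode + max(1, mode)
      while (ldens(hi) > lv) hi <- mode + 2 * (hi - mode)
      other <- stats::uniroot(function(u) ldens(u) - lv, c(mode, hi),
                              tol = 1e-10)$root
      hi <- other
    } else {
      hi <- vi
      if (ldens(0) >= lv) {
        lo <- 0   # density at 0 already below the level: left tail empty
      } else {
        lo <- stats::uniroot(function(u) ldens(u) - lv,
                             c(.Machine$double.xmin, mode), tol = 1e-10)$root
      }
    }
    pchisq(lo, df) + pchisq(hi, df, lower.tail = FALSE)
  }, numeric(1))
}
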