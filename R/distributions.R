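#' Multinomial log probability mass
#'
#' Thin validating wrapper around [stats::dmultinom()]: returns
#' `log[n!/prod(x!) * prod(theta^x)]`, with `-Inf` whenever some `x[t] > 0` has
#' `theta[t] = 0`.
#'
#' @param x count vector.
#' @param theta probability vector over the same categories (must sum to 1).
#' @param size the total; defaults to `sum(x)` and must equal it.
#' @return the log probability.
#' @examples
#' ldmultinom(c(2, 2), c(0.5, 0.5))  # log(6/16)
#' @export
ldmultinom <- function(x, theta, size = sum(x)) {
  if (length(x) != length(theta)) stop("x and theta lengths differ")
  if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
  if (sum(x) != size) stop("sum(x) must equal size")
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8)
    stop("theta must be a probability vector")
  stats::dmultinom(x, size = size, prob = theta, log = TRUE)
}

# vectorized multinomial log-pmf over the columns of X (K x G), common theta
ldmultinom_cols <- function(X, theta) {
  lt <- ifelse(theta > 0, log(theta), -Inf)
  contrib <- X * lt
  contrib[X == 0] <- 0
  lgamma(colSums(X) + 1) - colSums(lgamma(X + 1)) + colSums(contrib)
}

#' Dirichlet-multinomial log probability mass
#'
#' `log[n! * Gamma(sum(a)) / Gamma(n + sum(a)) * prod(Gamma(a + y) /
#' (y! * Gamma(a)))]`, computed via log-gamma throughout. A zero parameter
#' `a[t] = 0` contributes a factor 1 when `y[t] = 0` and makes the whole mass 0
#' (`-Inf`) when `y[t] > 0`: a clone absent from the bottleneck cannot be
#' sequenced.
#'
#' @param y count vector.
#' @param a non-negative parameter vector; in the growth model `a = phi * z`
#'   with `z` the latent bottleneck survivor counts, and in the predictive
#'   ordinate `a = alpha`, the moment-matched Dirichlet parameters.
#' @param size the total; defaults to `sum(y)` and must equal it.
#' @return the log probability.
#' @export
lddirmnom <- function(y, a, size = sum(y)) {
  if (length(y) != length(a)) stop("y and a lengths differ")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (sum(y) != size) stop("sum(y) must equal size")
  if (any(a < 0)) stop("a must be non-negative")
  a0 <- sum(a)
  if (a0 == 0) {
    if (size > 0) stop("all-zero parameter vector with positive total")
    return(0)
  }
  if (any(y > 0 & a == 0)) return(-Inf)
  pos <- a > 0
  lgamma(size + 1) - sum(lgamma(y + 1)) + lgamma(a0) - lgamma(size + a0) +
    sum(lgamma(a[pos] + y[pos]) - lgamma(a[pos]))
}

# Dirichlet-multinomial log-pmf over columns of X (K x G), common parameter a
lddirmnom_cols <- function(X, a) {
  a0 <- sum(a)
  term <- lgamma(a + X) - lgamma(a) - lgamma(X + 1)
  if (any(a == 0)) {
    zero <- a == 0
    term[zero, ] <- ifelse(X[zero, , drop = FALSE] > 0, -Inf, 0)
  }
  n <- colSums(X)
  lgamma(n + 1) + lgamma(a0) - lgamma(n + a0) + colSums(term)
}

#' Conditional moments of the Dirichlet-multinomial growth model
#'
#' Given latent survivor counts `z` and overdispersion `phi`, the sequenced
#' counts have mean `n * mu` and variance `n * mu * (1 - mu) * (1 + (n - 1) /
#' (phi * sum(z)))`, with `mu = z / sum(z)`. The last factor is the variance
#' inflation over the multinomial; it disappears as `phi -> Inf` or `n = 1`.
#'
#' @param n sequencing total.
#' @param z latent count vector with positive sum.
#' @param phi positive overdispersion parameter (per-survivor growth-rate
#'   variability; each survivor contributes a Gamma(`phi`, 1) share).
#' @return a list with per-category `mean` and `var`.
#' @export
dm_conditional_moments <- function(n, z, phi) {
  if (sum(z) <= 0) stop("sum(z) must be positive")
  if (phi <= 0) stop("phi must be positive")
  mu <- z / sum(z)
  list(mean = n * mu,
       var = n * mu * (1 - mu) * (1 + (n - 1) / (phi * sum(z))))
}

#' Collapse categories of a count vector, table, or dataset
#'
#' Sums counts within each collapsed category. The Dirichlet-multinomial family
#' is closed under this operation (with parameters summed the same way), so
#' analyses may be run at any coarser type resolution.
#'
#' @param x a named count vector, a [count_table()], or a [tcr_dataset()].
#' @param partition a named character vector mapping every category of `x` to
#'   its collapsed label.
#' @return the collapsed object; collapsed categories appear in first-use order.
#' @export
collapse_categories <- function(x, partition) UseMethod("collapse_categories")

collapse_map <- function(categories, partition) {
  if (is.null(names(partition))) stop("partition must be named by category")
  miss <- setdiff(categories, names(partition))
  if (length(miss))
    stop("partition does not map categories: ", paste(miss, collapse = ", "))
  grp <- as.character(partition[categories])
  factor(grp, levels = unique(grp))
}

#' @export
collapse_categories.default <- function(x, partition) {
  g <- collapse_map(names(x), partition)
  out <- rowsum(as.numeric(x), g)[, 1L]
  setNames(out, levels(g))
}

#' @export
collapse_categories.count_table <- function(x, partition) {
  g <- collapse_map(rownames(x), partition)
  out <- rowsum(unclass(x), g)
  count_table(out[levels(g), , drop = FALSE], levels(g), colnames(x),
              attr(x, "source_tag"))
}

#' @export
collapse_categories.tcr_dataset <- function(x, partition) {
  tabs <- lapply(x$tables, function(tb)
    if (is.null(tb)) NULL else collapse_categories(tb, partition))
  tcr_dataset(tabs$wt_mc, tabs$mt_mc, tabs$wt_sc, tabs$mt_sc, x$meta)
}

#' Moment-matched Dirichlet approximation to posterior draws
#'
#' Summarizes a sample of simplex vectors (MCMC draws of the category
#' frequencies) as a Dirichlet distribution by the method of moments: the mean
#' vector is matched exactly, and the precision `alpha0` is estimated per
#' category as `m * (1 - m) / v - 1` and aggregated by the mean-weighted
#' average over non-degenerate categories.
#'
#' @param thetas a G x K matrix, each row on the simplex.
#' @param cap ceiling for the precision estimate; reached (with a warning) when
#'   the draws are numerically degenerate.
#' @return a list of class `"dirichlet_approx"` with elements `alpha`, `alpha0`
#'   and `mean`.
#' @examples
#' set.seed(1)
#' fit_dirichlet_moments(rdirichlet(1e4, c(2, 3, 5)))$alpha
#' @export
fit_dirichlet_moments <- function(thetas, cap = 1e8) {
  thetas <- as.matrix(thetas)
  if (nrow(thetas) < 2L) stop("need at least two draws")
  if (any(abs(rowSums(thetas) - 1) > 1e-6)) stop("rows must lie on the simplex")
  m <- colMeans(thetas)
  v <- apply(thetas, 2L, var)
  ok <- v > 0 & m > 0 & m < 1
  if (!any(ok)) {
    warning("degenerate draws: precision capped at ", cap)
    alpha0 <- cap
  } else {
    a0_t <- m[ok] * (1 - m[ok]) / v[ok] - 1
    alpha0 <- sum(m[ok] * a0_t) / sum(m[ok])
    if (!is.finite(alpha0) || alpha0 > cap) {
      warning("degenerate draws: precision capped at ", cap)
      alpha0 <- cap
    }
    alpha0 <- max(alpha0, .Machine$double.eps)
  }
  structure(list(alpha = m * alpha0, alpha0 = alpha0, mean = m),
            class = "dirichlet_approx")
}

#' @export
print.dirichlet_approx <- function(x, ...) {
  cat(sprintf("dirichlet_approx: K = %d, precision alpha0 = %.4g\n",
              length(x$alpha), x$alpha0))
  print(x$alpha)
  invisible(x)
}
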