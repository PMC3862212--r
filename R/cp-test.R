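new_cpm_test <- function(pvalue, method, mc_size, seed, observed_ordinate = NA,
                         auxiliary = list()) {
  structure(list(pvalue = pvalue, method = method, mc_size = mc_size,
                 seed = seed, observed_ordinate = observed_ordinate,
                 auxiliary = auxiliary),
            class = "cpm_test")
}

#' @export
print.cpm_test <- function(x, ...) {
  cat(sprintf("%s\n  p-value = %.5g", x$method, x$pvalue))
  if (!is.na(x$mc_size)) cat(sprintf("  (Monte Carlo size %g)", x$mc_size))
  cat("\n")
  if (is.finite(x$observed_ordinate))
    cat(sprintf("  observed log ordinate = %.4f\n", x$observed_ordinate))
  for (nm in intersect(c("lambda", "df", "alpha0"), names(x$auxiliary)))
    cat(sprintf("  %s = %.4g\n", nm, x$auxiliary[[nm]]))
  invisible(x)
}

#' Log predictive ordinate of a count vector
#'
#' The posterior predictive distribution of the pooled WT counts, after
#' integrating the multinomial over the moment-matched Dirichlet approximation
#' of `p(theta | y)`, is Dirichlet-multinomial; this evaluates its log mass at
#' `x`.
#'
#' @param x count vector over the model's categories.
#' @param approx a [fit_dirichlet_moments()] object.
#' @return the log predictive ordinate (deterministic given `x` and `approx`).
#' @export
predictive_ordinate <- function(x, approx) {
  stopifnot(inherits(approx, "dirichlet_approx"))
  if (length(x) != length(approx$alpha))
    stop("x and the Dirichlet approximation have different category counts")
  lddirmnom(x, approx$alpha)
}

#' Sample posterior predictive replicates of the pooled WT counts
#'
#' One replicate per saved posterior draw: `X_rep[, g] ~ Multinomial(m,
#' theta_g)`, so marginally the replicates follow the posterior predictive
#' distribution given the mutant data.
#'
#' @param draws a [fit_posterior()] object.
#' @param m replicate total.
#' @param nsim number of replicates (default one per saved draw).
#' @return a K x nsim integer matrix.
#' @export
sample_predictive_replicates <- function(draws, m, nsim = draws$draws) {
  stopifnot(inherits(draws, "dm_posterior"))
  if (m < 0) stop("m must be non-negative")
  K <- ncol(draws$thetas)
  idx <- if (nsim == draws$draws) seq_len(nsim) else
    seq(1L, draws$draws, length.out = nsim)
  out <- matrix(0L, K, length(idx),
                dimnames = list(draws$categories, NULL))
  if (m == 0) return(out)
  for (j in seq_along(idx))
    out[, j] <- rmultinom(1L, m, draws$thetas[idx[j], ])
  out
}

#' Conditional predictive p-value for the mutant/wild-type comparison
#'
#' The test statistic is the posterior predictive ordinate of the pooled WT
#' count vector, where the posterior conditions only on the mutant data
#' (MT-MC counts through the Poisson bottleneck / Dirichlet-multinomial growth
#' hierarchy, MT-SC counts as multinomial). The p-value is the posterior
#' predictive probability that a hypothetical WT replicate is no more probable
#' than the observed one:
#' `p_cp = P( p(X_rep | y) <= p(x | y) | Y = y )`,
#' estimated by one multinomial replicate per saved posterior draw and a
#' moment-matched Dirichlet-multinomial evaluation of both ordinates (ties
#' count toward the event). Small values indicate WT frequencies that the
#' mutant-conditioned model finds surprising, i.e. evidence against equality
#' of the two populations.
#'
#' @param dataset a [tcr_dataset()] with WT and MT tables (and metadata for
#'   MT-MC samples).
#' @param fit an optional [fit_posterior()] object already fitted to the same
#'   dataset's mutant data; fitted here (with `draws`, `burnin`, `...`) when
#'   omitted.
#' @param draws,burnin passed to [fit_posterior()] when `fit` is omitted.
#' @param seed optional seed covering both fitting and replicate sampling.
#' @param ... further arguments to [fit_posterior()].
#' @return a `"cpm_test"` object: `pvalue`, Monte Carlo size `mc_size = G`,
#'   `observed_ordinate`, and auxiliary summaries (Dirichlet precision,
#'   acceptance rates, ESS).
#' @examples
#' d <- jregion_dataset(default_meta = TRUE)
#' cp_test(d, draws = 500, burnin = 200, seed = 1)
#' @export
cp_test <- function(dataset, fit = NULL, draws = 10000, burnin = 2000,
                    seed = NULL, ...) {
  stopifnot(inherits(dataset, "tcr_dataset"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit))
    fit <- fit_posterior(dataset, draws = draws, burnin = burnin, ...)
  stopifnot(inherits(fit, "dm_posterior"))
  if (fit$draws < 1) stop("no posterior draws")
  x <- pool_wildtype(dataset)
  m <- sum(x)
  if (length(x) != ncol(fit$thetas))
    stop("dataset and fit have different category counts")
  approx <- fit_dirichlet_moments(fit$thetas)
  # evaluate the observed ordinate through the same vectorized path as the
  # replicates so that structural ties match bit for bit
  o_obs <- lddirmnom_cols(matrix(x), approx$alpha)
  reps <- sample_predictive_replicates(fit, m)
  o_rep <- lddirmnom_cols(reps, approx$alpha)
  tol <- 1e-9 * max(1, abs(o_obs))
  pvalue <- mean(o_rep <= o_obs + tol)
  new_cpm_test(pvalue, "conditional predictive p-value", fit$draws, seed,
               observed_ordinate = o_obs,
               auxiliary = list(alpha0 = approx$alpha0, m = m,
                                accept = fit$accept, ess = fit$ess,
                                ordinates = o_rep))
}
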