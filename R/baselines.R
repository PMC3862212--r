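#' Log conditional ordinate of a K x 2 table given its margins
#'
#' Under independence, the first column `x` of a K x 2 table with row margins
#' `s = x + y` and column total `m = sum(x)` follows the multivariate
#' (generalized) hypergeometric law; this returns the log of that conditional
#' probability: `sum(lchoose(s, x)) - lchoose(sum(s), m)`.
#'
#' @param x,y non-negative count vectors of equal length (the two columns).
#' @return the log conditional probability of `x` given the margins.
#' @export
fisher_ordinate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(x < 0) || any(y < 0)) stop("negative counts")
  s <- x + y
  sum(lchoose(s, x)) - lchoose(sum(s), sum(x))
}

#' Fisher's exact test for a K x 2 table, ordinate criterion
#'
#' The p-value is the conditional probability, given both margins, that a
#' table drawn from the margin-conditioned null has ordinate no larger than
#' the observed one (ties included). Exact enumeration of the table space is
#' used when it is small; otherwise `B` tables are sampled from the
#' conditional null via [stats::r2dtable()]. Valid for plain multinomial data;
#' overdispersion in one column deflates it, which is what the conditional
#' predictive test corrects.
#'
#' @param x,y the two columns of the table (e.g. pooled WT and pooled MT
#'   counts per category), or pass a [tcr_dataset()] as `x` to pool
#'   automatically (WT = MC + SC wild type; MT = MC + SC mutant).
#' @param B Monte Carlo size (default 1e5).
#' @param exact_limit enumerate exactly when the table space has at most this
#'   many tables.
#' @param seed optional seed.
#' @return a `"cpm_test"` object.
#' @examples
#' fisher_test(c(3, 1), c(1, 3), B = 1e4, seed = 1)
#' @export
fisher_test <- function(x, y = NULL, B = 1e5, exact_limit = 1e6, seed = NULL) {
  if (inherits(x, "tcr_dataset")) {
    y <- pool_mutant(x)
    x <- pool_wildtype(x)
  }
  if (is.null(y)) stop("y is required unless x is a tcr_dataset")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(x < 0) || any(y < 0)) stop("negative counts")
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(x + y)
  m <- sum(x)
  obs <- sum(lchoose(s, x))          # normalizer omitted: common to all tables
  tol <- 1e-7 * max(1, abs(obs))
  n_tables <- .fisher_table_count(s, m)
  if (is.finite(n_tables) && n_tables <= exact_limit) {
    p <- .fisher_exact_enum(s, m, obs - lchoose(sum(s), m), tol)
    return(new_cpm_test(min(p, 1), "Fisher exact test (enumeration)", NA, seed,
                        observed_ordinate = obs - lchoose(sum(s), m),
                        auxiliary = list(tables = n_tables)))
  }
  if (B < 1e4) stop("B must be at least 1e4")
  hits <- 0
  left <- B
  while (left > 0) {
    nb <- min(left, 20000L)
    tabs <- stats::r2dtable(nb, s, c(m, sum(y)))
    ords <- vapply(tabs, function(tb) sum(lchoose(s, tb[, 1L])), numeric(1))
    hits <- hits + sum(ords <= obs + tol)
    left <- left - nb
  }
  new_cpm_test(hits / B, "Fisher exact test (Monte Carlo)", B, seed,
               observed_ordinate = obs - lchoose(sum(s), m),
               auxiliary = list(se = sqrt(hits / B * (1 - hits / B) / B)))
}

#' Simulation-approximated marginal log-likelihood
#'
#' For each sample with MT-MC counts, estimates the marginal likelihood
#' `p(y_mc | theta, phi) = E_Z[ P(y_mc | Z) ]` by forward Monte Carlo over the
#' latent bottleneck counts `Z ~ Poisson(s * f * theta)`, averaging on the
#' probability scale via log-sum-exp. Forward draws with an empty bottleneck
#' (`sum(Z) = 0`) are excluded and the average renormalized: a sequenced
#' sample implies a non-empty culture, matching the generator's redraw
#' convention. Multinomial components (MT-SC, and the WT tables when
#' `include_wt`) are added exactly.
#'
#' @param dataset a [tcr_dataset()] with metadata.
#' @param theta simplex vector for the mutant arm (and for WT unless
#'   `theta_wt` is given).
#' @param phi positive overdispersion parameter.
#' @param sims Monte Carlo size per sample (at least 100).
#' @param theta_wt optional separate simplex vector for the WT multinomial
#'   components.
#' @param include_wt include the WT multinomial components.
#' @param seed optional seed.
#' @return the estimated log-likelihood.
#' @export
approx_marginal_loglik <- function(dataset, theta, phi, sims = 1e4,
                                   theta_wt = NULL, include_wt = TRUE,
                                   seed = NULL) {
  stopifnot(inherits(dataset, "tcr_dataset"))
  if (sims < 100) stop("sims must be at least 100 for a usable estimate")
  if (abs(sum(theta) - 1) > 1e-8 || any(theta < 0)) stop("invalid theta")
  if (phi <= 0) stop("phi must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta_wt)) theta_wt <- theta
  K <- length(dataset_categories(dataset))
  inp <- mt_mc_inputs(dataset)
  ll <- 0
  for (i in seq_along(inp$sf)) {
    y <- inp$ymc[, i]
    if (sum(y) == 0) next   # an unsequenced sample carries no information
    Z <- matrix(rpois(K * sims, inp$sf[i] * theta), K, sims)
    keep <- colSums(Z) > 0
    lp <- lddirmnom_cols_z(y, Z[, keep, drop = FALSE], phi)
    li <- if (any(keep)) logsumexp(lp) - log(sum(keep)) else -Inf
    if (!is.finite(li))
      warning("all forward draws incompatible with sample ", i,
              "; marginal likelihood estimated as 0")
    ll <- ll + li
  }
  sc <- dataset$tables$mt_sc
  if (!is.null(sc))
    for (i in seq_len(ncol(sc)))
      if (sum(sc[, i]) > 0) ll <- ll + ldmultinom(sc[, i], theta)
  if (include_wt) {
    for (nm in c("wt_mc", "wt_sc")) {
      tb <- dataset$tables[[nm]]
      if (!is.null(tb))
        for (i in seq_len(ncol(tb)))
          if (sum(tb[, i]) > 0) ll <- ll + ldmultinom(tb[, i], theta_wt)
    }
  }
  ll
}

# DM log-pmf of fixed y under parameter columns phi * Z
lddirmnom_cols_z <- function(y, Z, phi) {
  n <- sum(y)
  A <- phi * Z
  a0 <- colSums(A)
  term <- lgamma(A + y) - lgamma(A)
  bad <- Z == 0
  if (any(bad)) term[bad] <- ifelse(rep(y, ncol(Z))[bad] > 0, -Inf, 0)
  out <- lgamma(n + 1) - sum(lgamma(y + 1)) + lgamma(a0) - lgamma(n + a0) +
    colSums(term)
  out[a0 == 0] <- if (n == 0) 0 else -Inf
  out
}

#' Likelihood-ratio baseline with posterior-mean plug-in
#'
#' Approximates the likelihood-ratio test of equal mutant and wild-type
#' frequency vectors. Maximum likelihood is impractical in the latent
#' hierarchy, so the MLEs are approximated by posterior means: the null fit
#' conditions on all data under a common frequency vector, the alternative
#' pairs the mutant-conditioned fit with the conjugate posterior mean of the
#' WT multinomial. Marginal likelihood components are estimated by forward
#' simulation over the latent bottleneck counts, and the statistic
#' `Lambda = 2 * (loglik_alt - loglik_null)` is referred to a chi-squared
#' distribution on K - 1 degrees of freedom (the alternative frees one extra
#' simplex vector).
#'
#' @param dataset a [tcr_dataset()] with all four tables and metadata.
#' @param null_fit,alt_fit optional pre-computed [fit_posterior()] objects
#'   (`include_wt = TRUE` for the null fit, mutant-only for the alternative).
#' @param sims forward-simulation size per likelihood component.
#' @param draws,burnin MCMC sizes used when fits are computed here.
#' @param seed optional seed.
#' @return a `"cpm_test"` object; auxiliary holds `lambda`, `df`, and both
#'   plug-in parameter settings. A negative `lambda` (Monte Carlo artifact)
#'   is reported with p-value 1 and a warning.
#' @export
lr_test <- function(dataset, null_fit = NULL, alt_fit = NULL, sims = 1e4,
                    draws = 2000, burnin = 1000, seed = NULL) {
  stopifnot(inherits(dataset, "tcr_dataset"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(dataset_categories(dataset))
  if (is.null(null_fit))
    null_fit <- fit_posterior(dataset, draws = draws, burnin = burnin,
                              include_wt = TRUE)
  if (is.null(alt_fit))
    alt_fit <- fit_posterior(dataset, draws = draws, burnin = burnin)
  theta0 <- colMeans(null_fit$thetas)
  phi0 <- mean(null_fit$phis)
  theta1 <- colMeans(alt_fit$thetas)
  phi1 <- mean(alt_fit$phis)
  x <- pool_wildtype(dataset)
  theta1_wt <- (x + 1) / (sum(x) + K)   # conjugate flat-Dirichlet posterior mean
  l0 <- approx_marginal_loglik(dataset, theta0, phi0, sims)
  l1 <- approx_marginal_loglik(dataset, theta1, phi1, sims,
                               theta_wt = theta1_wt)
  lambda <- 2 * (l1 - l0)
  df <- K - 1
  if (lambda < 0) {
    warning("negative likelihood-ratio statistic (simulation artifact); ",
            "reporting p-value 1")
    pvalue <- 1
  } else {
    pvalue <- pchisq(lambda, df = df, lower.tail = FALSE)
  }
  new_cpm_test(pvalue, "likelihood-ratio test (posterior-mean plug-in)",
               sims, seed,
               auxiliary = list(lambda = lambda, df = df, loglik_null = l0,
                                loglik_alt = l1, theta_null = theta0,
                                theta_mt = theta1, theta_wt = theta1_wt,
                                phi_null = phi0, phi_alt = phi1))
}
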