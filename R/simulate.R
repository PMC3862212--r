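#' Configuration of the synthetic-data generator
#'
#' Describes one draw of the full hierarchy: per sample, latent bottleneck
#' survivors `Z ~ Poisson(s * f * theta_mt)`, mass-culture mutant counts
#' `Y_mc ~ DirMult(n_mc, phi * Z)`, single-cell mutant counts
#' `Y_sc ~ Multinomial(n_sc, theta_mt)`, and wild-type counts
#' `X_mc ~ Multinomial(m_mc, theta_wt)`, `X_sc ~ Multinomial(m_sc, theta_wt)`.
#' Under the null, `theta_wt` and `theta_mt` are identical.
#'
#' @param theta_wt simplex vector of wild-type category frequencies.
#' @param theta_mt simplex vector for the mutant arm (defaults to
#'   `theta_wt`, the null).
#' @param phi positive growth overdispersion parameter.
#' @param s,f per-sample treated-cell counts and mutant frequencies
#'   (recycled to the number of samples).
#' @param m_mc,m_sc,n_mc,n_sc per-sample sequencing totals for the WT-MC,
#'   WT-SC, MT-MC and MT-SC tables.
#' @param categories,samples optional labels.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(theta_wt, theta_mt = theta_wt, phi, s, f,
                       m_mc, m_sc, n_mc, n_sc,
                       categories = NULL, samples = NULL) {
  K <- length(theta_wt)
  if (length(theta_mt) != K) stop("theta_wt and theta_mt lengths differ")
  if (abs(sum(theta_wt) - 1) > 1e-8 || abs(sum(theta_mt) - 1) > 1e-8 ||
      any(theta_wt < 0) || any(theta_mt < 0))
    stop("theta vectors must lie on the simplex")
  if (phi <= 0) stop("phi must be positive")
  S <- max(length(s), length(f), length(m_mc), length(m_sc),
           length(n_mc), length(n_sc))
  cfg <- list(theta_wt = theta_wt, theta_mt = theta_mt, phi = phi,
              s = rep_len(s, S), f = rep_len(f, S),
              m_mc = rep_len(m_mc, S), m_sc = rep_len(m_sc, S),
              n_mc = rep_len(n_mc, S), n_sc = rep_len(n_sc, S),
              categories = categories %||% paste0("t", seq_len(K)),
              samples = samples %||% paste0("s", seq_len(S)),
              null = isTRUE(all.equal(theta_wt, theta_mt)))
  if (any(cfg$s * cfg$f <= 0 & cfg$n_mc > 0))
    stop("s * f must be positive wherever MT-MC counts are requested")
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: K = %d, %d samples, phi = %.3g, %s mode\n",
              length(x$theta_wt), length(x$s), x$phi,
              if (x$null) "null" else "alternative"))
  cat(sprintf("  expected bottleneck survivors s*f: %s\n",
              paste(signif(x$s * x$f, 3), collapse = " ")))
  invisible(x)
}

#' Study conditions matched to the bundled J-region data
#'
#' Builds a [sim_config()] whose sample sizes equal the J-region sequencing
#' totals and whose system parameters follow the fitted posterior: `theta`
#' and `phi` default to the posterior means of a mutant-conditioned fit
#' supplied in `fit`. In alternative mode the two arms get separate estimates
#' matching the experimental setting as closely as possible: the mutant arm
#' uses the posterior mean of the mutant-conditioned fit (raw pooled MT
#' frequencies would overstate the separation, since mass-culture clustering
#' is bottleneck noise that the model attributes to the latent hierarchy, not
#' to the frequency vector), and the wild-type arm uses the conjugate
#' posterior mean of the pooled WT counts (equivalently, pseudocount-1
#' empirical frequencies).
#'
#' @param mode `"null"` (common frequency vector) or `"alt"`.
#' @param fit a [fit_posterior()] object for the J-region fixture, used for
#'   the posterior-mean `theta` (null mode) and `phi`; required unless both
#'   `theta` and `phi` are given.
#' @param theta optional explicit common/null frequency vector.
#' @param phi optional explicit overdispersion value.
#' @param s,f bottleneck metadata per sample (defaults: the documented
#'   fixture defaults).
#' @return a [sim_config()].
#' @export
jregion_sim_config <- function(mode = c("null", "alt"), fit = NULL,
                               theta = NULL, phi = NULL, s = 1e6, f = 1e-5) {
  mode <- match.arg(mode)
  d <- jregion_dataset()
  K <- length(dataset_categories(d))
  sizes <- lapply(d$tables, colSums)
  if (is.null(phi)) {
    if (is.null(fit)) stop("supply either fit or phi")
    phi <- mean(fit$phis)
  }
  if (mode == "null") {
    if (is.null(theta)) {
      if (is.null(fit)) stop("supply either fit or theta")
      theta <- colMeans(fit$thetas)
    }
    theta_wt <- theta_mt <- theta / sum(theta)
  } else {
    if (is.null(fit)) stop("alternative mode needs a fit for theta_mt")
    x <- pool_wildtype(d)
    theta_wt <- (x + 1) / sum(x + 1)
    theta_mt <- colMeans(fit$thetas)
    theta_mt <- theta_mt / sum(theta_mt)
  }
  sim_config(theta_wt, theta_mt, phi = phi, s = s, f = f,
             m_mc = sizes$wt_mc, m_sc = sizes$wt_sc,
             n_mc = sizes$mt_mc, n_sc = sizes$mt_sc,
             categories = dataset_categories(d),
             samples = colnames(d$tables$wt_mc))
}

#' Draw one synthetic dataset from the bottleneck/growth hierarchy
#'
#' Samples with zero bottleneck survivors are redrawn (an empty culture would
#' yield no sequencing run); the number of redraws is recorded in the
#' `"redraws"` attribute.
#'
#' @param config a [sim_config()].
#' @param max_redraw abort if a sample needs more redraws than this.
#' @return a [tcr_dataset()] with all four tables and metadata.
#' @examples
#' cfg <- sim_config(c(0.5, 0.3, 0.2), phi = 1, s = 1e6, f = 1e-5,
#'                   m_mc = 100, m_sc = 30, n_mc = 100, n_sc = 50)
#' simulate_dataset(cfg)
#' @export
simulate_dataset <- function(config, max_redraw = 1e4) {
  stopifnot(inherits(config, "sim_config"))
  K <- length(config$theta_wt)
  S <- length(config$s)
  mk <- function() matrix(0L, K, S, dimnames = list(config$categories,
                                                    config$samples))
  wt_mc <- mk(); wt_sc <- mk(); mt_mc <- mk(); mt_sc <- mk()
  redraws <- 0L
  for (i in seq_len(S)) {
    lam <- config$s[i] * config$f[i] * config$theta_mt
    repeat {
      z <- rpois(K, lam)
      if (sum(z) > 0) break
      redraws <- redraws + 1L
      if (redraws > max_redraw)
        stop("s * f too small: bottleneck empty after ", max_redraw,
             " redraws")
    }
    if (config$n_mc[i] > 0) {
      repeat {
        u <- rgamma(K, shape = config$phi * z)
        if (sum(u) > 0) break
      }
      mt_mc[, i] <- rmultinom(1L, config$n_mc[i], u / sum(u))
    }
    if (config$n_sc[i] > 0)
      mt_sc[, i] <- rmultinom(1L, config$n_sc[i], config$theta_mt)
    if (config$m_mc[i] > 0)
      wt_mc[, i] <- rmultinom(1L, config$m_mc[i], config$theta_wt)
    if (config$m_sc[i] > 0)
      wt_sc[, i] <- rmultinom(1L, config$m_sc[i], config$theta_wt)
  }
  out <- tcr_dataset(
    wt_mc = count_table(wt_mc, source_tag = "WT-MC"),
    mt_mc = count_table(mt_mc, source_tag = "MT-MC"),
    wt_sc = count_table(wt_sc, source_tag = "WT-SC"),
    mt_sc = count_table(mt_sc, source_tag = "MT-SC"),
    meta = sample_meta(config$samples, config$s, config$f))
  attr(out, "redraws") <- redraws
  out
}

run_replicates <- function(config, R, draws, burnin, thin, seed, progress) {
  if (!is.null(seed)) set.seed(seed)
  pvals <- numeric(R)
  for (r in seq_len(R)) {
    d <- simulate_dataset(config)
    fit <- fit_posterior(d, draws = draws, burnin = burnin, thin = thin)
    pvals[r] <- cp_test(d, fit = fit)$pvalue
    if (progress && r %% 25 == 0)
      message(sprintf("replicate %d/%d", r, R))
  }
  pvals
}

#' Null calibration experiment for the conditional predictive p-value
#'
#' Repeatedly simulates data under the null hierarchy, runs the full
#' posterior-plus-predictive pipeline on each replicate, and summarizes how
#' close the resulting p-values are to uniform.
#'
#' @param config a null-mode [sim_config()].
#' @param R number of replicates.
#' @param draws,burnin MCMC sizes per replicate (reduced defaults for
#'   desk-scale runs; `draws = 1e4` reproduces the full-scale experiment).
#' @param thin thinning per replicate chain; the default keeps the reduced
#'   chains as well mixed per saved draw as the full-scale run (a
#'   poorly-mixed chain understates the posterior spread, which inflates the
#'   moment-matched precision and skews p-values small).
#' @param seed optional seed.
#' @param progress message every 25 replicates.
#' @return a list of class `"cpm_experiment"`: the R p-values, the empirical
#'   CDF at 0.01/0.05/0.10, and the Kolmogorov-Smirnov comparison with
#'   uniform.
#' @export
type1_experiment <- function(config, R = 200, draws = 2000, burnin = 500,
                             thin = 4, seed = NULL, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$null) stop("type1_experiment needs a null-mode config")
  pvals <- run_replicates(config, R, draws, burnin, thin, seed, progress)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  structure(list(pvalues = pvals, R = R, draws = draws,
                 coverage = vapply(c(0.01, 0.05, 0.10),
                                   function(a) mean(pvals <= a), numeric(1)),
                 thresholds = c(0.01, 0.05, 0.10),
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 mode = "null"),
            class = "cpm_experiment")
}

#' Power experiment under the alternative
#'
#' As [type1_experiment()], but the generator uses separate wild-type and
#' mutant frequency vectors; reports the rejection probability at the 0.01
#' and 0.05 thresholds with binomial standard errors.
#'
#' @inheritParams type1_experiment
#' @param config an alternative-mode [sim_config()] (passing a null config
#'   simply estimates the size).
#' @param thresholds rejection thresholds.
#' @return a `"cpm_experiment"` list with `power` and `se`.
#' @export
power_experiment <- function(config, R = 200, draws = 2000, burnin = 500,
                             thin = 4, thresholds = c(0.01, 0.05), seed = NULL,
                             progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  pvals <- run_replicates(config, R, draws, burnin, thin, seed, progress)
  pow <- vapply(thresholds, function(a) mean(pvals <= a), numeric(1))
  structure(list(pvalues = pvals, R = R, draws = draws,
                 coverage = pow, thresholds = thresholds,
                 power = setNames(pow, thresholds),
                 se = setNames(sqrt(pow * (1 - pow) / R), thresholds),
                 mode = if (config$null) "null" else "alt"),
            class = "cpm_experiment")
}

#' @export
print.cpm_experiment <- function(x, ...) {
  cat(sprintf("cpm_experiment (%s mode): R = %d replicates, G = %d draws\n",
              x$mode, x$R, x$draws))
  for (j in seq_along(x$thresholds))
    cat(sprintf("  P(p <= %.2f) = %.3f\n", x$thresholds[j], x$coverage[j]))
  if (!is.null(x$ks_p))
    cat(sprintf("  KS vs uniform: D = %.3f, p = %.3g\n", x$ks_stat, x$ks_p))
  invisible(x)
}
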