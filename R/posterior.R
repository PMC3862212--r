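mt_mc_inputs <- function(dataset) {
  cats <- dataset_categories(dataset)
  tb <- dataset$tables$mt_mc
  if (is.null(tb)) {
    list(ymc = matrix(0L, length(cats), 0L), sf = numeric(), samples = character())
  } else {
    if (is.null(dataset$meta) && any(colSums(tb) > 0))
      stop("bottleneck metadata (s, f) is required for samples with MT-MC counts")
    idx <- match(colnames(tb), dataset$meta$sample)
    sf <- dataset$meta$s[idx] * dataset$meta$f[idx]
    if (any(sf <= 0 & colSums(tb) > 0))
      stop("s * f must be positive for every sample with MT-MC data")
    list(ymc = unclass(tb), sf = sf, samples = colnames(tb))
  }
}

pooled_or_zero <- function(dataset, which) {
  cats <- dataset_categories(dataset)
  tb <- dataset$tables[[which]]
  if (is.null(tb)) setNames(numeric(length(cats)), cats) else rowSums(tb)
}

#' Unnormalized log joint density of the latent state and the mutant data
#'
#' Sums, over samples, the Poisson bottleneck log-mass of the latent survivor
#' counts, the Dirichlet-multinomial log-mass of the MT-MC counts given those
#' survivors, and the multinomial log-mass of the MT-SC counts, under the flat
#' Dirichlet prior on `theta` and the flat (truncated) prior on `phi`. States
#' violating the support (`z = 0` where a sequence of that type was observed)
#' get `-Inf` rather than an error.
#'
#' @param state a list with elements `z` (K x S matrix of non-negative
#'   integers), `theta` (simplex vector), `phi` (positive scalar).
#' @param dataset a [tcr_dataset()] with MT tables and metadata.
#' @param include_wt also add the pooled WT multinomial log-mass (used for the
#'   common-frequency fit of the likelihood-ratio baseline).
#' @param phi_max truncation of the flat prior on `phi`.
#' @return the unnormalized log density.
#' @export
log_joint <- function(state, dataset, include_wt = FALSE, phi_max = 1e6) {
  theta <- state$theta
  phi <- state$phi
  if (any(theta <= 0) || abs(sum(theta) - 1) > 1e-8)
    stop("theta must be strictly positive on the simplex")
  if (phi <= 0) stop("phi must be positive")
  if (phi > phi_max) return(-Inf)
  inp <- mt_mc_inputs(dataset)
  z <- state$z
  lp <- 0
  if (length(inp$sf)) {
    z <- as.matrix(z)
    if (any(z < 0)) return(-Inf)
    for (i in seq_along(inp$sf)) {
      y <- inp$ymc[, i]
      if (any(y > 0 & z[, i] == 0)) return(-Inf)
      lp <- lp + sum(stats::dpois(z[, i], inp$sf[i] * theta, log = TRUE))
      if (sum(y) > 0) {
        if (sum(z[, i]) == 0) return(-Inf)
        lp <- lp + lddirmnom(y, phi * z[, i])
      }
    }
  }
  ysc <- pooled_or_zero(dataset, "mt_sc")
  if (sum(ysc) > 0) lp <- lp + ldmultinom(ysc, theta)
  if (include_wt) {
    x <- pool_wildtype(dataset)
    lp <- lp + ldmultinom(x, theta)
  }
  lp
}

# Geyer-style initial-sequence effective sample size
ess_one <- function(x) {
  g <- length(x)
  if (g < 10 || var(x) == 0) return(NA_real_)
  rho <- acf(x, lag.max = min(g - 1, 2000L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  g / (1 + 2 * s)
}

#' Fit the posterior of the overdispersed mutant-count model
#'
#' Metropolis-Hastings block sampler targeting `p(z, theta, phi | y)`, the
#' posterior of the latent bottleneck survivor counts `z`, the category
#' frequencies `theta`, and the growth overdispersion `phi`, conditioning on
#' the mutant count data: MT-MC counts enter through the Poisson bottleneck
#' and Dirichlet-multinomial growth hierarchy, MT-SC counts as plain
#' multinomial. Each scan updates `z` (per-coordinate +/-1 walk, reflecting at
#' the support floor), then `theta` (Dirichlet proposal centred at the current
#' value), then `phi` (log-scale Gaussian walk). Proposal scales adapt toward
#' 20-40% acceptance during burn-in only, then freeze.
#'
#' @param dataset a [tcr_dataset()]; metadata is required for samples with
#'   MT-MC counts.
#' @param draws number of saved draws G (default 1e4).
#' @param burnin number of warm-up scans discarded (default 2000).
#' @param thin keep every `thin`-th post-burn-in scan.
#' @param seed optional integer seed (R's RNG drives the whole chain).
#' @param include_wt also condition on the pooled WT counts through a
#'   multinomial term (for the null fit of [lr_test()]). The conditional
#'   predictive test itself must NOT condition on WT data.
#' @param blocks which parameter blocks to update; fixing a block at its
#'   initial value is mainly useful for sampler diagnostics.
#' @param init optional list overriding initial `theta`, `z`, `phi`.
#' @param proposal optional list with starting `c` (Dirichlet concentration,
#'   default `500 * K`) and `sigma` (log-phi step, default 0.3).
#' @param adapt adapt proposal scales during burn-in.
#' @param phi_max truncation of the flat prior on `phi`.
#' @param save_z record the posterior mean of the latent counts.
#' @return an object of class `"dm_posterior"`: saved `thetas` (G x K),
#'   `phis`, per-block acceptance rates, effective sample sizes, the frozen
#'   proposal scales, and the final latent state.
#' @examples
#' d <- jregion_dataset(default_meta = TRUE)
#' fit <- fit_posterior(d, draws = 500, burnin = 200, seed = 1)
#' coef(fit)["phi"]
#' @export
fit_posterior <- function(dataset, draws = 10000, burnin = 2000, thin = 1,
                          seed = NULL, include_wt = FALSE,
                          blocks = c("z", "theta", "phi"), init = NULL,
                          proposal = NULL, adapt = TRUE, phi_max = 1e6,
                          save_z = FALSE) {
  stopifnot(inherits(dataset, "tcr_dataset"))
  if (draws < 1) stop("draws must be positive")
  blocks <- match.arg(blocks, c("z", "theta", "phi"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  cats <- dataset_categories(dataset)
  K <- length(cats)
  inp <- mt_mc_inputs(dataset)
  ysc <- pooled_or_zero(dataset, "mt_sc")
  xwt <- if (include_wt) pool_wildtype(dataset) else numeric(K)

  # empirical frequencies with pseudocount 1, from everything conditioned on
  pool <- rowSums(inp$ymc) + ysc + if (include_wt) xwt else 0
  theta_hat <- (pool + 1) / sum(pool + 1)
  theta0 <- if (!is.null(init$theta)) init$theta else theta_hat
  phi0 <- if (!is.null(init$phi)) init$phi else 1
  z0 <- if (!is.null(init$z)) {
    z <- as.matrix(init$z)
    storage.mode(z) <- "integer"
    z
  } else {
    z <- matrix(0L, K, length(inp$sf))
    for (i in seq_along(inp$sf))
      z[, i] <- pmax((inp$ymc[, i] > 0) * 1L,
                     as.integer(round(inp$sf[i] * theta0)))
    z
  }
  prop_c <- if (!is.null(proposal$c)) proposal$c else 500 * K
  prop_s <- if (!is.null(proposal$sigma)) proposal$sigma else 0.3

  res <- .sampler_run(inp$ymc, as.numeric(ysc), as.numeric(xwt), include_wt,
                      inp$sf, as.integer(draws), as.integer(burnin),
                      as.integer(thin), as.numeric(theta0), z0,
                      phi0, prop_c, prop_s, adapt, phi_max,
                      "z" %in% blocks, "theta" %in% blocks, "phi" %in% blocks,
                      save_z)
  colnames(res$thetas) <- cats
  dimnames(res$z_mean) <- dimnames(res$z_last) <- list(cats, inp$samples)
  phi_identified <- any(colSums(inp$ymc) > 0)
  ess <- c(phi = ess_one(res$phis),
           theta = if (K > 1) min(apply(res$thetas, 2L, ess_one)) else NA_real_)
  structure(list(thetas = res$thetas, phis = res$phis,
                 accept = res$accept, proposal = res$proposal,
                 z_mean = if (save_z) res$z_mean else NULL,
                 z_last = res$z_last,
                 draws = as.integer(draws), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed,
                 include_wt = include_wt, categories = cats,
                 phi_identified = phi_identified, ess = ess,
                 phi_max = phi_max),
            class = "dm_posterior")
}

#' @export
print.dm_posterior <- function(x, ...) {
  cat(sprintf(
    "dm_posterior: %d saved draws (burn-in %d, thin %d), K = %d categories\n",
    x$draws, x$burnin, x$thin, length(x$categories)))
  cat(sprintf("  acceptance: z %.2f, theta %.2f, phi %.2f\n",
              x$accept["z"], x$accept["theta"], x$accept["phi"]))
  cat(sprintf("  posterior mean phi: %.3g (ESS %.0f)%s\n", mean(x$phis),
              x$ess["phi"],
              if (x$phi_identified) "" else "  [phi NOT identified: no MC data]"))
  invisible(x)
}

#' @export
summary.dm_posterior <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  th <- object$thetas
  tab <- cbind(mean = colMeans(th), sd = apply(th, 2L, sd),
               t(apply(th, 2L, quantile, probs = probs)))
  phi <- c(mean = mean(object$phis), sd = sd(object$phis),
           quantile(object$phis, probs = probs))
  out <- list(theta = tab, phi = phi, accept = object$accept,
              ess = object$ess, draws = object$draws,
              phi_identified = object$phi_identified)
  class(out) <- "summary.dm_posterior"
  out
}

#' @export
print.summary.dm_posterior <- function(x, ...) {
  cat("Posterior summary (conditional on mutant data)\n\ntheta:\n")
  print(round(x$theta, 4))
  cat("\nphi:\n")
  print(round(x$phi, 4))
  cat(sprintf("\nacceptance z/theta/phi: %.2f / %.2f / %.2f; min ESS %.0f\n",
              x$accept["z"], x$accept["theta"], x$accept["phi"],
              min(x$ess, na.rm = TRUE)))
  if (!x$phi_identified)
    cat("note: no MT-MC counts, phi restrained only by its prior\n")
  invisible(x)
}

#' @export
coef.dm_posterior <- function(object, ...) {
  c(setNames(colMeans(object$thetas),
             paste0("theta.", object$categories)),
    phi = mean(object$phis))
}

#' Plot posterior category frequencies against empirical frequencies
#'
#' Boxplots of the posterior draws of each category frequency, conditional on
#' the mutant data, with the pooled empirical frequencies of the supplied
#' dataset overlaid as points.
#'
#' @param x a [fit_posterior()] object.
#' @param dataset optional [tcr_dataset()] whose pooled WT and MT frequencies
#'   are overlaid.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.dm_posterior <- function(x, dataset = NULL, ...) {
  ord <- order(apply(x$thetas, 2L, stats::median))
  graphics::boxplot(x$thetas[, ord, drop = FALSE], horizontal = TRUE,
                    las = 1, outline = FALSE,
                    xlab = "category frequency", ...)
  if (!is.null(dataset)) {
    wt <- pool_wildtype(dataset); mt <- pool_mutant(dataset)
    graphics::points((wt / sum(wt))[ord], seq_along(ord), pch = 19,
                     col = "blue")
    graphics::points((mt / sum(mt))[ord], seq_along(ord), pch = 17,
                     col = "red")
    graphics::legend("bottomright", pch = c(19, 17),
                     col = c("blue", "red"),
                     legend = c("pooled WT", "pooled MT"), bty = "n")
  }
  invisible(x)
}

#' Posterior predictive wild-type replicates
#'
#' Draws one multinomial replicate of the pooled WT count vector per saved
#' `theta` draw, i.e. samples from the posterior predictive distribution of WT
#' counts given the mutant data.
#'
#' @param object a [fit_posterior()] object.
#' @param nsim number of saved draws to use (default: all).
#' @param seed optional seed.
#' @param m total count of each replicate.
#' @param ... unused.
#' @return a K x nsim integer matrix.
#' @export
simulate.dm_posterior <- function(object, nsim = object$draws, seed = NULL,
                                  m, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (missing(m)) stop("the replicate total m is required")
  sample_predictive_replicates(object, m, nsim = nsim)
}

#' Serialize posterior draws to a flat TSV plus a JSON diagnostics sidecar
#'
#' One row per saved draw: `phi` then the `theta` columns. Diagnostics
#' (acceptance rates, ESS, proposal scales, seed) go to `<path>.json`.
#'
#' @param fit a [fit_posterior()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "dm_posterior"))
  df <- data.frame(phi = fit$phis, fit$thetas, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  diag <- list(accept = as.list(fit$accept), ess = as.list(fit$ess),
               proposal = as.list(fit$proposal), draws = fit$draws,
               burnin = fit$burnin, thin = fit$thin,
               seed = fit$seed, phi_identified = fit$phi_identified)
  jsonlite::write_json(diag, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
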