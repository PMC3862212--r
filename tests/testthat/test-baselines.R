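test_that("hypergeometric ordinate: 2x2 closed form, degenerate margin, normalization", {
  # classical 2x2 hypergeometric: P(X11 = x) = C(s1,x) C(s2,m-x) / C(s1+s2,m)
  expect_equal(fisher_ordinate(c(1, 0), c(0, 1)),
               log(choose(1, 1) * choose(1, 0) / choose(2, 1)))
  expect_equal(fisher_ordinate(c(3, 1), c(1, 3)),
               log(choose(4, 3) * choose(4, 1) / choose(8, 4)))
  # x = s, y = 0: the unique table given its margins
  expect_equal(fisher_ordinate(c(2, 5), c(0, 0)), 0)
  # normalization over the margin-constrained table space
  s <- c(3, 2, 1); m <- 3
  tot <- 0
  for (x1 in 0:3) for (x2 in 0:2) {
    x3 <- m - x1 - x2
    if (x3 >= 0 && x3 <= 1) tot <- tot + exp(fisher_ordinate(c(x1, x2, x3),
                                                             s - c(x1, x2, x3)))
  }
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(fisher_ordinate(c(-1, 2), c(1, 1)), "negative")
})

test_that("Monte Carlo Fisher agrees with exact enumeration on a 2x2 grid", {
  grid <- expand.grid(a = c(1, 3, 6, 9), b = c(1, 4, 8, 12, 2))
  for (i in seq_len(nrow(grid))) {
    x <- c(grid$a[i], grid$b[i]); y <- c(grid$b[i], grid$a[i])
    exact <- fisher_test(x, y)            # tiny table space: auto-enumerated
    expect_match(exact$method, "enumeration")
    mc <- fisher_test(x, y, B = 2e4, exact_limit = 0, seed = i)
    se <- sqrt(exact$pvalue * (1 - exact$pvalue) / 2e4)
    expect_lt(abs(mc$pvalue - exact$pvalue), 3 * se + 1e-12)
    # and the enumeration agrees with stats::fisher.test (probability criterion)
    ft <- fisher.test(cbind(x, y))$p.value
    expect_equal(exact$pvalue, ft, tolerance = 1e-8)
  }
})

test_that("identical diffuse columns give a large Fisher p-value", {
  x <- c(10, 12, 9, 11, 8)
  res <- fisher_test(x, x, B = 1e4, exact_limit = 0, seed = 1)
  expect_gt(res$pvalue, 0.5)
})

test_that("marginal likelihood: exact singletons and a truncated-grid oracle", {
  # single category: every dataset has probability 1
  d1 <- mc_only_dataset(matrix(4L), s = 50, f = 0.1)
  expect_equal(approx_marginal_loglik(d1, theta = 1, phi = 2, sims = 200,
                                      include_wt = FALSE), 0)
  expect_error(approx_marginal_loglik(d1, 1, 1, sims = 50), "at least 100")
  # K = 2 tiny counts: compare against exhaustive summation over a Z grid,
  # conditioning on a non-empty bottleneck as the estimator does
  d2 <- mc_only_dataset(matrix(c(2L, 1L)), s = 20, f = 0.1)
  theta <- c(0.6, 0.4); phi <- 1.5; sf <- 2
  exact <- 0
  for (z1 in 0:40) for (z2 in 0:40) {
    if (z1 + z2 == 0) next
    pz <- dpois(z1, sf * theta[1]) * dpois(z2, sf * theta[2])
    py <- if (z1 == 0) 0 else exp(lddirmnom(c(2, 1), phi * c(z1, z2)))
    exact <- exact + pz * py
  }
  exact <- exact / (1 - exp(-sf))
  set.seed(2)
  ests <- replicate(20, approx_marginal_loglik(d2, theta, phi, sims = 2000,
                                               include_wt = FALSE))
  expect_lt(abs(mean(exp(ests)) - exact), 5 * sd(exp(ests)) / sqrt(20))
  # Monte Carlo rate: variance shrinks roughly like 1/B
  set.seed(3)
  v_small <- var(replicate(20, approx_marginal_loglik(d2, theta, phi, sims = 100,
                                                      include_wt = FALSE)))
  v_big <- var(replicate(20, approx_marginal_loglik(d2, theta, phi, sims = 1e4,
                                                    include_wt = FALSE)))
  expect_lt(v_big, v_small / 10)
})

test_that("likelihood-ratio test: null-consistent data give a large p-value", {
  set.seed(5)
  theta <- c(0.4, 0.3, 0.2, 0.1)
  cfg <- sim_config(theta, theta, phi = 1, s = 1e6, f = 1e-5,
                    m_mc = 400, m_sc = 100, n_mc = 400, n_sc = 200)
  d <- simulate_dataset(cfg)
  res <- lr_test(d, sims = 5000, draws = 1500, burnin = 500, seed = 6)
  expect_gt(res$pvalue, 0.1)
  expect_equal(res$auxiliary$df, 3)
})

test_that("likelihood-ratio statistic is invariant to category permutation", {
  set.seed(7)
  cfg <- sim_config(c(0.5, 0.3, 0.2), phi = 1, s = 1e6, f = 1e-5,
                    m_mc = 100, m_sc = 30, n_mc = 100, n_sc = 50)
  d <- simulate_dataset(cfg)
  p <- c(2, 3, 1)
  cats <- rownames(d$tables$wt_mc)
  dp <- tcr_dataset(
    wt_mc = toy_table(unclass(d$tables$wt_mc)[p, , drop = FALSE], "WT-MC", cats = cats[p]),
    mt_mc = toy_table(unclass(d$tables$mt_mc)[p, , drop = FALSE], "MT-MC", cats = cats[p]),
    wt_sc = toy_table(unclass(d$tables$wt_sc)[p, , drop = FALSE], "WT-SC", cats = cats[p]),
    mt_sc = toy_table(unclass(d$tables$mt_sc)[p, , drop = FALSE], "MT-SC", cats = cats[p]),
    meta = d$meta)
  r1 <- lr_test(d, sims = 4000, draws = 1000, burnin = 400, seed = 8)
  r2 <- lr_test(dp, sims = 4000, draws = 1000, burnin = 400, seed = 8)
  expect_equal(r1$auxiliary$lambda, r2$auxiliary$lambda, tolerance = 0.5)
})
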