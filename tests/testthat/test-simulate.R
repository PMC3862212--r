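test_that("simulated datasets satisfy the count-table contracts exactly", {
  set.seed(1)
  cfg <- sim_config(c(0.5, 0.3, 0.2), phi = 1, s = 1e6, f = 1e-5,
                    m_mc = c(80, 90), m_sc = c(20, 10),
                    n_mc = c(85, 100), n_sc = c(50, 60))
  d <- simulate_dataset(cfg)
  expect_s3_class(d, "tcr_dataset")
  expect_equal(unname(colSums(d$tables$mt_mc)), c(85, 100))
  expect_equal(unname(colSums(d$tables$wt_mc)), c(80, 90))
  expect_equal(unname(colSums(d$tables$wt_sc)), c(20, 10))
  expect_equal(unname(colSums(d$tables$mt_sc)), c(50, 60))
  expect_true(all(d$tables$mt_mc >= 0))
  # determinism under a fixed seed
  set.seed(7); d1 <- simulate_dataset(cfg)
  set.seed(7); d2 <- simulate_dataset(cfg)
  expect_identical(d1$tables, d2$tables)
})

test_that("tiny bottlenecks are redrawn and hopeless ones error out", {
  cfg <- sim_config(c(0.5, 0.5), phi = 1, s = 10, f = 0.01,
                    m_mc = 0, m_sc = 0, n_mc = 10, n_sc = 0)
  set.seed(2)
  d <- simulate_dataset(cfg)       # sf = 0.1: many redraws, still succeeds
  expect_gt(attr(d, "redraws"), 0)
  cfg2 <- sim_config(c(0.5, 0.5), phi = 1, s = 10, f = 1e-9,
                     m_mc = 0, m_sc = 0, n_mc = 10, n_sc = 0)
  set.seed(3)
  expect_error(simulate_dataset(cfg2, max_redraw = 100), "redraws")
})

test_that("mass-culture counts show the modelled variance inflation", {
  theta <- c(0.5, 0.3, 0.2)
  freq_var <- function(sf, phi, reps = 800, n = 200) {
    cfg <- sim_config(theta, theta, phi = phi, s = 1e6, f = sf / 1e6,
                      m_mc = 0, m_sc = 0, n_mc = n, n_sc = 0)
    f1 <- replicate(reps, simulate_dataset(cfg)$tables$mt_mc[1, 1] / n)
    var(f1)
  }
  mult_var <- theta[1] * (1 - theta[1]) / 200
  set.seed(4)
  # large survivor count and large phi: essentially multinomial
  expect_lt(abs(freq_var(1e4, 1e4) - mult_var), 0.3 * mult_var)
  # a tight bottleneck (about 3 expected survivors) inflates the variance
  expect_gt(freq_var(3, 1), 5 * mult_var)
})

test_that("null-mode generator feeds a calibrated test at small scale", {
  set.seed(5)
  cfg <- sim_config(c(0.45, 0.3, 0.25), phi = 1, s = 1e6, f = 1e-5,
                    m_mc = 100, m_sc = 30, n_mc = 100, n_sc = 60)
  ex <- type1_experiment(cfg, R = 60, draws = 800, burnin = 300, seed = 6)
  expect_length(ex$pvalues, 60)
  expect_true(all(ex$pvalues >= 0 & ex$pvalues <= 1))
  # gross miscalibration would reject here; fine-grained check is in the
  # acceptance suite at the study's sizes
  expect_gt(ex$ks_p, 0.001)
  one <- type1_experiment(cfg, R = 1, draws = 300, burnin = 100, seed = 7)
  expect_length(one$pvalues, 1)
})

test_that("power rises with the separation between the arms", {
  base <- c(0.4, 0.3, 0.2, 0.1)
  tilt <- function(delta) {
    # move mass delta onto the first category, total variation delta
    th <- base * (1 - delta / (1 - base[1]))
    th[1] <- base[1] + delta
    th / sum(th)
  }
  set.seed(8)
  pow <- sapply(c(0, 0.1, 0.2, 0.3), function(delta) {
    cfg <- sim_config(theta_wt = tilt(delta), theta_mt = base, phi = 1,
                      s = 1e6, f = 1e-5, m_mc = rep(80, 3), m_sc = rep(20, 3),
                      n_mc = rep(80, 3), n_sc = rep(40, 3))
    ex <- power_experiment(cfg, R = 60, draws = 600, burnin = 250,
                           seed = 90 + round(100 * delta))
    ex$power[["0.05"]]
  })
  expect_true(all(diff(pow) >= -0.08))   # nondecreasing up to binomial noise
  expect_gt(pow[4], pow[1] + 0.3)
  # thresholds are monotone within one experiment
  cfg <- sim_config(tilt(0.2), base, phi = 1, s = 1e6, f = 1e-5,
                    m_mc = rep(80, 3), m_sc = rep(20, 3),
                    n_mc = rep(80, 3), n_sc = rep(40, 3))
  ex <- power_experiment(cfg, R = 40, draws = 500, burnin = 200, seed = 9)
  expect_lte(ex$power[["0.01"]], ex$power[["0.05"]])
})

test_that("J-matched configurations take their parameters from the fit", {
  d <- suppressMessages(jregion_dataset(default_meta = TRUE))
  fit <- fit_posterior(d, draws = 400, burnin = 200, seed = 10)
  cfg0 <- jregion_sim_config("null", fit = fit)
  expect_true(cfg0$null)
  expect_equal(cfg0$theta_wt, unname(colMeans(fit$thetas)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cfg0$phi, mean(fit$phis))
  expect_equal(unname(cfg0$n_mc), c(81, 86, 92, 95, 82, 107))
  cfg1 <- jregion_sim_config("alt", fit = fit)
  expect_false(cfg1$null)
  x <- pool_wildtype(d)
  expect_equal(cfg1$theta_wt, unname((x + 1) / sum(x + 1)), ignore_attr = TRUE)
  expect_error(jregion_sim_config("null"), "fit or")
})
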