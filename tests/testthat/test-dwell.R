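test_that("dwell pooling builds step CDFs and flags sparse pairs", {
  r <- data.frame(trace_id = "t", from_state = 1, to_state = 2,
                  e_before = 0.2, e_after = 0.8,
                  dwell = c(0.3, 0.1, 0.2))
  class(r) <- c("transition_records", "data.frame")
  model <- list(K = 2, levels = c(0.2, 0.8), w = c(0.5, 0.5),
                sigma = c(0.02, 0.02), from = c(1, 2), to = c(2, 1))
  class(model) <- "tdp_cluster_model"
  dw <- collect_dwells(r, model)
  expect_equal(dw[["1->2"]]$dwell, c(0.1, 0.2, 0.3))
  expect_equal(dw[["1->2"]]$cdf, c(1, 2, 3) / 3)
  expect_false(dw[["1->2"]]$sufficient)   # 3 < 5 dwells
  expect_equal(dw[["2->1"]]$n, 0)
})

test_that("simulated exponential dwells pass a KS test against Exp(k)", {
  sc <- two_state_scheme(1, 1)
  p <- simulate_state_path(sc, 1100, initial_state = "cnr", seed = 17)
  dw <- (p$t_exit - p$t_entry)[-nrow(p)]
  expect_gt(length(dw), 1000)
  ks <- suppressWarnings(ks.test(dw, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("mono fit on an exact exponential CDF is essentially exact", {
  # quantiles at the fitting plotting positions: residuals can vanish
  t <- qexp(((1:100) - 0.5) / 100, rate = 2)
  f <- fit_dwell_cdf(t, 1)
  expect_equal(f$k1, 2, tolerance = 1e-6)
  expect_equal(f$A1, 1)
  expect_lt(f$rss, 1e-12)
})

test_that("biexponential components are recovered within 15%", {
  set.seed(23)
  n <- 5000
  t <- c(rexp(n / 2, 1), rexp(n / 2, 10))
  f <- fit_dwell_cdf(t, 2)
  expect_equal(f$k1, 10, tolerance = 0.15)
  expect_equal(f$k2, 1, tolerance = 0.15)
  expect_equal(f$A1, 0.5, tolerance = 0.1)
  expect_gte(f$k1, f$k2)      # fast component reported first
  expect_equal(f$A1 + f$A2, 1)
})

test_that("bi fit of mono data degenerates gracefully and BIC prefers mono", {
  set.seed(31)
  t <- rexp(800, 2)
  both <- fit_dwell(t)
  b <- both$bi
  if (!is.null(b))
    expect_true(b$A2 < 0.1 || abs(b$k1 - b$k2) / b$k1 < 0.25)
  expect_equal(both$chosen$n_components, both$mono$n_components)
})

test_that("the weighted-average rate follows the printed formula", {
  expect_equal(weighted_rate(1, 5, 0, NA), 5)
  expect_equal(weighted_rate(0.5, 2, 0.5, 2), 2)
  expect_equal(weighted_rate(0.5, 1, 0.5, 3), 1.5)   # 1/(0.5 + 1/6)
  # symmetric under component exchange
  expect_equal(weighted_rate(0.3, 1.2, 0.7, 4), weighted_rate(0.7, 4, 0.3, 1.2))
  expect_error(weighted_rate(0.5, 0, 0.5, 2), "rates")
  expect_error(weighted_rate(0.6, 1, 0.6, 1), "sum to 1")
})

test_that("error propagation matches independent evaluation of the formulas", {
  # all uncertainties zero
  expect_equal(rate_error(0.5, 1, 0.5, 2)$dk_av, 0)
  # single-component reduction: dM = (1/k1) (dk1/k1)
  e <- rate_error(1, 4, 0, NA, dA1 = 0, dk1 = 0.2)
  expect_equal(e$dk_av, (1 / 4) * (0.2 / 4))
  # frozen oracle value: A1 = A2 = 0.5, k1 = k2 = 1, all deltas 0.1
  #   M = N = 0.5;  dM = dN = 0.5 sqrt(0.2^2 + 0.1^2) = 0.1118034
  #   dk_av = sqrt(2) * 0.1118034 = 0.1581139 (verbatim mode, time units)
  e2 <- rate_error(0.5, 1, 0.5, 1, 0.1, 0.1, 0.1, 0.1)
  expect_equal(e2$dM, 0.1118034, tolerance = 1e-6)
  expect_equal(e2$dk_av, 0.1581139, tolerance = 1e-6)
  # propagated mode multiplies by k_av^2 = 1 here
  e3 <- rate_error(0.5, 1, 0.5, 1, 0.1, 0.1, 0.1, 0.1, mode = "propagated")
  expect_equal(e3$dk_av, e2$dk_av)
  e4 <- rate_error(0.5, 2, 0.5, 2, 0.1, 0.1, 0.1, 0.1, mode = "propagated")
  expect_equal(e4$dk_av, e4$k_av^2 * sqrt(e4$dM^2 + e4$dN^2))
  expect_error(rate_error(0, 1, dA1 = 0.1), "relative error")
})

test_that("cluster-weight scaling preserves total exit flux", {
  expect_equal(scale_by_cluster_weight(2.0, 1)$k_scaled, 2.0)
  # lifetime mode is the literal reading: lifetime x weight
  s <- scale_by_cluster_weight(0.5, 0.5, mode = "lifetime")
  expect_equal(s$lifetime_scaled, 1.0)
  expect_error(scale_by_cluster_weight(1, 1.5), "weight")
  # two competing exits with known branching: scaled rates sum to the
  # state's total exit rate (simulation with known rates); fast return
  # rates keep the chain cycling through cnr
  sc <- kinetic_scheme(5, 1.0, 0.86, 5, 0, 0)  # cnr exits: ->lnr 1.0, ->cr 0.86
  p <- simulate_state_path(sc, 4000, initial_state = "cnr", seed = 41)
  i <- which(p$state == "cnr")
  i <- i[i < nrow(p)]
  dest <- p$state[i + 1]
  dw <- (p$t_exit - p$t_entry)[i]
  k_tot_hat <- 1 / mean(dw)
  w_cr <- mean(dest == "cr")
  k_cr <- scale_by_cluster_weight(k_tot_hat, w_cr)$k_scaled
  k_lnr <- scale_by_cluster_weight(k_tot_hat, 1 - w_cr)$k_scaled
  expect_equal(k_cr + k_lnr, k_tot_hat, tolerance = 1e-12)
  expect_equal(k_cr, 0.86, tolerance = 0.1)
  expect_equal(k_lnr, 1.0, tolerance = 0.1)
})

test_that("bootstrap SDs are seeded, sized and asymptotically sane", {
  set.seed(51)
  t <- rexp(500, 1)
  b1 <- bootstrap_rates(t, n_components = 1, n_boot = 100, seed = 5)
  b2 <- bootstrap_rates(t, n_components = 1, n_boot = 100, seed = 5)
  expect_identical(b1$boots, b2$boots)
  expect_equal(nrow(b1$boots), 100)
  expect_equal(b1$sd3, 3 * b1$sd)
  # asymptotic SD of the rate MLE is k/sqrt(n)
  expect_lt(b1$sd[["k1"]], 3 * 1 / sqrt(500))
  expect_gt(b1$sd[["k1"]], (1 / 3) * 1 / sqrt(500))
  # near-degenerate data: tiny spread around a tiny rate
  b3 <- bootstrap_rates(rep(2, 50) + (1:50) * 1e-6, n_components = 1,
                        n_boot = 20, seed = 1)
  expect_lt(b3$sd[["k1"]], 1e-3)
})
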