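make_path <- function(states, mu, id = "t", exposure = 0.05) {
  structure(data.frame(frame = seq_along(states), state = states,
                       level = mu[states]),
            trace_id = id, exposure = exposure, K = length(mu), mu = mu,
            class = c("idealized_path", "data.frame"))
}

test_that("interior transitions are extracted with hand-counted dwells", {
  p <- make_path(c(rep(1, 10), rep(2, 5), rep(1, 5)), mu = c(0.2, 0.8))
  r <- extract_transitions(p)
  # first and last runs are truncated by the window: one interior record
  expect_equal(nrow(r), 1)
  expect_equal(r$from_state, 2)
  expect_equal(r$to_state, 1)
  expect_equal(r$dwell, 5 * 0.05)
  expect_equal(r$e_before, 0.8)
  expect_equal(r$e_after, 0.2)
})

test_that("constant paths and empty inputs contribute nothing", {
  p <- make_path(rep(1, 50), mu = 0.4)
  expect_equal(nrow(extract_transitions(p)), 0)
  expect_equal(nrow(extract_transitions(list())), 0)
})

test_that("blur states (all one-frame dwells) are absorbed into skips", {
  # state 3 only ever appears for single frames between 1 and 2:
  # records should show direct 1 <-> 2 transitions
  st <- c(rep(1, 10), 3, rep(2, 10), 3, rep(1, 10), rep(2, 10), rep(1, 5))
  p <- make_path(st, mu = c(0.2, 0.8, 0.5))
  r <- extract_transitions(p)
  expect_false(any(r$from_state == 3 | r$to_state == 3))
  expect_equal(nrow(r), 3)
  # the orphan frame joins the preceding run: dwell 10 + 1 frames
  expect_equal(r$dwell[1], 11 * 0.05)
})

test_that("TDP grid places mass where transitions are and keeps total mass", {
  r <- data.frame(trace_id = "t", from_state = 1, to_state = 2,
                  e_before = 0.3, e_after = 0.5, dwell = 0.2)
  class(r) <- c("transition_records", "data.frame")
  g <- build_tdp(r, n_bins = 50, bandwidth = 0.02)
  peak <- which(g$density == max(g$density), arr.ind = TRUE)
  expect_lt(abs(g$x[peak[1]] - 0.3), 0.011)   # within one bin
  expect_lt(abs(g$y[peak[2]] - 0.5), 0.011)
  expect_equal(sum(g$density), 1, tolerance = 1e-6)
  # bandwidth 0 is the raw histogram
  g0 <- build_tdp(r, n_bins = 50, bandwidth = 0)
  expect_equal(sum(g0$density > 0), 1)
  expect_warning(build_tdp(r[0, ], 50, 0.02), "no transition")
})

test_that("symmetric two-state data give a near-symmetric grid", {
  set.seed(2)
  n <- 400
  fr <- rep(c(1, 2), n / 2)
  r <- data.frame(trace_id = "t", from_state = fr, to_state = 3 - fr,
                  e_before = c(0.2, 0.8)[fr] + rnorm(n, 0, 0.01),
                  e_after = c(0.2, 0.8)[3 - fr] + rnorm(n, 0, 0.01),
                  dwell = 0.2)
  class(r) <- c("transition_records", "data.frame")
  g <- build_tdp(r, n_bins = 40, bandwidth = 0.03)
  asym <- sum(abs(g$density - t(g$density))) / sum(g$density)
  expect_lt(asym, 0.2)
})

test_that("two-level transitions cluster to K_opt = 2 at the true levels", {
  set.seed(5)
  n <- 300
  fr <- rep(c(1, 2), n / 2)
  r <- data.frame(trace_id = "t", from_state = fr, to_state = 3 - fr,
                  e_before = c(0.2, 0.8)[fr] + rnorm(n, 0, 0.015),
                  e_after = c(0.2, 0.8)[3 - fr] + rnorm(n, 0, 0.015),
                  dwell = 0.2)
  class(r) <- c("transition_records", "data.frame")
  m <- cluster_tdp(r, k_range = 1:5, n_init = 10, seed = 1)
  expect_equal(m$K, 2)
  expect_equal(m$levels, c(0.2, 0.8), tolerance = 0.02)
  expect_equal(sum(m$w), 1, tolerance = 1e-9)
})

test_that("EM recovers parameters of the constrained mixture itself", {
  set.seed(9)
  lev <- c(0.2, 0.5, 0.8)
  pr <- rotafret:::tdp_pairs(3)
  w <- c(0.3, 0.05, 0.25, 0.1, 0.05, 0.25)  # ordered pairs, sums to 1
  n <- 2000
  cl <- sample(seq_along(w), n, TRUE, prob = w)
  sd0 <- 0.02
  x1 <- lev[pr$from[cl]] + rnorm(n, 0, sd0)
  x2 <- lev[pr$to[cl]] + rnorm(n, 0, sd0)
  r <- data.frame(trace_id = "t", from_state = pr$from[cl],
                  to_state = pr$to[cl], e_before = x1, e_after = x2,
                  dwell = 0.2)
  class(r) <- c("transition_records", "data.frame")
  m <- cluster_tdp(r, k_range = 3, n_init = 10, seed = 2)
  expect_equal(m$levels, lev, tolerance = 3 * sd0 / sqrt(n / 6))
  got_w <- m$w
  se_w <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(got_w - w) < 3 * se_w + 0.01))
  expect_true(all(abs(m$sigma - sd0) < 0.005))
})

test_that("BIC selects the true K in >= 90% of seeded replicates", {
  lev <- c(0.2, 0.5, 0.8)
  pr <- rotafret:::tdp_pairs(3)
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 400
    cl <- sample(seq_along(pr$from), n, TRUE)
    x1 <- lev[pr$from[cl]] + rnorm(n, 0, 0.02)
    x2 <- lev[pr$to[cl]] + rnorm(n, 0, 0.02)
    r <- data.frame(trace_id = "t", from_state = pr$from[cl],
                    to_state = pr$to[cl], e_before = x1, e_after = x2,
                    dwell = 0.2)
    class(r) <- c("transition_records", "data.frame")
    m <- cluster_tdp(r, k_range = 1:6, n_init = 10, seed = s)
    hits <- hits + (m$K == 3)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("cluster assignment fractions are normalized and deterministic", {
  set.seed(4)
  n <- 200
  fr <- rep(c(1, 2), n / 2)
  r <- data.frame(trace_id = "t", from_state = fr, to_state = 3 - fr,
                  e_before = c(0.3, 0.7)[fr] + rnorm(n, 0, 0.01),
                  e_after = c(0.3, 0.7)[3 - fr] + rnorm(n, 0, 0.01),
                  dwell = 0.2)
  class(r) <- c("transition_records", "data.frame")
  m <- cluster_tdp(r, k_range = 2, n_init = 5, seed = 3)
  f1 <- transition_counts(m, r)
  f2 <- transition_counts(m, r)
  expect_identical(f1, f2)
  expect_equal(sum(f1), 1)
  # stationary two-state data: forward and reverse fractions agree
  expect_equal(f1[1, 2], f1[2, 1], tolerance = 0.05)
})

test_that("degenerate K inputs are handled with diagnostics", {
  r <- data.frame(trace_id = "t", from_state = rep(1:2, 10),
                  to_state = rep(2:1, 10),
                  e_before = rep(c(0.2, 0.8), 10),
                  e_after = rep(c(0.8, 0.2), 10), dwell = 0.2)
  class(r) <- c("transition_records", "data.frame")
  m <- cluster_tdp(r, k_range = c(1, 2, 10), n_init = 3, seed = 1)
  tab <- m$bic_table
  expect_match(tab$note[tab$K == 10], "skipped")  # 20 records < p(10)
  expect_error(cluster_tdp(r[1:5, ], 1:2), ">= 10")
})
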