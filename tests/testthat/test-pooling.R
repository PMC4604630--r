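test_that("Rubin pooling matches hand application of the rules", {
  p <- rubin_pool(data.frame(estimate = c(1, 3), se = c(1, 1)))
  expect_equal(p$estimate, 2, tolerance = 1e-10)
  expect_equal(p$within, 1, tolerance = 1e-10)
  expect_equal(p$between, 2, tolerance = 1e-10)
  expect_equal(p$variance, 1 + (1 + 1 / 2) * 2, tolerance = 1e-10)
  expect_identical(p$mechanism, "MAR")

  # all estimates equal: variance collapses to the within part
  q <- rubin_pool(data.frame(estimate = rep(1.7, 6), se = rep(0.3, 6)))
  expect_equal(q$estimate, 1.7, tolerance = 1e-12)
  expect_equal(q$variance, 0.09, tolerance = 1e-12)
  expect_equal(q$between, 0, tolerance = 0)

  expect_error(rubin_pool(data.frame(estimate = 1, se = 1)), "m >= 2")
  expect_error(rubin_pool(data.frame(estimate = c(1, Inf), se = c(1, 1))),
               "finite")
})

test_that("delta-weights match hand evaluation and handle delta = 0", {
  w0 <- delta_weights(c(3.2, -1, 0.4, 7), delta = 0)
  expect_equal(w0$normalized, rep(0.25, 4), tolerance = 1e-12)

  w <- delta_weights(c(1, 2), delta = 1)
  expect_equal(w$normalized, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-10)
  expect_equal(w$normalized[1], 0.7310585786, tolerance = 1e-9)

  we <- delta_weights(c(0, 0, 0), delta = 5)
  expect_equal(we$normalized, rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(delta_weights(c(1, NaN), 1), "finite")
  expect_error(delta_weights(c(1, 2), Inf), "finite")
})

test_that("weights are stable in log space and agree with naive summation", {
  # naive oracle on small instances
  set.seed(31)
  for (k in 1:20) {
    m <- sample(2:8, 1)
    sums <- rnorm(m, sd = 3)
    delta <- runif(1, -3, 3)
    naive <- exp(-delta * sums) / sum(exp(-delta * sums))
    expect_equal(delta_weights(sums, delta)$normalized, naive,
                 tolerance = 1e-10)
  }
  # extreme magnitudes that overflow the naive route
  w <- delta_weights(c(500, 0, -500), delta = 3)
  expect_equal(sum(w$normalized), 1, tolerance = 1e-12)
  expect_equal(w$normalized[3], 1, tolerance = 1e-12)
})

test_that("direction of up-weighting follows the sign of delta", {
  sums <- c(4, -2, 1, 0.5)
  expect_identical(which.max(delta_weights(sums, 0.7)$normalized),
                   which.min(sums))
  expect_identical(which.max(delta_weights(sums, -0.7)$normalized),
                   which.max(sums))
})

test_that("MNAR pooling matches hand application of the weighted rules", {
  est <- data.frame(estimate = c(1, 3), se = c(1, 1))
  w <- delta_weights(c(0, log(3)), delta = 1)  # normalized (0.75, 0.25)
  expect_equal(w$normalized, c(0.75, 0.25), tolerance = 1e-12)
  p <- mnar_pool(est, w)
  expect_equal(p$estimate, 1.5, tolerance = 1e-10)
  expect_equal(p$within, 1, tolerance = 1e-10)
  expect_equal(p$between, 0.75 * 0.25 + 0.25 * 2.25, tolerance = 1e-10)
  expect_equal(p$between, 0.75, tolerance = 1e-10)
  expect_equal(p$variance, 1 + 1.5 * 0.75, tolerance = 1e-10)

  # all weight on one imputation: variance collapses to that se^2
  wk <- delta_weights(c(0, 1e8), delta = 1)
  pk <- mnar_pool(data.frame(estimate = c(2.5, 9), se = c(0.4, 1)), wk)
  expect_equal(pk$estimate, 2.5, tolerance = 1e-12)
  expect_equal(pk$variance, 0.16, tolerance = 1e-12)

  expect_error(mnar_pool(est, delta_weights(c(1, 2, 3), 1)), "different")
})

test_that("delta = 0 reduces MNAR pooling to Rubin pooling", {
  set.seed(32)
  est <- data.frame(estimate = rnorm(7), se = runif(7, 0.5, 1))
  sums <- rnorm(7)
  mar <- rubin_pool(est)
  mnar <- mnar_pool(est, delta_weights(sums, 0))
  expect_equal(mnar$estimate, mar$estimate, tolerance = 1e-12)
  expect_equal(mnar$within, mar$within, tolerance = 1e-12)
  # weighted between-variance has no m/(m-1) correction
  expect_equal(mnar$between, (7 - 1) / 7 * mar$between, tolerance = 1e-12)
})

test_that("normalized weights are shift-invariant in the imputed values", {
  set.seed(33)
  sums <- rnorm(10)
  for (shift in c(-100, 0.5, 3e3)) {
    # adding c to every imputed value shifts every S_j by n_mis * c equally
    a <- delta_weights(sums, 0.8)$normalized
    b <- delta_weights(sums + shift, 0.8)$normalized
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("maximum weight is nondecreasing in delta for delta >= 0", {
  set.seed(34)
  for (k in 1:10) {
    sums <- rnorm(12, sd = 2)
    deltas <- seq(0, 3, by = 0.1)
    mx <- vapply(deltas, function(d) max(delta_weights(sums, d)$normalized),
                 numeric(1))
    expect_true(all(diff(mx) >= -1e-12))
    expect_true(all(diff(mx) > 0))  # sums distinct: strictly increasing
    expect_equal(mx[1], 1 / 12, tolerance = 1e-12)
  }
})

test_that("the MNAR estimate lies within the range of per-imputation estimates", {
  set.seed(35)
  for (k in 1:25) {
    m <- sample(3:15, 1)
    est <- data.frame(estimate = rnorm(m), se = runif(m, 0.1, 1))
    w <- delta_weights(rnorm(m, sd = 4), runif(1, -4, 4))
    p <- mnar_pool(est, w)
    expect_gte(p$estimate, min(est$estimate) - 1e-12)
    expect_lte(p$estimate, max(est$estimate) + 1e-12)
  }
})

test_that("pooled results serialise to JSON with all components", {
  p <- rubin_pool(data.frame(estimate = c(1, 3), se = c(1, 1)))
  obj <- jsonlite::fromJSON(pooled_json(p, estimand = "marginal_mean"))
  expect_equal(obj$estimate, 2)
  expect_equal(obj$variance, 4)
  expect_identical(obj$mechanism, "MAR")
  expect_identical(obj$estimand, "marginal_mean")
  mp <- mnar_pool(data.frame(estimate = c(1, 3), se = c(1, 1)),
                  delta_weights(c(1, 2), 0.3))
  obj2 <- jsonlite::fromJSON(pooled_json(mp))
  expect_equal(obj2$delta, 0.3)
})
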