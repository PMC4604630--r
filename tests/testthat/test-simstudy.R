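test_that("replicates are deterministic given the scenario seed", {
  sc <- scenario("continuous", n = 60, n_sims = 5, m_list = c(3, 5), seed = 7)
  a <- run_replicate(sc, 3)
  b <- run_replicate(sc, 3)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$auroc, b$auroc)
  # different replicate ids give different data
  expect_false(isTRUE(all.equal(a$estimates$estimate,
                                run_replicate(sc, 4)$estimates$estimate)))
})

test_that("delta = 0 analysis makes the weighted estimate equal the MI estimate", {
  sc <- scenario("continuous", n = 80, delta_gen = 0, delta_analysis = 0,
                 gamma = 1, n_sims = 4, m_list = c(5), seed = 11)
  for (i in 1:4) {
    r <- run_replicate(sc, i)
    est <- r$estimates
    for (e in unique(est$estimand)) {
      mi <- est$estimate[est$method == "mi_mar" & est$estimand == e]
      mnar <- est$estimate[est$method == "mnar_weighted" & est$estimand == e]
      expect_equal(mnar, mi, tolerance = 1e-12)
    }
    expect_equal(r$max_weight$max_weight, 1 / 5, tolerance = 1e-12)
  }
})

test_that("a micro-replicate reproduces a hand-composed pipeline", {
  sc <- scenario("continuous", n = 12, n_sims = 2, m_list = c(2),
                 alpha = 0.5, gamma = 1, delta_gen = 0.4, seed = 19)
  r <- run_replicate(sc, 1)

  # recompose the pipeline with the same derived seed and draw order
  set.seed(misens:::replicate_seed(19, 1))
  complete <- sim_bivnorm(12, rho = 0.5)
  inc <- apply_mnar(complete, 0.5, 1, 0.4)
  auc <- missingness_auroc(complete, inc$r)
  full_mean <- analyze(complete$y, complete$x, "marginal_mean")
  cc_mean <- complete_case(inc, "marginal_mean")
  full_slope <- analyze(complete$y, complete$x, "linear_slope")
  cc_slope <- complete_case(inc, "linear_slope")
  imps <- impute_normal(inc, 2)
  w <- delta_weights(imps, 0.4)
  est_mean <- analyze_imputations(imps, inc$x, "marginal_mean")
  mar <- rubin_pool(est_mean)
  mnar <- mnar_pool(est_mean, w)

  expect_equal(r$auroc, auc, tolerance = 1e-12)
  g <- function(meth, e) {
    d <- r$estimates
    d$estimate[d$method == meth & d$estimand == e]
  }
  expect_equal(g("full", "marginal_mean"), full_mean$estimate, tolerance = 1e-12)
  expect_equal(g("complete_case", "marginal_mean"), cc_mean$estimate,
               tolerance = 1e-12)
  expect_equal(g("full", "linear_slope"), full_slope$estimate, tolerance = 1e-12)
  expect_equal(g("complete_case", "linear_slope"), cc_slope$estimate,
               tolerance = 1e-12)
  expect_equal(g("mi_mar", "marginal_mean"), mar$estimate, tolerance = 1e-12)
  expect_equal(g("mnar_weighted", "marginal_mean"), mnar$estimate,
               tolerance = 1e-12)
})

test_that("scenario aggregation produces the expected table shape", {
  sc <- scenario("continuous", n = 60, n_sims = 6, m_list = c(3, 4), seed = 23)
  res <- run_scenario(sc)
  s <- res$summary
  expect_setequal(unique(s$method),
                  c("full", "complete_case", "mi_mar", "mnar_weighted"))
  # full and complete-case do not depend on m: one row each per estimand
  expect_identical(sum(s$method == "full" & s$estimand == "marginal_mean"), 1L)
  expect_true(all(is.na(s$m[s$method %in% c("full", "complete_case")])))
  expect_identical(sort(unique(s$m[s$method == "mi_mar"])), c(3L, 4L))
  expect_true(all(s$mc_se >= 0))
  expect_true(all(s$n_reps == 6))
  expect_identical(res$n_failed, 0L)
  expect_true(res$mean_auroc > 0.5 && res$mean_auroc < 1)
  expect_identical(nrow(res$max_weight), 2L)
})

test_that("failed replicates abort the study when they exceed 10%", {
  # alpha = 10 observes everything: every replicate is degenerate
  sc <- scenario("continuous", n = 30, alpha = 10, gamma = 0, delta_gen = 0,
                 n_sims = 5, m_list = c(3), seed = 29)
  expect_error(run_scenario(sc), "10%")
})

test_that("scenario configs round-trip through YAML and JSON", {
  cfg <- list(outcome_type = "binary", n = 50, alpha = -0.4, gamma = 1,
              delta_gen = 1, n_sims = 10, seed = 3, m_list = c(5, 10))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  sc <- read_scenario(yml)
  expect_identical(sc$outcome_type, "binary")
  expect_identical(sc$m_list, c(5L, 10L))
  expect_equal(sc$delta_analysis, 1)  # defaults to delta_gen

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  sc2 <- read_scenario(jsn)
  expect_equal(sc2[names(sc2) != "m_list"], sc[names(sc) != "m_list"],
               ignore_attr = TRUE)

  yaml::write_yaml(c(cfg, list(bogus = 1)), yml)
  expect_error(read_scenario(yml), "unknown scenario keys")
  expect_error(scenario("continuous", m_list = c(1, 5)), ">= 2")
})

test_that("no-imputation scenarios run the pre-imputation methods only", {
  sc <- scenario("continuous", n = 80, n_sims = 5, m_list = NULL, seed = 31)
  res <- run_scenario(sc)
  expect_setequal(unique(res$summary$method), c("full", "complete_case"))
  expect_null(res$max_weight)
  expect_length(res$aurocs, 5)
})

test_that("large m concentrates the weight and fattens the estimator's tails", {
  # study condition: n = 100, delta = 1; per replicate, compare the weighted
  # estimate built from the first 5 imputations with the one from all 1000
  set.seed(47)
  n_reps <- 120
  est5 <- est1k <- mw1k <- rel_dom <- numeric(n_reps)
  contained <- logical(n_reps)
  for (k in seq_len(n_reps)) {
    d <- sim_bivnorm(100)
    inc <- apply_mnar(d, 0, 1, 1)
    if (attr(inc, "degenerate") || sum(inc$r) < 4) {
      est5[k] <- NA; next
    }
    imps <- impute_normal(inc, 1000)
    est <- analyze_imputations(imps, inc$x, "marginal_mean")
    w5 <- delta_weights(imps$sums[1:5], 1)
    w1k <- delta_weights(imps, 1)
    est5[k] <- mnar_pool(est[1:5, ], w5)$estimate
    p <- mnar_pool(est, w1k)
    est1k[k] <- p$estimate
    mw1k[k] <- max(w1k$normalized)
    rel_dom[k] <- max(w1k$normalized) * 1000 / (max(w5$normalized) * 5)
    contained[k] <- p$estimate >= min(est$estimate) &&
      p$estimate <= max(est$estimate)
  }
  ok <- !is.na(est5)
  expect_gt(mean(ok), 0.9)
  # weighted estimate always inside the per-imputation MAR estimate range
  expect_true(all(contained[ok]))
  # a single imputation carries nearly all the weight at m = 1000, and its
  # dominance relative to the uniform reference 1/m grows with m
  expect_gt(mean(mw1k[ok]), 0.5)
  expect_gt(mean(mw1k[ok] > 100 / 1000), 0.95)
  expect_gt(mean(rel_dom[ok] > 1), 0.95)
  # heavier tails of the replicate distribution at m = 1000 than at m = 5
  kurt <- function(v) { z <- (v - mean(v)) / sd(v); mean(z^4) - 3 }
  expect_gt(kurt(est1k[ok]), kurt(est5[ok]))
})

test_that("results and manifest are written as tidy CSV plus JSON", {
  sc <- scenario("continuous", n = 60, n_sims = 4, m_list = c(3), seed = 37)
  res <- run_scenario(sc)
  dir <- withr::local_tempdir()
  write_scenario_results(res, dir)
  out <- read.csv(file.path(dir, "results.csv"))
  expect_identical(names(out),
                   c("method", "m", "estimand", "mean_estimate", "mc_se",
                     "n_reps"))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(man$scenario$outcome_type, "continuous")
  expect_identical(man$n_failed, 0L)
  expect_true(file.exists(file.path(dir, "replicates.csv")))
})
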