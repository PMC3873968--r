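test_that("method-of-moments fits match the closed-form parameters", {
  ln <- fit_moments("lognormal", 6.00, 2.46)
  expect_equal(unname(ln$params["sdlog"]), 0.394180792505, tolerance = 1e-9)
  expect_equal(unname(ln$params["meanlog"]), 1.71407022064, tolerance = 1e-9)

  g <- fit_moments("gamma", 0.88, 0.05)
  expect_equal(unname(g$params["shape"]), 309.76)
  expect_equal(unname(g$params["rate"]), 352.0)

  b <- fit_moments("beta", 0.135, 0.0675)
  expect_equal(unname(b$params["shape1"] / sum(b$params)), 0.135)
  # sd = 0.25 is still feasible for mean 0.135 (sd^2 < mean*(1-mean));
  # the bound is crossed at sd = 0.35
  expect_silent(fit_moments("beta", 0.135, 0.25))
  expect_error(fit_moments("beta", 0.135, 0.35), "infeasible")
  expect_error(fit_moments("gamma", 0.5, 0), "sd")
})

test_that("samplers recover their target moments (seeded, 3 SE)", {
  set.seed(101)
  n <- 2e4
  for (case in list(list("lognormal", 6.00, 2.46),
                    list("gamma", 0.88, 0.05),
                    list("beta", 0.135, 0.0675))) {
    x <- fit_moments(case[[1]], case[[2]], case[[3]])$sampler(n)
    se_mean <- case[[3]] / sqrt(n)
    expect_lt(abs(mean(x) - case[[2]]), 3 * se_mean)
    # asymptotic SE of the sample sd with empirical kurtosis
    k <- mean((x - mean(x))^4) / stats::var(x)^2
    se_sd <- stats::sd(x) * sqrt((k - 1) / (4 * n))
    expect_lt(abs(stats::sd(x) - case[[3]]), 3 * se_sd)
  }
})

test_that("sample_params is reproducible, degenerate-stable and respects bounds", {
  p <- small_params()
  specs <- degenerate_specs(p)
  d1 <- sample_params(p, specs, seed = 11)
  for (path in c("risk.odds_ratio", "risk.prevalence", "utilities.stage1",
                 "utilities.stage4"))
    expect_equal(param_get(d1, path), param_get(p, path), tolerance = 1e-6,
                 label = path)
  expect_equal(d1$stage_dist$program, p$stage_dist$program, tolerance = 1e-6)

  full <- default_psa_specs(p)
  a <- sample_params(p, full, seed = 7)
  b <- sample_params(p, full, seed = 7)
  expect_identical(a$risk$odds_ratio, b$risk$odds_ratio)
  expect_identical(a$epi$weights, b$epi$weights)
  expect_true(all(a$utilities$stage <= 1))
  expect_equal(sum(a$stage_dist$program), 1, tolerance = 1e-12)
  expect_equal(nrow(a$epi$weights), 1L) # starting age collapsed to the draw

  # law of large numbers on the odds-ratio draws
  set.seed(5)
  or_spec <- list(list(path = "risk.odds_ratio", family = "lognormal",
                       mean = 6.00, sd = 2.46))
  draws <- replicate(1e4, param_get(sample_params(p, or_spec), "risk.odds_ratio"))
  expect_lt(abs(mean(draws) - 6.00), 3 * 2.46 / sqrt(1e4))
})

test_that("one-way DSA is flat on a degenerate range and signed on model runs", {
  p <- small_params(ages = 60)
  d0 <- one_way_dsa("risk.odds_ratio", c(6, 6), grid_size = 2, params = p)
  s0 <- dsa_summary(d0)
  expect_equal(s0$max_swing, 0)
  expect_false(s0$influential)

  d_r <- one_way_dsa("econ.discount_rate", c(0.03, 0.05), grid_size = 3,
                     params = p)
  # NHB non-increasing in the discount rate for every strategy
  for (s in unique(d_r$strategy)) {
    cur <- d_r[d_r$strategy == s, ]
    expect_true(all(diff(cur$nhb[order(cur$value)]) <= 0), label = s)
  }
  d_or <- one_way_dsa("risk.odds_ratio", c(2.4, 21.5), grid_size = 3,
                      params = p)
  for (s in c("surveil2y", "surveil1y")) {
    cur <- d_or[d_or$strategy == s, ]
    expect_true(all(diff(cur$nhb[order(cur$value)]) >= 0), label = s)
  }
})

test_that("threshold finder localizes analytic crossings and labels intervals", {
  an <- function(theta) c(A = theta, B = 1 - theta)
  th <- find_switch_thresholds("theta", c(0, 1), eval_fn = an, tol = 1e-8)
  expect_equal(th$cutpoints, 0.5, tolerance = 1e-6)
  expect_equal(th$optimal, c("B", "A"))

  flat <- find_switch_thresholds("theta", c(0, 1),
                                 eval_fn = function(t) c(A = 1, B = 0))
  expect_length(flat$cutpoints, 0L)
  expect_equal(flat$optimal, "A")

  two <- function(theta) c(A = -(theta - 0.3) * (theta - 0.8), B = 0)
  th2 <- find_switch_thresholds("theta", c(0, 1), eval_fn = two, tol = 1e-8)
  expect_equal(th2$cutpoints, c(0.3, 0.8), tolerance = 1e-6)
  expect_equal(th2$optimal, c("B", "A", "B"))
})

test_that("PSA with degenerate distributions reproduces the deterministic base case", {
  p <- small_params(ages = 55, sexes = "male")
  base <- evaluate_strategies(p)
  res <- run_psa(p, specs = degenerate_specs(p), n = 2, seed = 3,
                 lambda_grid = c(20000, 46200))
  for (it in 1:2) {
    smp <- res$samples[res$samples$iteration == it, ]
    expect_equal(smp$cost[match(base$strategy, smp$strategy)], base$cost,
                 tolerance = 1e-6)
    expect_equal(smp$effect[match(base$strategy, smp$strategy)], base$qaly,
                 tolerance = 1e-6)
  }
  expect_true(all(res$ceaf$probability == 1)) # deterministic optimum
})

test_that("PSA runs are seed-reproducible and the CEAF is well formed", {
  p <- small_params(ages = c(50, 60))
  r1 <- run_psa(p, n = 5, seed = 21, lambda_grid = c(0, 30000, 46200, 90000))
  r2 <- run_psa(p, n = 5, seed = 21, lambda_grid = c(0, 30000, 46200, 90000))
  expect_identical(r1$samples, r2$samples)
  expect_true(all(r1$ceaf$probability >= 0 & r1$ceaf$probability <= 1))
  # growing n leaves earlier iterations untouched (counter-based substreams)
  r3 <- run_psa(p, n = 7, seed = 21, lambda_grid = c(46200))
  expect_identical(r3$samples[r3$samples$iteration <= 5, ],
                   r1$samples[, ])
  # frontier strategy maximizes expected NMB at every lambda
  for (k in seq_len(nrow(r1$ceaf))) {
    l <- r1$ceaf$lambda[k]
    m <- tapply(if (l > 0) l * r1$samples$effect - r1$samples$cost
                else -r1$samples$cost,
                r1$samples$strategy, mean)
    expect_equal(r1$ceaf$strategy[k], names(m)[which.max(m)])
  }
})
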