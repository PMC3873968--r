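test_that("split_incidence satisfies both constraints and matches the bisection oracle", {
  # frozen from the bisection oracle at q=0.001, p=0.135, OR=6
  s <- split_incidence(0.001, 0.135, 6.0)
  expect_equal(unname(s["q_low"]), 5.97876647127e-4, tolerance = 1e-9)
  expect_equal(unname(s["q_high"]), 3.576568149892e-3, tolerance = 1e-9)

  for (q in c(1e-4, 1e-3, 5e-3, 0.02)) {
    for (p in c(0.05, 0.135, 0.5)) {
      for (or in c(1, 1.5, 6, 21.5)) {
        s <- split_incidence(q, p, or)
        # mixture and odds-ratio constraints, directly
        expect_lt(abs(p * s["q_high"] + (1 - p) * s["q_low"] - q), 1e-10)
        odds <- function(x) x / (1 - x)
        expect_lt(abs(odds(s["q_high"]) - or * odds(s["q_low"])), 1e-10)
        expect_true(s["q_low"] <= q + 1e-15 && s["q_high"] >= q - 1e-15)
        o <- split_incidence_bisect(q, p, or)
        expect_equal(unname(s), unname(o), tolerance = 1e-8)
      }
    }
  }

  expect_equal(unname(split_incidence(0.002, 0.3, 1)), c(0.002, 0.002))
  # p -> 1: the whole population is high risk
  s <- split_incidence(0.002, 1 - 1e-9, 6)
  expect_equal(unname(s["q_high"]), 0.002, tolerance = 1e-6)
  expect_error(split_incidence(1.2, 0.1, 6), "q_pop")
})

test_that("stage death probabilities follow the constant-hazard conversion", {
  surv <- list(five_year = c(0.90, 0.70, 0.40, 0.00), stage4_epsilon = 0.001)
  expect_equal(annual_stage_death_prob(1, surv), 1 - 0.9^0.2)
  expect_equal(annual_stage_death_prob(1, surv), 0.020851637639, tolerance = 1e-10)
  expect_equal(annual_stage_death_prob(4, surv), 0.748811356849, tolerance = 1e-10)
  surv$five_year[2] <- 1
  expect_equal(annual_stage_death_prob(2, surv), 0)
  surv$five_year[3] <- 1.4
  expect_error(annual_stage_death_prob(3, surv), "\\[0, 1\\]")
})

test_that("competing risks combine independently and attribute by hazard share", {
  expect_equal(combine_competing_risks(0, 0.02), 0.02)
  expect_equal(combine_competing_risks(0.1, 0.02), 0.118)
  expect_equal(combine_competing_risks(1, 1), 1)
  expect_equal(death_attribution(0, 0.02), 0)
  expect_equal(death_attribution(0.02, 0), 1)
  expect_equal(death_attribution(0.1, 0.1), 0.5)
})

test_that("detection weights follow schedules and interval-effect fractions", {
  p <- default_params()
  expect_equal(detection_weight("none", "high", 3, p), 0)
  for (t in 0:5)
    expect_equal(detection_weight("surveil1y", "high", t, p), 0.93)
  expect_equal(detection_weight("surveil2y", "high", 0, p), 0.93) # cycle 0 is an OGD year
  expect_equal(detection_weight("surveil2y", "high", 1, p), 0.93 * 0.60)
  expect_equal(detection_weight("surveil2y", "low", 1, p), 0)  # no follow-up group
  expect_equal(detection_weight("screen2y", "low", 2, p), 0.93)
  expect_equal(detection_weight("screen2y", "low", 3, p), 0.93 * 0.40)
  expect_equal(detection_weight("screen2y_surveil1y", "high", 3, p), 0.93)
  expect_equal(detection_weight("screen2y_surveil1y", "low", 3, p), 0.93 * 0.40)
})

test_that("stage mix interpolates between usual care and programme detection", {
  prog <- c(0.85, 0.04, 0.08, 0.03); usual <- c(0.07, 0.17, 0.33, 0.43)
  expect_equal(stage_mix_at_diagnosis(0, prog, usual), usual)
  expect_equal(stage_mix_at_diagnosis(1, prog, usual), prog)
  expect_equal(stage_mix_at_diagnosis(0.5, prog, usual), c(0.46, 0.105, 0.205, 0.23))
  expect_equal(sum(stage_mix_at_diagnosis(0.31, prog, usual)), 1)
})

test_that("OGD delivery cost inflates by the programme-cost proportion", {
  expect_equal(ogd_delivery_cost(340, 0.40), 340 / 0.6)
  expect_equal(ogd_delivery_cost(350, 0), 350)
  # cycle-0 accounting visible in traces: screening charges the follow-up
  # price at entry, surveillance arms the baseline price
  p <- small_params()
  p$epi$incidence <- zero_incidence_table()
  tr_scr <- run_cohort("screen2y", "male", 60, p)
  expect_equal(tr_scr$cost[1], 340 / 0.6, tolerance = 1e-12)
  tr_sur <- run_cohort("surveil1y", "male", 60, p)
  expect_equal(tr_sur$cost[1], 350 / 0.6, tolerance = 1e-12)
  # thereafter only the surviving high-risk group gets annual follow-up OGDs
  expect_equal(tr_sur$ogd[2], tr_sur$asym_high[1], tolerance = 1e-12)
})

test_that("occupancy is conserved and incidence is strategy-invariant", {
  p <- small_params(ages = 55)
  states <- c("asym_low", "asym_high", paste0("gc_stage", 1:4),
              "dead_gc", "dead_other")
  traces <- lapply(strategy_names(), run_cohort, sex = "male", start_age = 55,
                   params = p)
  for (tr in traces)
    expect_lt(max(abs(rowSums(tr[states]) - 1)), 1e-12)
  ref <- traces[[1]]
  for (tr in traces[-1]) {
    n <- min(nrow(tr), nrow(ref))
    expect_lt(max(abs(tr$gc_incidence[1:n] - ref$gc_incidence[1:n])), 1e-10)
  }
})

test_that("with detection switched off every arm nests the reference arm", {
  p <- small_params(ages = 58)
  p$test$sensitivity <- 0
  out <- lapply(strategy_names(), function(s)
    lifetime_outcomes(run_cohort(s, "female", 58, p)))
  out <- do.call(rbind, out)
  expect_lt(max(abs(out$qaly - out$qaly[1])), 1e-10)
  expect_lt(max(abs(out$gc_deaths - out$gc_deaths[1])), 1e-10)
  # cost differs from the reference arm exactly by the programme OGD spend
  tr <- run_cohort("surveil1y", "female", 58, p)
  disc <- (1 + p$econ$discount_rate)^-(tr$cycle)
  unit <- c(350, rep(340, nrow(tr) - 1)) / (1 - 0.40)
  program_spend <- sum(tr$ogd * unit * disc)
  expect_equal(out$cost[out$strategy == "surveil1y"] - out$cost[1],
               program_spend, tolerance = 1e-9)
})

test_that("disease-free limit reproduces discounted life expectancy", {
  p <- small_params()
  p$epi$incidence <- zero_incidence_table()
  tr <- run_cohort("none", "female", 50, p)
  le <- discounted_life_expectancy(p$epi$mortality, "female", 50, 0.03)
  expect_equal(sum(tr$qaly), le, tolerance = 1e-9)
  expect_equal(sum(tr$cost), 0)

  p$econ$discount_rate <- 0
  tr0 <- run_cohort("none", "female", 50, p)
  le0 <- discounted_life_expectancy(p$epi$mortality, "female", 50, 0)
  expect_equal(sum(tr0$qaly), le0, tolerance = 1e-9)
})

test_that("a pure stage cohort without background mortality recovers 5-year survival", {
  p <- small_params()
  p$epi$mortality <- zero_mortality_table()
  p$epi$incidence <- zero_incidence_table()
  for (s in 1:3) {
    tr <- run_cohort("none", "male", 60, p, initial = list(stage = s))
    alive5 <- 1 - (tr$dead_gc[5] + tr$dead_other[5])
    expect_equal(alive5, p$survival$five_year[s], tolerance = 1e-9)
    expect_equal(tr$dead_other[5], 0) # no competing deaths to attribute
  }
})

test_that("run_cohort matches a matrix-product oracle in the two-state reduction", {
  p <- small_params()
  p$epi$incidence <- zero_incidence_table()
  tr <- run_cohort("none", "male", 70, p)
  q <- rate_lookup(p$epi$mortality, 70:72, "male")
  v <- c(1, 0) # (alive, dead)
  for (i in 1:3) {
    M <- matrix(c(1 - q[i], q[i], 0, 1), 2, 2, byrow = TRUE)
    v <- as.vector(v %*% M)
    expect_equal(tr$asym_low[i], v[1], tolerance = 1e-12)
    expect_equal(tr$dead_other[i], v[2], tolerance = 1e-12)
  }
})

test_that("surveillance improves staging without changing overall incidence", {
  p <- small_params(ages = 60)
  tr_none <- run_cohort("none", "male", 60, p)
  tr_ann <- run_cohort("surveil1y", "male", 60, p)
  o_none <- lifetime_outcomes(tr_none); o_ann <- lifetime_outcomes(tr_ann)
  expect_gt(o_ann$qaly, o_none$qaly)
  expect_lt(o_ann$gc_deaths, o_none$gc_deaths)
  # early stage-1 occupancy is larger under annual surveillance
  expect_gt(tr_ann$gc_stage1[3], tr_none$gc_stage1[3])
})

test_that("lifetime_outcomes and aggregate_outcomes do the stated arithmetic", {
  tr <- data.frame(cycle = 0:1, cost = c(100, 50), qaly = c(1, 1 / 1.03),
                   ogd = c(1, 0), dead_gc = c(0, 0.01))
  attr(tr, "strategy") <- "none"; attr(tr, "sex") <- "male"
  attr(tr, "start_age") <- 60
  out <- lifetime_outcomes(tr)
  expect_equal(out$qaly, 1.97087378641, tolerance = 1e-10)
  expect_equal(out$cost, 150)

  res <- data.frame(strategy = "none", sex = c("male", "male"),
                    start_age = c(50, 60), cost = c(100, 200),
                    qaly = c(20, 15), ogd = 0, gc_deaths = 0)
  w <- data.frame(age = c(50, 60), sex = "male", weight = c(0.25, 0.75))
  agg <- aggregate_outcomes(res, w)
  expect_equal(agg$cost, 175)
  expect_equal(agg$qaly, 16.25)
  w_bad <- data.frame(age = c(50, 61), sex = "male", weight = c(0.25, 0.75))
  expect_error(aggregate_outcomes(res, w_bad), "not covered")
})

test_that("surveillance benefit responds monotonically to risk and discounting", {
  base <- small_params(ages = 60, sexes = "male")
  gain <- function(p) {
    q1 <- lifetime_outcomes(run_cohort("surveil1y", "male", 60, p))$qaly
    q0 <- lifetime_outcomes(run_cohort("none", "male", 60, p))$qaly
    q1 - q0
  }
  g_or <- vapply(c(2.4, 6, 21.5), function(or)
    gain(param_set(base, "risk.odds_ratio", or)), numeric(1))
  expect_true(all(diff(g_or) > 0))
  g_p <- vapply(c(0.065, 0.135, 0.27), function(pr)
    gain(param_set(base, "risk.prevalence", pr)), numeric(1))
  expect_true(all(diff(g_p) > 0))
  g_r <- vapply(c(0, 0.03, 0.05), function(r)
    gain(param_set(base, "econ.discount_rate", r)), numeric(1))
  expect_true(all(diff(g_r) < 0))
})

test_that("stage-4 epsilon choice does not drive results", {
  p <- small_params(ages = 60, sexes = "male")
  q_eps <- function(eps) {
    p$survival$stage4_epsilon <- eps
    lifetime_outcomes(run_cohort("none", "male", 60, p))$qaly
  }
  expect_equal(q_eps(0.001), q_eps(0.01), tolerance = 1e-3)
})
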