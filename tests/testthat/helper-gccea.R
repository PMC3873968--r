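# shared fixtures and independent oracles

# default parameters on a reduced starting population (fast model runs)
small_params <- function(ages = c(50, 60), sexes = c("male", "female")) {
  p <- default_params()
  w <- p$epi$weights
  w <- w[w$age %in% ages & w$sex %in% sexes, , drop = FALSE]
  p$epi$weights <- normalize_weights(w)
  p
}

# bisection oracle for the low/high risk incidence split: solves the mixture
# and odds-ratio constraints directly, independent of the closed form
split_incidence_bisect <- function(q_pop, p, or, iters = 200L) {
  f <- function(x) {
    oh <- or * x / (1 - x)
    p * oh / (1 + oh) + (1 - p) * x - q_pop
  }
  lo <- 0; hi <- q_pop
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  oh <- or * x / (1 - x)
  c(q_low = x, q_high = oh / (1 + oh))
}

# discounted life expectancy straight from a life table (cycle-start accrual,
# same termination rule as the engine)
discounted_life_expectancy <- function(mortality, sex, start_age, r,
                                       termination_fraction = 0.99,
                                       max_age = 110) {
  ages <- start_age:max_age
  q <- rate_lookup(mortality, ages, sex)
  surv <- 1; total <- 0
  for (i in seq_along(ages)) {
    total <- total + surv / (1 + r)^(i - 1)
    surv <- surv * (1 - q[i])
    if (1 - surv >= termination_fraction) break
  }
  total
}

# exact brute-force frontier oracle: enumerates all pairwise NMB crossing
# lambdas and takes the argmax-NMB strategy on each open interval
brute_force_frontier <- function(cost, effect) {
  n <- length(cost)
  cand <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    de <- effect[j] - effect[i]
    if (de != 0) {
      l <- (cost[j] - cost[i]) / de
      if (is.finite(l) && l > 0) cand <- c(cand, l)
    }
  }
  cand <- sort(unique(cand))
  probes <- c(min(c(cand, 1)) / 2,
              if (length(cand) > 1) (cand[-length(cand)] + cand[-1]) / 2,
              max(c(cand, 1)) * 2)
  winners <- vapply(probes, function(l) which.max(l * effect - cost), integer(1))
  list(frontier_set = sort(unique(winners)), probes = probes, winners = winners)
}

published_league <- function() {
  path <- system.file("extdata", "published_league_table.csv", package = "gccea")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

zero_mortality_table <- function() {
  bind_rate_tables(
    rate_table(0:110, rep("male", 111), rep(0, 111), "mortality"),
    rate_table(0:110, rep("female", 111), rep(0, 111), "mortality"))
}

zero_incidence_table <- function() {
  bind_rate_tables(
    rate_table(0:110, rep("male", 111), rep(0, 111), "incidence"),
    rate_table(0:110, rep("female", 111), rep(0, 111), "incidence"))
}

# degenerate PSA specs (no starting-age draw): distributions collapse onto
# the base case
degenerate_specs <- function(params) {
  specs <- lapply(1:4, function(s)
    list(path = paste0("utilities.stage", s), family = "gamma",
         mean = params$utilities$stage[s], sd = 1e-9, truncate_upper = 1))
  c(specs, list(
    list(path = "risk.odds_ratio", family = "lognormal",
         mean = params$risk$odds_ratio, sd = 1e-9),
    list(path = "risk.prevalence", family = "beta",
         mean = params$risk$prevalence, sd = 1e-9),
    list(path = "stage_dist.program", family = "dirichlet",
         proportions = params$stage_dist$program, ess = 1e18),
    list(path = "stage_dist.usual", family = "dirichlet",
         proportions = params$stage_dist$usual, ess = 1e18)
  ))
}
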