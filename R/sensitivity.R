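#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full five-arm model on the weighted target population at each
#' grid point of one parameter, all else held at base case, and reports the
#' per-strategy net health benefit at the chosen willingness-to-pay.
#'
#' @param param_path parameter dot-path (see [param_get()]); the virtual path
#'   `"population.start_age"` varies the starting age
#' @param range length-2 numeric `c(low, high)`
#' @param grid_size number of grid points (>= 2)
#' @param params base-case `gccea_params`
#' @param lambda willingness-to-pay ($/QALY)
#' @param eval_fn optional override: a function `f(theta)` returning a named
#'   numeric vector of per-strategy NHB (used for analytic test problems);
#'   when supplied the model is not run
#' @return data.frame with columns `param`, `value`, `strategy`, `cost`,
#'   `qaly`, `nhb` (cost/qaly `NA` under `eval_fn`)
#' @export
one_way_dsa <- function(param_path, range, grid_size = 5L, params = NULL,
                        lambda = NULL, eval_fn = NULL) {
  stopifnot(length(range) == 2L, grid_size >= 2L)
  grid <- seq(range[1], range[2], length.out = grid_size)
  if (is.null(eval_fn)) {
    if (is.null(lambda)) lambda <- params$econ$wtp
    eval_full <- function(theta) {
      p <- param_set(params, param_path, theta)
      res <- evaluate_strategies(p)
      data.frame(strategy = res$strategy, cost = res$cost, qaly = res$qaly,
                 nhb = nhb(res$cost, res$qaly, lambda))
    }
  } else {
    eval_full <- function(theta) {
      v <- eval_fn(theta)
      data.frame(strategy = names(v), cost = NA_real_, qaly = NA_real_, nhb = v)
    }
  }
  out <- lapply(grid, function(th) cbind(param = param_path, value = th,
                                         eval_full(th)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise a one-way DSA into swing and direction
#'
#' The swing of a strategy is the range of its NHB over the grid; a parameter
#' is influential when some strategy's swing reaches `influence_threshold`
#' (0.2 QALY by default). The reported direction is the sign of the NHB
#' change from the low to the high end for the strategy with the largest
#' swing, since several parameters move only a subset of arms.
#'
#' @param dsa a [one_way_dsa()] result
#' @param influence_threshold QALY change defining influence
#' @return one-row data.frame: `param`, `max_swing`, `influential`,
#'   `direction` (`"positive"`/`"negative"`/`"flat"`), `driver` strategy
#' @export
dsa_summary <- function(dsa, influence_threshold = 0.2) {
  by_s <- split(dsa, dsa$strategy)
  swing <- vapply(by_s, function(d) diff(range(d$nhb)), numeric(1))
  delta <- vapply(by_s, function(d) {
    d <- d[order(d$value), ]
    d$nhb[nrow(d)] - d$nhb[1L]
  }, numeric(1))
  driver <- names(which.max(swing))
  dirn <- if (max(swing) == 0) "flat" else if (delta[driver] > 0) "positive" else "negative"
  data.frame(param = dsa$param[1L], max_swing = max(swing),
             influential = max(swing) >= influence_threshold,
             direction = dirn, driver = driver, stringsAsFactors = FALSE)
}

#' Locate optimal-strategy switch points of one parameter
#'
#' Scans a coarse grid of the parameter for changes in the NHB-optimal
#' strategy, then bisects each sign change of the NHB difference between the
#' two competing strategies down to `tol` in parameter units. Each located
#' sub-interval's label is verified by a mid-point evaluation.
#'
#' @inheritParams one_way_dsa
#' @param tol bisection tolerance in parameter units
#' @param scan_size coarse scan grid size
#' @param max_crossings error out beyond this many cut-points rather than
#'   silently truncating a non-monotone pathology
#' @return list with `param`, `cutpoints` (increasing, interior), `optimal`
#'   (labels on the `length(cutpoints) + 1` sub-intervals), `direction`
#'   (from [dsa_summary()] on the scan)
#' @export
find_switch_thresholds <- function(param_path, range, params = NULL,
                                   lambda = NULL, tol = 1e-6,
                                   eval_fn = NULL, scan_size = 9L,
                                   max_crossings = 8L) {
  if (is.null(eval_fn)) {
    if (is.null(lambda)) lambda <- params$econ$wtp
    eval_fn <- function(theta) {
      p <- param_set(params, param_path, theta)
      res <- evaluate_strategies(p)
      stats::setNames(nhb(res$cost, res$qaly, lambda), res$strategy)
    }
  }
  grid <- seq(range[1], range[2], length.out = scan_size)
  evals <- lapply(grid, eval_fn)
  winners <- vapply(evals, function(v) names(v)[which.max(v)], character(1))
  cut <- numeric(0)
  labs <- winners[1L]
  for (i in seq_len(scan_size - 1L)) {
    if (winners[i] == winners[i + 1L]) next
    a <- winners[i]; b <- winners[i + 1L]
    g <- function(th) { v <- eval_fn(th); v[[a]] - v[[b]] }
    lo <- grid[i]; hi <- grid[i + 1L]
    glo <- g(lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    cut <- c(cut, (lo + hi) / 2)
    labs <- c(labs, b)
    if (length(cut) > max_crossings)
      stop("more than ", max_crossings,
           " optimal-strategy crossings: non-monotone pathology", call. = FALSE)
  }
  # verify sub-interval labels at mid-points
  bounds <- c(range[1], cut, range[2])
  for (k in seq_along(labs)) {
    mid <- (bounds[k] + bounds[k + 1L]) / 2
    v <- eval_fn(mid)
    labs[k] <- names(v)[which.max(v)]
  }
  dsa <- data.frame(param = param_path,
                    value = rep(grid, each = length(evals[[1L]])),
                    strategy = rep(names(evals[[1L]]), scan_size),
                    cost = NA_real_, qaly = NA_real_,
                    nhb = unlist(evals, use.names = FALSE))
  list(param = param_path, cutpoints = cut, optimal = labs,
       direction = dsa_summary(dsa)$direction)
}

# ---- probabilistic sensitivity analysis --------------------------------

#' Fit a distribution by the method of moments
#'
#' Gamma: `shape = (mean/sd)^2`, `rate = mean/sd^2`. Log-normal:
#' `sigma^2 = log(1 + sd^2/mean^2)`, `mu = log(mean) - sigma^2/2`. Beta:
#' `nu = mean(1-mean)/sd^2 - 1`, `alpha = mean*nu`, `beta = (1-mean)*nu`
#' (errors when `sd^2 >= mean(1-mean)`, the feasibility bound).
#'
#' @param family `"gamma"`, `"lognormal"` or `"beta"`
#' @param mean,sd target moments (`sd > 0`; beta requires `0 < mean < 1`)
#' @return list with `family`, fitted `params`, and `sampler(n)` drawing from
#'   the fitted distribution
#' @export
fit_moments <- function(family = c("gamma", "lognormal", "beta"), mean, sd) {
  family <- match.arg(family)
  if (!(sd > 0)) stop("sd must be > 0", call. = FALSE)
  switch(family,
    gamma = {
      if (mean <= 0) stop("gamma mean must be > 0", call. = FALSE)
      shape <- (mean / sd)^2; rate <- mean / sd^2
      list(family = family, params = c(shape = shape, rate = rate),
           sampler = function(n) stats::rgamma(n, shape = shape, rate = rate))
    },
    lognormal = {
      if (mean <= 0) stop("lognormal mean must be > 0", call. = FALSE)
      s2 <- log(1 + sd^2 / mean^2)
      mu <- log(mean) - s2 / 2
      list(family = family, params = c(meanlog = mu, sdlog = sqrt(s2)),
           sampler = function(n) stats::rlnorm(n, meanlog = mu, sdlog = sqrt(s2)))
    },
    beta = {
      if (!(mean > 0 && mean < 1)) stop("beta mean must be in (0, 1)", call. = FALSE)
      if (sd^2 >= mean * (1 - mean))
        stop("infeasible beta moments: sd^2 >= mean*(1-mean)", call. = FALSE)
      nu <- mean * (1 - mean) / sd^2 - 1
      a <- mean * nu; b <- (1 - mean) * nu
      list(family = family, params = c(shape1 = a, shape2 = b),
           sampler = function(n) stats::rbeta(n, shape1 = a, shape2 = b))
    })
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Default PSA distribution specs
#'
#' The nine uncertain quantities: the four stage utilities (Gamma, truncated
#' at 1), the odds ratio (log-normal, mean 6.00 sd 2.46), the premalignancy
#' prevalence (Beta, mean 0.135 sd 0.0675), the two stage distributions
#' (Dirichlet with concentration `proportions * dirichlet_ess`) and the
#' starting age/sex (drawn from the population weights).
#'
#' @param params a `gccea_params` (for base means and the age weights)
#' @return list of distribution specs consumed by [sample_params()]
#' @export
default_psa_specs <- function(params) {
  u_sd <- c(0.05, 0.07, 0.10, 0.08)
  specs <- lapply(1:4, function(s) {
    list(path = paste0("utilities.stage", s), family = "gamma",
         mean = params$utilities$stage[s], sd = u_sd[s], truncate_upper = 1)
  })
  c(specs, list(
    list(path = "risk.odds_ratio", family = "lognormal", mean = 6.00, sd = 2.46),
    list(path = "risk.prevalence", family = "beta", mean = 0.135, sd = 0.0675),
    list(path = "stage_dist.program", family = "dirichlet",
         proportions = params$stage_dist$program, ess = params$psa$dirichlet_ess),
    list(path = "stage_dist.usual", family = "dirichlet",
         proportions = params$stage_dist$usual, ess = params$psa$dirichlet_ess),
    list(path = "population.start_age", family = "empirical_age",
         weights = params$epi$weights)
  ))
}

#' Draw one parameter set for the PSA
#'
#' Draws are independent across specs. Gamma-drawn utilities are censored at
#' 1; a Dirichlet spec replaces the whole stage-proportion vector; an
#' `empirical_age` spec collapses the population weights to the drawn
#' (age, sex) cell. Draws can transiently violate the base-case ordering of
#' stage utilities (the stated marginals overlap); the engine does not rely
#' on that ordering.
#'
#' @param base_params base-case `gccea_params`
#' @param specs list of distribution specs ([default_psa_specs()] shaped)
#' @param seed optional integer seed for this draw
#' @return a `gccea_params` draw
#' @export
sample_params <- function(base_params, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- base_params
  for (sp in specs) {
    if (sp$family %in% c("gamma", "lognormal", "beta")) {
      x <- fit_moments(sp$family, sp$mean, sp$sd)$sampler(1)
      if (!is.null(sp$truncate_upper)) x <- min(x, sp$truncate_upper)
      p <- param_set(p, sp$path, x)
    } else if (sp$family == "dirichlet") {
      draw <- rdirichlet1(sp$proportions * sp$ess)
      parts <- param_path_split(sp$path)
      p <- assign_path(p, parts, draw)
    } else if (sp$family == "empirical_age") {
      w <- sp$weights
      j <- sample.int(nrow(w), 1L, prob = w$weight)
      pick <- data.frame(age = w$age[j], sex = w$sex[j], weight = 1)
      p$epi$weights <- normalize_weights(pick)
    } else stop("unknown PSA family: ", sp$family, call. = FALSE)
  }
  p
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 9973) %% 2147483629L)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each Monte Carlo iteration a parameter set is drawn (seeded by a
#' counter-based substream so that earlier iterations are unchanged when `n`
#' grows), the full five-arm model is run on it, and per-strategy cost and
#' effect are recorded. The cost-effectiveness acceptability frontier is then
#' computed on `lambda_grid`: at each willingness-to-pay the frontier
#' strategy maximises the *expected* net monetary benefit, and its
#' probability is the fraction of iterations in which it attains the maximal
#' NMB (exact ties split equally).
#'
#' @param params base-case `gccea_params`
#' @param specs distribution specs (default [default_psa_specs()])
#' @param n number of Monte Carlo iterations
#' @param seed integer master seed
#' @param lambda_grid willingness-to-pay grid ($/QALY)
#' @return list with `samples` (iteration, strategy, cost, effect) and
#'   `ceaf` (lambda, strategy, probability)
#' @export
run_psa <- function(params, specs = default_psa_specs(params), n = 1000L,
                    seed = 1L, lambda_grid = seq(0, 100000, by = 1000)) {
  stopifnot(n >= 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    draw <- sample_params(params, specs, seed = derive_seed(seed, i))
    res <- evaluate_strategies(draw)
    rows[[i]] <- data.frame(iteration = i, strategy = res$strategy,
                            cost = res$cost, effect = res$qaly,
                            stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  list(samples = samples, ceaf = ceaf(samples, lambda_grid))
}

#' Cost-effectiveness acceptability frontier from PSA samples
#'
#' @param samples data.frame with `iteration`, `strategy`, `cost`, `effect`
#' @param lambda_grid willingness-to-pay grid (values > 0 are evaluated;
#'   a 0 entry is kept and treated as the limit `lambda -> 0+`, where only
#'   cost matters)
#' @return data.frame `lambda`, `strategy` (max expected NMB), `probability`
#' @export
ceaf <- function(samples, lambda_grid) {
  strategies <- unique(samples$strategy)
  cost <- matrix(samples$cost[order(samples$iteration, match(samples$strategy, strategies))],
                 ncol = length(strategies), byrow = TRUE,
                 dimnames = list(NULL, strategies))
  eff <- matrix(samples$effect[order(samples$iteration, match(samples$strategy, strategies))],
                ncol = length(strategies), byrow = TRUE,
                dimnames = list(NULL, strategies))
  out <- lapply(lambda_grid, function(l) {
    nmb <- if (l > 0) l * eff - cost else -cost
    mean_nmb <- colMeans(nmb)
    star <- strategies[which.max(mean_nmb)]
    rowmax <- apply(nmb, 1L, max)
    is_max <- nmb >= rowmax # exact ties share credit
    credit <- is_max[, star] / rowSums(is_max)
    data.frame(lambda = l, strategy = star, probability = mean(credit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
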