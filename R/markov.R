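#' Split population incidence into low- and high-risk incidence
#'
#' Given the annual population probability of developing gastric cancer
#' `q_pop`, the prevalence `p` of premalignant lesions and the odds ratio
#' `or` of cancer for lesion carriers versus non-carriers, returns the pair
#' `(q_low, q_high)` satisfying the mixture constraint
#' `p * q_high + (1 - p) * q_low = q_pop` and the odds constraint
#' `odds(q_high) = or * odds(q_low)`. The system reduces to a quadratic in
#' `q_low`, solved in closed form with the numerically stable root.
#'
#' @param q_pop annual population probability, `0 <= q_pop < 1`
#' @param p prevalence of premalignancy, in (0, 1)
#' @param or odds ratio >= 1
#' @return named numeric vector `c(q_low =, q_high =)`
#' @export
split_incidence <- function(q_pop, p, or) {
  if (!(q_pop >= 0 && q_pop < 1)) stop("q_pop must be in [0, 1)", call. = FALSE)
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (or < 1) stop("odds ratio must be >= 1", call. = FALSE)
  if (q_pop == 0 || or == 1)
    return(c(q_low = q_pop, q_high = q_pop))
  # (1-p)(or-1) x^2 + [p*or + 1 - p + q(1-or)] x - q = 0, x = q_low
  A <- (1 - p) * (or - 1)
  B <- p * or + 1 - p + q_pop * (1 - or)
  C <- -q_pop
  # B > 0 here; take the positive root via the stable formulation
  disc <- B * B - 4 * A * C
  q_low <- (2 * C) / (-B - sqrt(disc))
  odds_high <- or * q_low / (1 - q_low)
  q_high <- odds_high / (1 + odds_high)
  if (!(q_low >= 0 && q_high <= 1))
    stop("no valid risk split in (0, 1)", call. = FALSE) # unreachable for valid inputs
  c(q_low = q_low, q_high = q_high)
}

#' Annual cancer-specific death probability from 5-year survival
#'
#' Constant-hazard conversion `1 - S5^(1/5)`. A stage with printed 5-year
#' survival of exactly 0 uses the configured residual `stage4_epsilon`
#' instead, keeping the hazard finite.
#'
#' @param stage clinical stage 1-4
#' @param survival list with `five_year` (length-4) and `stage4_epsilon`
#' @return annual probability of dying from gastric cancer
#' @export
annual_stage_death_prob <- function(stage, survival) {
  stopifnot(stage %in% 1:4)
  s5 <- survival$five_year[stage]
  if (s5 < 0 || s5 > 1) stop("5-year survival outside [0, 1]", call. = FALSE)
  if (s5 == 0) s5 <- survival$stage4_epsilon
  1 - s5^(1 / 5)
}

#' Combine independent competing death risks
#'
#' `1 - (1 - p_gc) * (1 - p_background)`: the probability of dying within a
#' cycle from either gastric cancer or another cause, assuming independent
#' risks. [death_attribution()] splits the combined deaths between causes in
#' proportion to the `-log(1 - p)` hazards.
#'
#' @param p_gc annual cancer-specific death probability
#' @param p_background annual other-cause death probability
#' @return total annual death probability
#' @export
combine_competing_risks <- function(p_gc, p_background) {
  stopifnot(all(p_gc >= 0 & p_gc <= 1), all(p_background >= 0 & p_background <= 1))
  1 - (1 - p_gc) * (1 - p_background)
}

#' Share of combined deaths attributable to gastric cancer
#' @inheritParams combine_competing_risks
#' @return fraction of deaths attributed to cancer (vectorised)
#' @export
death_attribution <- function(p_gc, p_background) {
  h_gc <- -log1p(-pmin(p_gc, 1 - 1e-15))
  h_bg <- -log1p(-pmin(p_background, 1 - 1e-15))
  tot <- h_gc + h_bg
  share <- ifelse(tot > 0, h_gc / tot, 0)
  # both probabilities 1 => hazards infinite; split evenly
  share[!is.finite(h_gc) & !is.finite(h_bg)] <- 0.5
  share[!is.finite(h_gc) & is.finite(h_bg)] <- 1
  share
}

# Per-group OGD schedule over cycles 0..n-1. A group with period NA has no
# scheduled follow-up (its only endoscopy is the classifying baseline OGD,
# which precedes the cycle's incident cancers and so carries no detection
# weight). Cycle 0 counts as an OGD year for scheduled groups.
schedule_group <- function(strategy, group, n_cycles) {
  period <- if (group == "high") strategy$highrisk_period else strategy$lowrisk_period
  cycles <- 0:(n_cycles - 1)
  if (is.na(period)) {
    delivered <- rep(FALSE, n_cycles)
    if (strategy$baseline_ogd) delivered[1] <- TRUE
    w_kind <- rep("none", n_cycles)
  } else {
    delivered <- cycles %% period == 0
    w_kind <- ifelse(delivered, "ogd", if (period == 2) "interval" else "none")
  }
  list(delivered = delivered, w_kind = w_kind)
}

#' Early-detection weight for a group and cycle
#'
#' `w = Se` in cycles where the group's schedule delivers an OGD, `Se * f` in
#' the interval years of a 2-yearly schedule (`f` the strategy's
#' interval-effect fraction), and 0 for groups without OGD follow-up.
#'
#' @param strategy a strategy spec (see [default_strategies()]) or its name
#' @param risk_group `"high"` or `"low"`
#' @param cycle_index cycle number, 0-based
#' @param params model parameters (for sensitivity and interval fraction)
#' @return detection weight in \[0, 1\]
#' @export
detection_weight <- function(strategy, risk_group, cycle_index, params) {
  if (is.character(strategy)) strategy <- params$strategies[[strategy]]
  sched <- schedule_group(strategy, risk_group, cycle_index + 1L)
  kind <- sched$w_kind[cycle_index + 1L]
  se <- params$test$sensitivity
  switch(kind,
         ogd = se,
         interval = se * strategy$interval_effect,
         none = 0)
}

#' Stage distribution of cancers diagnosed under partial early detection
#'
#' Element-wise mixture `w * program + (1 - w) * usual` of the
#' programme-detected and usual-practice stage distributions.
#'
#' @param w detection weight in \[0, 1\]
#' @param program_dist,usual_dist length-4 stage proportions summing to 1
#' @return length-4 stage distribution
#' @export
stage_mix_at_diagnosis <- function(w, program_dist, usual_dist) {
  stopifnot(w >= 0, w <= 1)
  w * program_dist + (1 - w) * usual_dist
}

#' Cost of delivering one OGD including programme overhead
#'
#' The programme cost proportion `pi` is the share of the total operating
#' budget spent on non-endoscopy activities, so the full per-examination
#' delivery cost is `endoscopy_cost / (1 - pi)`.
#'
#' @param endoscopy_cost raw OGD/biopsy cost
#' @param proportion programme cost proportion in \[0, 1)
#' @return delivered cost per OGD
#' @export
ogd_delivery_cost <- function(endoscopy_cost, proportion) {
  stopifnot(proportion >= 0, proportion < 1)
  endoscopy_cost / (1 - proportion)
}

#' Run one Markov cohort
#'
#' Propagates a cohort starting asymptomatic at `start_age` through annual
#' cycles under one strategy. Cycle order: OGD delivery and programme costs
#' for alive non-cancer occupants, incidence (population probability, split
#' into low/high risk for intervention arms, with the split re-solved each
#' cycle at the current high-risk share so total incidence is unaffected by
#' stratification), stage assignment and diagnosis/treatment costs, utility
#' accrual (asymptomatic 1, stage-specific for cancer states, 0 dead), then
#' mortality (background for asymptomatic; background combined with the
#' constant stage-specific excess hazard for cancer states). Post-treatment
#' follow-up cost accrues to cancer survivors for at most 5 years after
#' diagnosis. Costs and QALYs are discounted by `(1 + r)^-cycle`; the trace
#' ends when the dead fraction reaches `termination_fraction` or age reaches
#' `max_age`.
#'
#' @param strategy strategy name or spec
#' @param sex `"male"` or `"female"`
#' @param start_age starting age (must be covered by the rate tables)
#' @param params a `gccea_params` object
#' @param initial optional non-standard initial state: `list(stage = s)`
#'   starts the whole cohort in cancer stage `s` at diagnosis (used for
#'   stage-survival checks)
#' @return a `cohort_trace`: data.frame of per-cycle end-of-cycle occupancy
#'   and discounted cost/QALY increments, with attributes `strategy`, `sex`,
#'   `start_age`
#' @export
run_cohort <- function(strategy, sex, start_age, params, initial = NULL) {
  if (is.character(strategy)) {
    strategy <- params$strategies[[strategy]]
    if (is.null(strategy)) stop("unknown strategy", call. = FALSE)
  }
  econ <- params$econ
  n_max <- econ$max_age - start_age + 1L
  if (n_max < 1L) stop("start_age exceeds max_age", call. = FALSE)
  ages <- start_age:econ$max_age
  q_bg <- rate_lookup(params$epi$mortality, ages, sex)
  q_pop <- rate_lookup(params$epi$incidence, ages, sex) / 1e5
  if (any(q_pop >= 1)) stop("incidence implies annual probability >= 1", call. = FALSE)
  disc <- (1 + econ$discount_rate)^-(0:(n_max - 1L))

  se <- params$test$sensitivity
  sp <- params$test$specificity
  costs <- params$costs
  u_stage <- params$utilities$stage
  u_asym <- params$utilities$asymptomatic
  prog <- params$stage_dist$program
  usual <- params$stage_dist$usual
  p_gc <- vapply(1:4, annual_stage_death_prob, numeric(1),
                 survival = params$survival)
  prev <- params$risk$prevalence
  or <- params$risk$odds_ratio
  stratified <- strategy$name != "none"

  sched_low <- schedule_group(strategy, "low", n_max)
  sched_high <- schedule_group(strategy, "high", n_max)
  w_of <- function(kind) switch(kind, ogd = se,
                                interval = se * strategy$interval_effect, none = 0)
  w_low <- vapply(sched_low$w_kind, w_of, numeric(1), USE.NAMES = FALSE)
  w_high <- vapply(sched_high$w_kind, w_of, numeric(1), USE.NAMES = FALSE)

  # state: two asymptomatic groups, 4 stages x years-since-diagnosis 0..6
  # (column 7 pools 6+ years; follow-up cost stops after 5 payments)
  L <- 0; H <- 0
  G <- matrix(0, nrow = 4, ncol = 7)
  dead_gc <- 0; dead_other <- 0
  if (is.null(initial)) {
    if (stratified) { H <- prev; L <- 1 - prev } else L <- 1
  } else {
    G[initial$stage, 1] <- 1
  }

  cols <- c("cycle", "age", "asym_low", "asym_high",
            paste0("gc_stage", 1:4), "dead_gc", "dead_other",
            "cost", "qaly", "ogd", "gc_incidence", "gc_deaths")
  out <- matrix(NA_real_, nrow = n_max, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (t in seq_len(n_max) - 1L) {
    i <- t + 1L
    age <- ages[i]
    alive_asym <- L + H

    # 1. OGD delivery
    n_ogd <- (if (sched_low$delivered[i]) L else 0) +
      (if (sched_high$delivered[i]) H else 0)
    unit <- if (t == 0L && strategy$baseline_ogd)
      ogd_delivery_cost(costs$baseline_ogd, costs$program_cost_proportion)
    else
      ogd_delivery_cost(costs$followup_ogd, costs$program_cost_proportion)
    cost <- n_ogd * unit + n_ogd * (1 - sp) * costs$dx_staging_program

    # 2. incidence: per-cycle re-solve keeps the pooled incidence exact
    q <- q_pop[i]
    if (stratified && alive_asym > 0 && q > 0) {
      p_t <- H / alive_asym
      if (p_t > 0 && p_t < 1) {
        qs <- split_incidence(q, p_t, or)
        q_l <- qs[["q_low"]]; q_h <- qs[["q_high"]]
      } else { q_l <- q; q_h <- q }
    } else { q_l <- q; q_h <- q }
    inc_L <- L * q_l
    inc_H <- H * q_h
    inc_tot <- inc_L + inc_H

    # 3. stage assignment and diagnosis/treatment costs
    mix_L <- stage_mix_at_diagnosis(w_low[i], prog, usual)
    mix_H <- stage_mix_at_diagnosis(w_high[i], prog, usual)
    new_stage <- inc_L * mix_L + inc_H * mix_H
    dx_unit_L <- w_low[i] * costs$dx_staging_program + (1 - w_low[i]) * costs$dx_staging_usual
    dx_unit_H <- w_high[i] * costs$dx_staging_program + (1 - w_high[i]) * costs$dx_staging_usual
    cost <- cost + inc_L * dx_unit_L + inc_H * dx_unit_H +
      sum(new_stage * costs$treatment)

    # 4. post-treatment follow-up: survivors 1-5 years after diagnosis
    cost <- cost + costs$post_treatment_followup * sum(G[, 2:6])

    # 5. utility accrual (alive at cycle start, full-year)
    stage_occ <- rowSums(G) + new_stage
    qaly <- (alive_asym - inc_tot) * u_asym + sum(stage_occ * u_stage)
    if (econ$half_cycle_correction && t == 0L) qaly <- qaly * 0.5

    # 6. mortality
    qb <- q_bg[i]
    L <- (L - inc_L) * (1 - qb)
    H <- (H - inc_H) * (1 - qb)
    dead_other <- dead_other + (alive_asym - inc_tot) * qb
    G[, 1] <- G[, 1] + new_stage
    p_tot <- combine_competing_risks(p_gc, qb)
    share <- death_attribution(p_gc, qb)
    deaths_stage <- rowSums(G) * p_tot
    dead_gc_inc <- sum(deaths_stage * share)
    dead_gc <- dead_gc + dead_gc_inc
    dead_other <- dead_other + sum(deaths_stage * (1 - share))
    G <- G * (1 - p_tot)

    # 7. advance years-since-diagnosis
    G[, 7] <- G[, 7] + G[, 6]
    G[, 2:6] <- G[, 1:5]
    G[, 1] <- 0

    out[i, ] <- c(t, age, L, H, rowSums(G), dead_gc, dead_other,
                  cost * disc[i], qaly * disc[i], n_ogd, inc_tot, dead_gc_inc)
    if (dead_gc + dead_other >= econ$termination_fraction) break
  }

  trace <- as.data.frame(out[!is.na(out[, 1]), , drop = FALSE])
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "strategy") <- strategy$name
  attr(trace, "sex") <- sex
  attr(trace, "start_age") <- start_age
  trace
}

#' Lifetime outcomes of a cohort trace
#'
#' Sums the discounted per-cycle increments into per-person discounted cost
#' and QALYs, lifetime OGD examinations (undiscounted count) and cumulative
#' gastric-cancer deaths.
#'
#' @param trace a `cohort_trace`
#' @return one-row data.frame with columns `strategy`, `sex`, `start_age`,
#'   `cost`, `qaly`, `ogd`, `gc_deaths`
#' @export
lifetime_outcomes <- function(trace) {
  data.frame(
    strategy = attr(trace, "strategy") %||% NA_character_,
    sex = attr(trace, "sex") %||% NA_character_,
    start_age = attr(trace, "start_age") %||% NA_real_,
    cost = sum(trace$cost),
    qaly = sum(trace$qaly),
    ogd = sum(trace$ogd),
    gc_deaths = trace$dead_gc[nrow(trace)],
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weight-average subgroup outcomes over the population
#'
#' @param results data.frame of [lifetime_outcomes()] rows (one per
#'   (strategy, sex, start_age) subgroup)
#' @param weights population weights (columns `age`, `sex`, `weight`)
#' @return data.frame with one row per strategy: weighted per-person
#'   `cost`, `qaly`, `ogd`, `gc_deaths`
#' @export
aggregate_outcomes <- function(results, weights) {
  wmap <- stats::setNames(weights$weight, paste(weights$age, weights$sex))
  wt <- wmap[paste(results$start_age, results$sex)]
  if (anyNA(wt))
    stop("subgroup keys in results not covered by the population weights", call. = FALSE)
  split_res <- split(seq_len(nrow(results)), results$strategy)
  out <- lapply(names(split_res), function(s) {
    rows <- results[split_res[[s]], , drop = FALSE]
    w <- wt[split_res[[s]]]
    if (abs(sum(w) - 1) > 1e-9)
      stop("weights for strategy ", s, " do not cover the full population", call. = FALSE)
    data.frame(strategy = s,
               cost = sum(rows$cost * w), qaly = sum(rows$qaly * w),
               ogd = sum(rows$ogd * w), gc_deaths = sum(rows$gc_deaths * w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  ord <- c(intersect(strategy_names(), out$strategy),
           setdiff(out$strategy, strategy_names()))
  out <- out[match(ord, out$strategy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate all strategies on the weighted target population
#'
#' Runs every requested strategy for every (age, sex) subgroup with positive
#' weight and aggregates to per-person population outcomes.
#'
#' @param params a `gccea_params` object
#' @param strategies character vector of strategy names (default: all five)
#' @param detail if `TRUE`, also return the per-subgroup results
#' @return data.frame of per-strategy population outcomes (and, with
#'   `detail`, attribute `"subgroups"` holding the per-subgroup rows)
#' @export
evaluate_strategies <- function(params, strategies = strategy_names(),
                                detail = FALSE) {
  w <- params$epi$weights
  w <- w[w$weight > 0, , drop = FALSE]
  rows <- vector("list", nrow(w) * length(strategies))
  k <- 0L
  for (s in strategies) {
    for (j in seq_len(nrow(w))) {
      k <- k + 1L
      rows[[k]] <- lifetime_outcomes(
        run_cohort(s, w$sex[j], w$age[j], params))
    }
  }
  sub <- do.call(rbind, rows)
  agg <- aggregate_outcomes(sub, w)
  if (detail) attr(agg, "subgroups") <- sub
  agg
}

#' Export a cohort trace to CSV
#' @param trace a `cohort_trace`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
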