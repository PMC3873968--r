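#' Built-in strategy definitions
#'
#' Five arms are modelled. `baseline_ogd` marks arms that enrol a surveillance
#' cohort with a dedicated baseline endoscopy (charged at the baseline OGD
#' cost); in the pure screening arm the cycle-0 examination is an ordinary
#' screening round. `highrisk_period` / `lowrisk_period` give the OGD
#' follow-up interval in years for each risk group (`NA` = no scheduled OGD),
#' and `interval_effect` is the fraction of the annual-follow-up early
#' detection effect retained in the non-OGD years of a 2-yearly schedule
#' (0.60 for 2-yearly surveillance, 0.40 for 2-yearly screening).
#'
#' @return named list of strategy specifications
#' @export
default_strategies <- function() {
  list(
    none = list(name = "none", label = "No OGD intervention",
                baseline_ogd = FALSE, highrisk_period = NA_real_,
                lowrisk_period = NA_real_, interval_effect = 0),
    surveil2y = list(name = "surveil2y", label = "2-yearly surveillance",
                     baseline_ogd = TRUE, highrisk_period = 2,
                     lowrisk_period = NA_real_, interval_effect = 0.60),
    surveil1y = list(name = "surveil1y", label = "Annual surveillance",
                     baseline_ogd = TRUE, highrisk_period = 1,
                     lowrisk_period = NA_real_, interval_effect = 0),
    screen2y = list(name = "screen2y", label = "2-yearly screening",
                    baseline_ogd = FALSE, highrisk_period = 2,
                    lowrisk_period = 2, interval_effect = 0.40),
    screen2y_surveil1y = list(name = "screen2y_surveil1y",
                              label = "2-yearly screening + annual surveillance",
                              baseline_ogd = TRUE, highrisk_period = 1,
                              lowrisk_period = 2, interval_effect = 0.40)
  )
}

#' All strategy names in cost order of the base case
#' @export
strategy_names <- function() names(default_strategies())

#' Default model parameters
#'
#' Point estimates: premalignancy prevalence 13.5% with gastric-cancer odds
#' ratio 6.0 for carriers; OGD sensitivity 0.93 and specificity 1; stage
#' distribution at diagnosis 85:4:8:3 under programme detection and 7:17:33:43
#' under usual care; stage-specific 5-year survival 90/70/40/0% (stage 4
#' modelled with a small residual `stage4_epsilon` so the constant hazard is
#' finite); 2012 US$ costs (baseline OGD 350, follow-up OGD 340, diagnosis and
#' staging 740 programme / 1155 usual care, treatment 17,000/27,200/38,000/
#' 15,500 by stage, post-treatment follow-up 955 per year for up to 5 years,
#' programme overhead 40% of the operating budget); stage utilities
#' 0.88/0.86/0.77/0.68 with asymptomatic 1 and dead 0; 3% annual discounting
#' and a willingness-to-pay of $46,200/QALY. Synthetic epidemiology
#' (Gompertz-Makeham life tables, exponential age-incidence) and uniform
#' population weights over ages 50-69 x sex are attached.
#'
#' @param epi optional list with elements `mortality`, `incidence`
#'   ([rate_table()]s covering both sexes) and `weights`
#'   ([default_population_weights()] shaped); defaults to the synthetic tables
#' @return an object of class `gccea_params`
#' @export
default_params <- function(epi = NULL) {
  if (is.null(epi)) {
    epi <- list(
      mortality = bind_rate_tables(generate_life_table("male"),
                                   generate_life_table("female")),
      incidence = bind_rate_tables(generate_incidence_table("male"),
                                   generate_incidence_table("female")),
      weights = default_population_weights()
    )
  }
  p <- list(
    risk = list(prevalence = 0.135, odds_ratio = 6.0),
    test = list(sensitivity = 0.93, specificity = 1.0),
    stage_dist = list(program = c(0.85, 0.04, 0.08, 0.03),
                      usual = c(0.07, 0.17, 0.33, 0.43)),
    survival = list(five_year = c(0.90, 0.70, 0.40, 0.00),
                    stage4_epsilon = 0.001),
    costs = list(baseline_ogd = 350, followup_ogd = 340,
                 dx_staging_program = 740, dx_staging_usual = 1155,
                 treatment = c(17000, 27200, 38000, 15500),
                 post_treatment_followup = 955,
                 program_cost_proportion = 0.40),
    utilities = list(asymptomatic = 1, dead = 0,
                     stage = c(0.88, 0.86, 0.77, 0.68)),
    econ = list(discount_rate = 0.03, wtp = 46200,
                termination_fraction = 0.99, max_age = 110,
                half_cycle_correction = FALSE),
    strategies = default_strategies(),
    psa = list(dirichlet_ess = 100),
    epi = epi
  )
  class(p) <- "gccea_params"
  p
}

# ---- parameter paths ---------------------------------------------------

# Flat dot-paths into the params list; vector components addressed with a
# 1-based index suffix, e.g. "utilities.stage1". "population.start_age"
# is virtual: setting it collapses the population weights to one age (both
# sexes, equal weight).
param_path_split <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Get a scalar parameter by dot-path
#' @param params a `gccea_params` object
#' @param path e.g. `"risk.odds_ratio"`, `"utilities.stage1"`,
#'   `"strategies.surveil2y.interval_effect"`
#' @return numeric scalar
#' @export
param_get <- function(params, path) {
  parts <- param_path_split(path)
  node <- params
  for (i in seq_along(parts)) {
    key <- parts[i]
    if (is.list(node) && !is.null(node[[key]])) {
      node <- node[[key]]
    } else if (is.list(node) && grepl("[0-9]+$", key)) {
      base <- sub("[0-9]+$", "", key)
      idx <- as.integer(sub(paste0("^", base), "", key))
      if (is.null(node[[base]]) || idx > length(node[[base]]))
        stop("unknown parameter path: ", path, call. = FALSE)
      node <- node[[base]][idx]
    } else {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
  }
  if (!is.numeric(node) || length(node) != 1L)
    stop("parameter path does not resolve to a scalar: ", path, call. = FALSE)
  node
}

#' Set a scalar parameter by dot-path
#' @inheritParams param_get
#' @param value new numeric value
#' @return modified `gccea_params`
#' @export
param_set <- function(params, path, value) {
  if (path == "population.start_age") {
    age <- as.integer(round(value))
    w <- data.frame(age = age, sex = c("male", "female"), weight = 0.5)
    params$epi$weights <- normalize_weights(w)
    return(params)
  }
  parts <- param_path_split(path)
  set_rec <- function(node, parts) {
    key <- parts[1]
    if (length(parts) == 1L) {
      if (!is.null(node[[key]]) && is.numeric(node[[key]]) &&
          length(node[[key]]) == 1L) {
        node[[key]] <- value
      } else if (grepl("[0-9]+$", key)) {
        base <- sub("[0-9]+$", "", key)
        idx <- as.integer(sub(paste0("^", base), "", key))
        if (is.null(node[[base]]) || idx > length(node[[base]]))
          stop("unknown parameter path: ", path, call. = FALSE)
        node[[base]][idx] <- value
      } else stop("unknown parameter path: ", path, call. = FALSE)
    } else {
      if (is.null(node[[key]]))
        stop("unknown parameter path: ", path, call. = FALSE)
      node[[key]] <- set_rec(node[[key]], parts[-1])
    }
    node
  }
  out <- set_rec(unclass(params), parts)
  class(out) <- "gccea_params"
  out
}

#' Plausible ranges for every tunable parameter
#'
#' Cost ranges follow the halve/double rule used for right-skewed cost data;
#' clinical and epidemiological ranges are literature bounds. Queried by the
#' deterministic sensitivity analysis.
#'
#' @return named list mapping parameter path to `c(low, high)`
#' @export
param_ranges <- function() {
  list(
    "risk.prevalence" = c(0.065, 0.27),
    "risk.odds_ratio" = c(2.4, 21.5),
    "test.sensitivity" = c(0.44, 0.99),
    "test.specificity" = c(0.95, 1.0),
    "costs.baseline_ogd" = c(175, 750),
    "costs.followup_ogd" = c(170, 680),
    "costs.dx_staging_program" = c(660, 820),
    "costs.dx_staging_usual" = c(960, 1440),
    "costs.treatment1" = c(8500, 34000),
    "costs.treatment2" = c(13600, 54400),
    "costs.treatment3" = c(19000, 76000),
    "costs.treatment4" = c(7800, 31100),
    "costs.post_treatment_followup" = c(900, 1300),
    "costs.program_cost_proportion" = c(0.20, 0.80),
    "utilities.stage1" = c(0.60, 1.00),
    "utilities.stage2" = c(0.62, 0.99),
    "utilities.stage3" = c(0.58, 0.95),
    "utilities.stage4" = c(0.51, 0.84),
    "econ.discount_rate" = c(0.0, 0.05),
    "econ.wtp" = c(15000, 100000),
    "strategies.surveil2y.interval_effect" = c(0.40, 0.90),
    "population.start_age" = c(50, 69)
  )
}

#' Validate a parameter set
#'
#' Checks every structural invariant (probabilities in range, stage
#' distributions summing to 1, non-increasing utilities and survival, costs
#' non-negative, epidemiology tables well formed and covering the population)
#' and returns a character vector of violations, empty when the set is valid.
#'
#' @param params a `gccea_params` object
#' @return character vector of violation messages (empty if none)
#' @export
validate_params <- function(params) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v

  p <- params$risk$prevalence
  v <- add(!(p > 0 && p < 1), "risk.prevalence: outside (0, 1)")
  v <- add(params$risk$odds_ratio < 1, "risk.odds_ratio: must be >= 1")
  v <- add(!(params$test$sensitivity >= 0 && params$test$sensitivity <= 1),
           "test.sensitivity: outside [0, 1]")
  v <- add(!(params$test$specificity >= 0 && params$test$specificity <= 1),
           "test.specificity: outside [0, 1]")
  for (nm in c("program", "usual")) {
    d <- params$stage_dist[[nm]]
    v <- add(length(d) != 4L || any(d < 0), paste0("stage_dist.", nm, ": negative or wrong length"))
    v <- add(abs(sum(d) - 1) > 1e-12, paste0("stage_dist.", nm, ": sum != 1"))
  }
  s5 <- params$survival$five_year
  v <- add(any(s5 < 0) || any(s5 > 1), "survival.five_year: outside [0, 1]")
  v <- add(is.unsorted(rev(s5)), "survival.five_year: must be non-increasing with stage")
  v <- add(!(params$survival$stage4_epsilon > 0 && params$survival$stage4_epsilon < 1),
           "survival.stage4_epsilon: outside (0, 1)")
  costs <- unlist(params$costs)
  v <- add(any(costs < 0), "costs: negative cost")
  v <- add(!(params$costs$program_cost_proportion >= 0 &&
               params$costs$program_cost_proportion < 1),
           "costs.program_cost_proportion: outside [0, 1)")
  u <- params$utilities$stage
  v <- add(any(u < 0) || any(u > 1), "utilities.stage: outside [0, 1]")
  v <- add(is.unsorted(rev(u)), "utilities.stage: must be non-increasing with stage")
  v <- add(params$econ$discount_rate < 0, "econ.discount_rate: negative")
  v <- add(params$econ$wtp <= 0, "econ.wtp: must be > 0")
  v <- add(!(params$econ$termination_fraction > 0 && params$econ$termination_fraction <= 1),
           "econ.termination_fraction: outside (0, 1]")
  for (st in params$strategies) {
    v <- add(!(st$interval_effect >= 0 && st$interval_effect <= 1),
             paste0("strategies.", st$name, ".interval_effect: outside [0, 1]"))
    for (fld in c("highrisk_period", "lowrisk_period"))
      v <- add(!(is.na(st[[fld]]) || st[[fld]] %in% c(1, 2)),
               paste0("strategies.", st$name, ".", fld, ": must be 1, 2 or NA"))
  }
  ok_epi <- tryCatch({
    validate_rate_table(params$epi$mortality)
    validate_rate_table(params$epi$incidence)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok_epi)) v <- c(v, paste0("epi: ", ok_epi))
  w <- params$epi$weights
  v <- add(any(w$weight < 0), "epi.weights: negative weight")
  v <- add(abs(sum(w$weight) - 1) > 1e-9, "epi.weights: weights do not sum to 1")
  v
}

# ---- config I/O --------------------------------------------------------

config_settable <- function() {
  # leaves of the params list a config file may override
  c("risk.prevalence", "risk.odds_ratio",
    "test.sensitivity", "test.specificity",
    "stage_dist.program", "stage_dist.usual",
    "survival.five_year", "survival.stage4_epsilon",
    "costs.baseline_ogd", "costs.followup_ogd", "costs.dx_staging_program",
    "costs.dx_staging_usual", "costs.treatment",
    "costs.post_treatment_followup", "costs.program_cost_proportion",
    "utilities.asymptomatic", "utilities.dead", "utilities.stage",
    "econ.discount_rate", "econ.wtp", "econ.termination_fraction",
    "econ.max_age", "econ.half_cycle_correction",
    "psa.dirichlet_ess",
    paste0("strategies.", names(default_strategies()), ".interval_effect"),
    "epi.mortality_csv", "epi.incidence_csv", "epi.weights_csv",
    "population.ages", "population.sexes", "seed")
}

flatten_keys <- function(x, prefix = NULL) {
  if (!is.list(x)) return(paste(prefix, collapse = "."))
  unlist(lapply(names(x), function(nm) flatten_keys(x[[nm]], c(prefix, nm))))
}

#' Load model parameters from a JSON config file
#'
#' The config is a nested JSON object covering any subset of the documented
#' keys (see `config_settable()` in the package source or the methods
#' vignette); unspecified fields take their defaults, unknown keys are
#' rejected with their full path named. `epi.mortality_csv`,
#' `epi.incidence_csv` and `epi.weights_csv` point to CSV files replacing the
#' synthetic epidemiology; `population.ages`/`population.sexes` restrict the
#' starting cohort.
#'
#' @param path JSON file path (or `NULL` for pure defaults)
#' @return a `gccea_params` object with attribute `"seed"` if the config sets one
#' @export
load_config <- function(path = NULL) {
  params <- default_params()
  if (is.null(path)) return(params)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- flatten_keys(cfg)
  unknown <- setdiff(keys, config_settable())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  base <- dirname(path)
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  if (!is.null(cfg$epi$mortality_csv))
    params$epi$mortality <- read_rate_table(resolve(cfg$epi$mortality_csv), "mortality")
  if (!is.null(cfg$epi$incidence_csv))
    params$epi$incidence <- read_rate_table(resolve(cfg$epi$incidence_csv), "incidence")
  if (!is.null(cfg$epi$weights_csv)) {
    w <- utils::read.csv(resolve(cfg$epi$weights_csv), stringsAsFactors = FALSE)
    params$epi$weights <- normalize_weights(w)
  }
  if (!is.null(cfg$population)) {
    w <- params$epi$weights
    if (!is.null(cfg$population$ages)) w <- w[w$age %in% cfg$population$ages, ]
    if (!is.null(cfg$population$sexes)) w <- w[w$sex %in% cfg$population$sexes, ]
    if (!nrow(w)) stop("population restriction leaves no subgroups", call. = FALSE)
    params$epi$weights <- normalize_weights(w)
  }
  plain <- setdiff(keys, c("epi.mortality_csv", "epi.incidence_csv",
                           "epi.weights_csv", "population.ages",
                           "population.sexes", "seed"))
  for (key in plain) {
    parts <- param_path_split(key)
    val <- cfg
    for (prt in parts) val <- val[[prt]]
    node <- params
    for (prt in parts[-length(parts)]) node <- node[[prt]]
    old <- node[[parts[length(parts)]]]
    if (is.numeric(old) && !is.numeric(val) ||
        (length(old) > 1L && length(val) != length(old)))
      stop("config key ", key, ": type/length mismatch", call. = FALSE)
    params <- assign_path(params, parts, val)
  }
  if (!is.null(cfg$seed)) attr(params, "seed") <- as.integer(cfg$seed)
  bad <- validate_params(params)
  if (length(bad))
    stop("invalid configuration: ", paste(bad, collapse = "; "), call. = FALSE)
  params
}

assign_path <- function(params, parts, val) {
  rec <- function(node, parts) {
    if (length(parts) == 1L) { node[[parts]] <- val; return(node) }
    node[[parts[1]]] <- rec(node[[parts[1]]], parts[-1])
    node
  }
  out <- rec(unclass(params), parts)
  class(out) <- "gccea_params"
  out
}

#' Write the scalar/vector parameters of a model to a JSON config
#'
#' The epidemiology tables themselves are not embedded; use
#' [write_rate_table()] for those. Round-trips through [load_config()].
#'
#' @param params a `gccea_params` object
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_config <- function(params, path) {
  cfg <- list(
    risk = params$risk, test = params$test, stage_dist = params$stage_dist,
    survival = params$survival, costs = params$costs,
    utilities = params$utilities, econ = params$econ,
    psa = list(dirichlet_ess = params$psa$dirichlet_ess),
    strategies = lapply(params$strategies,
                        function(s) list(interval_effect = s$interval_effect))
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
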