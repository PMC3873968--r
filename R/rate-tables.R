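#' Age- and sex-specific rate tables
#'
#' A `rate_table` holds one annual quantity per (age, sex) cell: either an
#' annual death probability (`kind = "mortality"`, values in \[0, 1\]) or an
#' annual gastric-cancer incidence per 100,000 (`kind = "incidence"`, values
#' >= 0; converted to a probability by /100000 inside the engine). Ages are
#' integer years and must be contiguous per sex.
#'
#' @param age integer vector of ages (years)
#' @param sex character vector, `"male"`/`"female"`
#' @param value numeric vector of annual probabilities or rates per 100,000
#' @param kind `"mortality"` or `"incidence"`
#' @return an object of class `rate_table`: a data.frame with columns
#'   `age`, `sex`, `value` and attribute `kind`
#' @export
rate_table <- function(age, sex, value, kind = c("mortality", "incidence")) {
  kind <- match.arg(kind)
  stopifnot(length(age) == length(sex), length(age) == length(value))
  age <- as.integer(age)
  sex <- as.character(sex)
  tbl <- data.frame(age = age, sex = sex, value = as.numeric(value),
                    stringsAsFactors = FALSE)
  tbl <- tbl[order(tbl$sex, tbl$age), , drop = FALSE]
  rownames(tbl) <- NULL
  class(tbl) <- c("rate_table", "data.frame")
  attr(tbl, "kind") <- kind
  validate_rate_table(tbl)
  tbl
}

validate_rate_table <- function(tbl) {
  kind <- attr(tbl, "kind")
  if (!all(c("age", "sex", "value") %in% names(tbl)))
    stop("rate table must have columns age, sex, value", call. = FALSE)
  if (!all(tbl$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (anyNA(tbl$value) || !is.numeric(tbl$value))
    stop("rate table values must be numeric and non-missing", call. = FALSE)
  if (any(duplicated(tbl[c("age", "sex")])))
    stop("duplicated (age, sex) rows in rate table", call. = FALSE)
  if (kind == "mortality" && (any(tbl$value < 0) || any(tbl$value > 1)))
    stop("mortality values must be annual probabilities in [0, 1]", call. = FALSE)
  if (kind == "incidence" && any(tbl$value < 0))
    stop("incidence values must be non-negative", call. = FALSE)
  for (s in unique(tbl$sex)) {
    a <- sort(tbl$age[tbl$sex == s])
    if (length(a) > 1L && !all(diff(a) == 1L))
      stop("ages must be contiguous for sex '", s, "'", call. = FALSE)
  }
  invisible(tbl)
}

#' Look up annual rates for a run of ages
#'
#' @param tbl a [rate_table()]
#' @param ages integer ages
#' @param sex a single sex
#' @return numeric vector of values, one per age
#' @export
rate_lookup <- function(tbl, ages, sex) {
  sub <- tbl[tbl$sex == sex, , drop = FALSE]
  idx <- match(as.integer(ages), sub$age)
  if (anyNA(idx))
    stop("rate table (", attr(tbl, "kind"), ") has no value for sex '", sex,
         "' at age(s) ", paste(ages[is.na(idx)], collapse = ", "), call. = FALSE)
  sub$value[idx]
}

#' Generate a Gompertz-Makeham life table
#'
#' Annual death probability `q(age) = 1 - exp(-(a + b * exp(c * age)))`,
#' clamped to \[0, 1\]. The Makeham term `a` is the age-independent hazard and
#' the Gompertz pair `(b, c)` the exponentially rising senescent hazard; the
#' defaults give a life expectancy of roughly 85 years, in the range of a
#' developed East-Asian population. Deterministic; `seed` is accepted for
#' interface stability but unused.
#'
#' @param sex `"male"` or `"female"`
#' @param makeham_a,makeham_b,makeham_c hazard parameters (1/year); `c` must
#'   be > 0 so that hazard rises with age
#' @param max_age last tabulated age (<= 110)
#' @param seed unused
#' @return a mortality [rate_table()] over ages `0:max_age`
#' @export
generate_life_table <- function(sex = c("female", "male"),
                                makeham_a = 5e-4,
                                makeham_b = if (match.arg(sex) == "male") 4.5e-5 else 2.5e-5,
                                makeham_c = 0.095,
                                max_age = 110L, seed = NULL) {
  sex <- match.arg(sex)
  if (!all(is.finite(c(makeham_a, makeham_b, makeham_c, max_age))))
    stop("life-table parameters must be finite", call. = FALSE)
  if (makeham_a < 0 || makeham_b < 0)
    stop("hazard parameters must be non-negative", call. = FALSE)
  if (makeham_c <= 0)
    stop("makeham_c must be > 0: death probability must not decrease with age",
         call. = FALSE)
  if (max_age > 110) stop("max_age must be <= 110", call. = FALSE)
  ages <- 0:max_age
  q <- 1 - exp(-(makeham_a + makeham_b * exp(makeham_c * ages)))
  q <- pmin(pmax(q, 0), 1)
  if (any(q[ages < 60] >= 1))
    stop("implausible parameters: annual death probability reaches 1 before age 60",
         call. = FALSE)
  rate_table(ages, rep(sex, length(ages)), q, kind = "mortality")
}

#' Generate an exponential-in-age gastric cancer incidence table
#'
#' `I(age) = base * (1 + growth)^(age - 50)` per 100,000 person-years, capped
#' at 2,000/100,000. Emulates the sharp rise of gastric-cancer risk after age
#' 50 in a low-to-intermediate-risk population; default male base rate is
#' twice the female one.
#'
#' @param sex `"male"` or `"female"`
#' @param base_rate_per100k_at50 incidence per 100,000 at age 50
#' @param annual_growth proportional annual increase (e.g. 0.07)
#' @param max_age last tabulated age
#' @return an incidence [rate_table()] over ages `0:max_age`
#' @export
generate_incidence_table <- function(sex = c("female", "male"),
                                     base_rate_per100k_at50 = if (match.arg(sex) == "male") 28 else 14,
                                     annual_growth = 0.07,
                                     max_age = 110L) {
  sex <- match.arg(sex)
  if (!all(is.finite(c(base_rate_per100k_at50, annual_growth))))
    stop("incidence parameters must be finite", call. = FALSE)
  if (base_rate_per100k_at50 < 0 || annual_growth < 0)
    stop("incidence parameters must be non-negative", call. = FALSE)
  ages <- 0:max_age
  rate <- base_rate_per100k_at50 * (1 + annual_growth)^(ages - 50)
  rate <- pmin(rate, 2000)
  rate_table(ages, rep(sex, length(ages)), rate, kind = "incidence")
}

bind_rate_tables <- function(...) {
  tbls <- list(...)
  kind <- unique(vapply(tbls, function(t) attr(t, "kind"), character(1)))
  if (length(kind) != 1L) stop("cannot bind rate tables of different kinds", call. = FALSE)
  df <- do.call(rbind, lapply(tbls, as.data.frame))
  rate_table(df$age, df$sex, df$value, kind = kind)
}

#' Read a rate table from CSV
#'
#' Expects header columns `age,sex,value`; `sex` in `male`/`female`;
#' mortality values are annual probabilities, incidence values per 100,000.
#'
#' @param path CSV file path
#' @param kind `"mortality"` or `"incidence"`
#' @return a [rate_table()]
#' @export
read_rate_table <- function(path, kind = c("mortality", "incidence")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("age", "sex", "value"), names(df))
  if (length(missing))
    stop("rate table CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$value))
    stop("rate table column 'value' must be numeric", call. = FALSE)
  rate_table(df$age, df$sex, df$value, kind = kind)
}

#' Write a rate table to CSV
#'
#' Values are written with 15 significant digits so that
#' `read_rate_table(write_rate_table(x))` round-trips to at least 12
#' significant digits.
#'
#' @param tbl a [rate_table()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_rate_table <- function(tbl, path) {
  out <- data.frame(age = tbl$age, sex = tbl$sex,
                    value = formatC(tbl$value, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand an age-banded table to single-year ages
#'
#' Registry tables are often published in 5-year bands; this helper repeats
#' each band value over its constituent single-year ages.
#'
#' @param df data.frame with columns `age_start`, `age_end`, `sex`, `value`
#' @param kind rate kind of the result
#' @return a [rate_table()]
#' @export
expand_age_bands <- function(df, kind = c("mortality", "incidence")) {
  kind <- match.arg(kind)
  stopifnot(all(c("age_start", "age_end", "sex", "value") %in% names(df)))
  if (any(df$age_end < df$age_start)) stop("age_end < age_start", call. = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ages <- df$age_start[i]:df$age_end[i]
    data.frame(age = ages, sex = df$sex[i], value = df$value[i])
  })
  out <- do.call(rbind, rows)
  rate_table(out$age, out$sex, out$value, kind = kind)
}

#' Population weights over starting ages 50-69
#'
#' The default is uniform: 20 ages x 2 sexes, each weight 1/40. Any
#' data.frame with columns `age`, `sex`, `weight` can be normalized with
#' [normalize_weights()].
#'
#' @return data.frame of class `population_weights` with columns
#'   `age`, `sex`, `weight` summing to 1
#' @export
default_population_weights <- function() {
  grid <- expand.grid(age = 50:69, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  grid$weight <- 1 / nrow(grid)
  normalize_weights(grid)
}

#' Normalize population weights
#'
#' @param w data.frame with columns `age`, `sex`, `weight`
#' @return the same data.frame with weights rescaled to sum to 1
#' @export
normalize_weights <- function(w) {
  stopifnot(all(c("age", "sex", "weight") %in% names(w)))
  if (any(w$weight < 0)) stop("population weights must be non-negative", call. = FALSE)
  if (any(duplicated(w[c("age", "sex")])))
    stop("duplicated (age, sex) rows in population weights", call. = FALSE)
  tot <- sum(w$weight)
  if (tot <= 0) stop("population weights must have positive total", call. = FALSE)
  w$weight <- w$weight / tot
  w <- w[order(w$sex, w$age), , drop = FALSE]
  rownames(w) <- NULL
  class(w) <- c("population_weights", "data.frame")
  w
}
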