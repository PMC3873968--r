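#' Net health benefit
#'
#' `effect - cost / lambda`, in QALY units. Rankings by net health benefit
#' and by net monetary benefit (`lambda * effect - cost`) coincide at fixed
#' willingness-to-pay.
#'
#' @param cost cost per person ($)
#' @param effect effectiveness per person (QALY)
#' @param lambda willingness-to-pay ($/QALY), > 0
#' @return net health benefit (QALY), vectorised
#' @export
nhb <- function(cost, effect, lambda) {
  stopifnot(all(lambda > 0))
  effect - cost / lambda
}

#' Build the cost-effectiveness frontier
#'
#' Orders strategies by ascending cost (ties broken by higher effect, then
#' name), flags strictly dominated strategies (some other strategy costs no
#' more and yields no less, with at least one strict inequality), then
#' iteratively removes extendedly dominated strategies until the incremental
#' cost-effectiveness ratios along the surviving sequence are strictly
#' increasing. ICERs are recomputed between surviving neighbours.
#'
#' @param outcomes data.frame with columns `strategy`, `cost`, `effect`
#'   (unique strategy names)
#' @return a `cea_frontier`: the input sorted by cost with columns `status`
#'   (`"on_frontier"`, `"dominated"`, `"extendedly_dominated"`) and `icer`
#'   (vs the previous on-frontier strategy; `NA` for the cheapest)
#' @export
build_frontier <- function(outcomes) {
  stopifnot(all(c("strategy", "cost", "effect") %in% names(outcomes)),
            nrow(outcomes) >= 1L)
  if (anyDuplicated(outcomes$strategy))
    stop("duplicate strategy names", call. = FALSE)
  df <- outcomes[order(outcomes$cost, -outcomes$effect, outcomes$strategy), ,
                 drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  status <- rep("on_frontier", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
          (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }
  # exact (cost, effect) ties collapse to the first-sorted point
  for (i in seq_len(n)) {
    if (status[i] != "on_frontier") next
    for (j in seq_len(i - 1L)) {
      if (status[j] == "on_frontier" &&
          df$cost[j] == df$cost[i] && df$effect[j] == df$effect[i]) {
        status[i] <- "dominated"
        break
      }
    }
  }

  repeat {
    idx <- which(status == "on_frontier")
    if (length(idx) <= 2L) break
    ic <- diff(df$cost[idx]) / diff(df$effect[idx])
    bad <- which(ic[-length(ic)] >= ic[-1L])
    if (!length(bad)) break
    status[idx[bad[1L] + 1L]] <- "extendedly_dominated"
  }

  idx <- which(status == "on_frontier")
  icer <- rep(NA_real_, n)
  if (length(idx) > 1L)
    icer[idx[-1L]] <- diff(df$cost[idx]) / diff(df$effect[idx])
  df$status <- status
  df$icer <- icer
  class(df) <- c("cea_frontier", "data.frame")
  df
}

#' Optimal strategy at a willingness-to-pay
#'
#' The most effective on-frontier strategy whose ICER against the previous
#' on-frontier strategy does not exceed `lambda` -- equivalently the argmax
#' of net monetary benefit. The least-cost (reference) strategy is returned
#' when no frontier ICER is below `lambda`.
#'
#' @param frontier a [build_frontier()] result
#' @param lambda willingness-to-pay ($/QALY), > 0
#' @return strategy name
#' @export
optimal_at_wtp <- function(frontier, lambda) {
  stopifnot(lambda > 0)
  idx <- which(frontier$status == "on_frontier")
  best <- idx[1L]
  for (i in idx[-1L])
    if (frontier$icer[i] <= lambda) best <- i else break
  frontier$strategy[best]
}

#' League table with net monetary benefit at a willingness-to-pay
#'
#' @param frontier a [build_frontier()] result
#' @param lambda willingness-to-pay ($/QALY)
#' @return the frontier with an `nmb` column and an `optimal` flag
#' @export
league_table <- function(frontier, lambda) {
  frontier$nmb <- lambda * frontier$effect - frontier$cost
  frontier$optimal <- frontier$strategy == optimal_at_wtp(frontier, lambda)
  frontier
}
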